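test_that("colony genotype calls respect depth and the het window", {
  cols <- data.frame(colony_id = c("c1", "c2", "c3", "c4"),
                     compartment = c("HSC", "HSC", "MPP", "MPP"))
  vaf <- matrix(c(0.48, 0.01, 0.45, 0.85), 4, 1,
                dimnames = list(NULL, "chr1.100.A.G"))
  depth <- matrix(c(1000L, 1000L, 5L, 1000L), 4, 1)
  mat <- genotype_colonies(colony_matrix("x", cols, vaf, depth))
  expect_equal(unname(mat$calls[, 1]),
               c("PRESENT",    # 0.48 deep: near-0.5 het
                 "ABSENT",     # 0.01 deep
                 "AMBIGUOUS",  # depth 5 below min_depth
                 "AMBIGUOUS")) # above het_high: not a clean het site
})

test_that("mouse-33 fixture recovers the nested two-subclone architecture", {
  fx <- ch_fixtures()
  model <- clone_model_fit(fx$mouse33$matrix, fx$mouse33$bm_vaf)
  expect_equal(nrow(model$clones), 3)
  muts <- strsplit(model$clones$mutations, ",")
  expect_setequal(unlist(muts), unname(fx$mouse33$keys))
  nell2 <- which(vapply(muts, function(m) fx$mouse33$keys[["Nell2"]] %in% m,
                        TRUE))
  # both CH clones nested inside the embryonic Nell2 clone, mutually exclusive
  expect_setequal(model$relations$nested$parent, nell2)
  expect_equal(nrow(model$relations$nested), 2)
  expect_equal(nrow(model$relations$exclusive), 1)
  expect_equal(nrow(model$conflicts), 0)
  expect_equal(sort(model$clones$fraction_bm), c(0.24, 0.28, 0.58))
  comp <- render_composition(model)
  expect_equal(comp$remainder, 1 - 0.58)
  expect_equal(length(comp$tree), 1)
  expect_equal(length(comp$tree[[1]]$children), 2)
})

test_that("mouse-85 fixture yields four exclusive clones delivering 80% of BM", {
  fx <- ch_fixtures()
  model <- clone_model_fit(fx$mouse85$matrix, fx$mouse85$bm_vaf)
  expect_equal(nrow(model$clones), 4)
  recovered <- lapply(strsplit(model$clones$mutations, ","), sort)
  truth <- lapply(fx$mouse85$groups, function(g) sort(unname(g)))
  expect_setequal(lapply(recovered, paste, collapse = "|"),
                  lapply(truth, paste, collapse = "|"))
  expect_equal(nrow(model$relations$nested), 0)
  expect_equal(nrow(model$relations$exclusive), 6)  # all pairs disjoint
  expect_equal(model$delivered_fraction, 0.8, tolerance = 1e-12)
  expect_equal(render_composition(model)$remainder, 0.2, tolerance = 1e-12)
})

test_that("mutations never seen in any colony stay singleton groups", {
  cols <- data.frame(colony_id = c("c1", "c2"),
                     compartment = c("HSC", "MPP"))
  vaf <- matrix(0, 2, 3, dimnames = list(NULL, c("chr1.1.A.G", "chr1.2.C.T",
                                                 "chr2.3.G.A")))
  depth <- matrix(1000L, 2, 3)
  mat <- genotype_colonies(colony_matrix("x", cols, vaf, depth))
  groups <- group_mutations(mat)
  expect_equal(length(groups), 3)
  expect_true(all(lengths(lapply(groups, `[[`, "support")) == 0))
})

test_that("crossing colony supports are recorded as tree conflicts", {
  cols <- data.frame(colony_id = c("c1", "c2", "c3"),
                     compartment = c("HSC", "HSC", "HSC"))
  vaf <- matrix(c(0.5, 0.5, 0,    # mutA: c1, c2
                  0, 0.5, 0.5),   # mutB: c2, c3
                3, 2, dimnames = list(NULL, c("chr1.1.A.G", "chr2.2.C.T")))
  depth <- matrix(1000L, 3, 2)
  mat <- genotype_colonies(colony_matrix("x", cols, vaf, depth))
  groups <- group_mutations(mat)
  rel <- infer_relations(groups, mat)
  expect_equal(nrow(rel$conflicts), 1)
  expect_equal(nrow(rel$nested), 0)
})

test_that("ambiguous colonies are excluded from containment decisions", {
  # mutB truly nested in mutA, but one colony is unreadable for mutB
  cols <- data.frame(colony_id = c("c1", "c2", "c3", "c4"),
                     compartment = rep("HSC", 4))
  vaf <- matrix(c(0.5, 0.5, 0.5, 0,
                  0.5, 0.4, 0, 0), 4, 2,
                dimnames = list(NULL, c("chr1.1.A.G", "chr2.2.C.T")))
  depth <- matrix(1000L, 4, 2)
  depth[2, 2] <- 5L  # c2 ambiguous for mutB
  mat <- genotype_colonies(colony_matrix("x", cols, vaf, depth))
  groups <- group_mutations(mat)
  rel <- infer_relations(groups, mat)
  expect_equal(nrow(rel$nested), 1)
  expect_equal(nrow(rel$conflicts), 0)
})

test_that("noise-free simulated colonies recover partition and tree exactly", {
  set.seed(29)
  for (rep in 1:100) {
    tree <- random_clone_tree()
    mat <- simulate_colony_matrix(tree$fractions, tree$parent,
                                  tree$mutations,
                                  n_hsc = 30, n_mpp = 30,
                                  noise = "none", assignment = "expected")
    mat <- genotype_colonies(mat)
    groups <- group_mutations(mat)
    # exact partition recovery
    recovered <- sort(vapply(groups, function(g)
      paste(sort(g$mutations), collapse = "|"), ""))
    truth <- sort(vapply(tree$mutations, function(m)
      paste(sort(m), collapse = "|"), ""))
    expect_identical(recovered, truth)
    # exact tree recovery: nesting matches the parent pointers
    rel <- infer_relations(groups, mat)
    g_of <- vapply(groups, function(g) {
      which(vapply(tree$mutations, function(m) setequal(m, g$mutations),
                   TRUE))
    }, 1L)
    true_pairs <- sort(stats::na.omit(vapply(seq_along(tree$parent),
      function(c) {
        if (is.na(tree$parent[c])) NA_character_
        else paste(match(c, g_of), match(tree$parent[c], g_of))
      }, "")))
    got_pairs <- sort(paste(rel$nested$child, rel$nested$parent))
    expect_identical(got_pairs, as.character(true_pairs))
    expect_equal(nrow(rel$conflicts), 0)
  }
})

test_that("nesting relation forms a forest on conflict-free input", {
  set.seed(31)
  for (rep in 1:20) {
    tree <- random_clone_tree()
    mat <- simulate_colony_matrix(tree$fractions, tree$parent,
                                  tree$mutations, n_hsc = 30, n_mpp = 30,
                                  noise = "none", assignment = "expected")
    mat <- genotype_colonies(mat)
    rel <- infer_relations(group_mutations(mat), mat)
    # each child has at most one minimal parent and no cycles
    expect_true(all(table(rel$nested$child) >= 1) ||
                  nrow(rel$nested) == 0)
    if (nrow(rel$nested) > 0) {
      expect_false(any(paste(rel$nested$parent, rel$nested$child) %in%
                         paste(rel$nested$child, rel$nested$parent)))
    }
  }
})

test_that("estimated fractions track truth within 0.02 under read noise", {
  set.seed(37)
  hits <- 0L; total <- 0L
  for (rep in 1:20) {
    sim <- simulate_cohort(sim_config(seed = 1000 + rep,
                                      n_irradiated = 6, n_control = 0,
                                      n_colony_animals = 0))
    tr <- sim$truth$mutations
    ch <- tr[tr$true_class == "CH_NONMOSAIC", ]
    if (nrow(ch) == 0) next
    key <- paste(ch$animal_id, variant_key(ch$chrom, ch$pos, ch$ref, ch$alt))
    pkey <- paste(sim$profiles$animal_id,
                  variant_key(sim$profiles$chrom, sim$profiles$pos,
                              sim$profiles$ref, sim$profiles$alt))
    est <- 2 * sim$profiles$vaf_BM[match(key, pkey)]
    truth_frac <- sim$truth$clones$fraction[
      match(paste(ch$animal_id, ch$clone_id),
            paste(sim$truth$clones$animal_id, sim$truth$clones$clone_id))]
    hits <- hits + sum(abs(est - truth_frac) <= 0.02)
    total <- total + length(est)
  }
  expect_gt(total, 200)
  expect_gte(hits / total, 0.95)
})

test_that("fraction checks flag nested children larger than their parent", {
  cols <- data.frame(colony_id = c("c1", "c2"), compartment = c("HSC", "MPP"))
  vaf <- matrix(c(0.5, 0.5, 0.5, 0), 2, 2,
                dimnames = list(NULL, c("chr1.1.A.G", "chr2.2.C.T")))
  depth <- matrix(1000L, 2, 2)
  mat <- genotype_colonies(colony_matrix("x", cols, vaf, depth))
  groups <- group_mutations(mat)
  rel <- infer_relations(groups, mat)
  bm <- c("chr1.1.A.G" = 0.1, "chr2.2.C.T" = 0.4)  # child bigger than parent
  model <- estimate_fractions(groups, rel, bm, mat)
  expect_true(length(model$checks) > 0)
  # single clone at the boundary VAF 0.5 -> fraction 1, passes <= 1 + tol
  bm1 <- c("chr1.1.A.G" = 0.5, "chr2.2.C.T" = NA)
  expect_warning(m1 <- estimate_fractions(groups, rel, bm1, mat),
                 "no BM observation")
  expect_equal(max(m1$clones$fraction_bm, na.rm = TRUE), 1)
})
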