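# Clonal architecture from single-HSPC colony genotypes: presence calls,
# grouping of co-occurring mutations into clones, nesting/exclusivity
# inference, and BM cell-fraction estimation by VAF doubling.

#' Colony genotype-call thresholds
#'
#' A colony grown from one cell carries a heterozygous mutation at a VAF
#' near 0.5; read sampling spreads this out, so presence is called inside a
#' het window.
#'
#' @param min_depth Minimum read depth to call at all (default 20).
#' @param het_low,het_high Heterozygous VAF window (defaults 0.3 and 0.7).
#' @param max_pattern_mismatch Colonies by which two mutations' presence
#'   patterns may differ and still be grouped into one clone (default 0).
#' @return Object of class `genotype_config`.
#' @export
genotype_config <- function(min_depth = 20L, het_low = 0.3, het_high = 0.7,
                            max_pattern_mismatch = 0L) {
  stopifnot(het_low > 0, het_low < 0.5, het_high > 0.5, het_high <= 1,
            min_depth > 0, max_pattern_mismatch >= 0)
  structure(list(min_depth = as.integer(min_depth), het_low = het_low,
                 het_high = het_high,
                 max_pattern_mismatch = as.integer(max_pattern_mismatch)),
            class = "genotype_config")
}

#' Call mutation presence in each colony
#'
#' PRESENT when depth >= `min_depth` and VAF in [`het_low`, `het_high`];
#' ABSENT when depth >= `min_depth` and VAF < `het_low`; AMBIGUOUS
#' otherwise (insufficient depth, missing data, or VAF above the het
#' window, which in a clonal colony suggests an artifact rather than a
#' heterozygous site).
#'
#' @param mat A [colony_matrix()].
#' @param config A [genotype_config()].
#' @return `mat` with its `calls` matrix filled.
#' @export
genotype_colonies <- function(mat, config = genotype_config()) {
  stopifnot(inherits(mat, "colony_matrix"))
  vaf <- mat$vaf; depth <- mat$depth
  calls <- matrix("AMBIGUOUS", nrow(vaf), ncol(vaf),
                  dimnames = dimnames(vaf))
  deep <- !is.na(depth) & depth >= config$min_depth & !is.na(vaf)
  calls[deep & vaf >= config$het_low & vaf <= config$het_high] <- "PRESENT"
  calls[deep & vaf < config$het_low] <- "ABSENT"
  mat$calls <- calls
  mat$config <- config
  mat
}

# colonies unambiguous for both of two call columns
.shared_unambiguous <- function(calls, i, j) {
  calls[, i] != "AMBIGUOUS" & calls[, j] != "AMBIGUOUS"
}

#' Group co-occurring mutations into candidate clones
#'
#' Two mutations belong to the same clone when their PRESENT-colony
#' patterns agree, up to `max_pattern_mismatch` colonies, over the colonies
#' unambiguous for both (single-linkage over such pairs). Mutations never
#' seen PRESENT each form their own group with empty support.
#'
#' @param mat A genotyped [colony_matrix()] (calls filled).
#' @return List of groups, each a list with `mutations` (variant keys) and
#'   `support` (colony ids PRESENT for at least one member).
#' @export
group_mutations <- function(mat) {
  stopifnot(inherits(mat, "colony_matrix"), !is.null(mat$calls))
  calls <- mat$calls
  m <- ncol(calls)
  if (m == 0) return(list())
  mm <- mat$config$max_pattern_mismatch
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (m > 1) {
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        ok <- .shared_unambiguous(calls, i, j)
        pi <- calls[ok, i] == "PRESENT"
        pj <- calls[ok, j] == "PRESENT"
        if (sum(pi | pj) == 0) next   # no shared support evidence
        if (sum(xor(pi, pj)) <= mm) parent[find(i)] <- find(j)
      }
    }
  }
  grp <- vapply(seq_len(m), find, 1L)
  grp <- match(grp, unique(grp))
  lapply(seq_len(max(grp)), function(g) {
    members <- mat$variants[grp == g]
    pres <- calls[, grp == g, drop = FALSE] == "PRESENT"
    list(mutations = members,
         support = mat$colonies$colony_id[rowSums(pres) > 0])
  })
}

#' Infer nesting and exclusivity between clone groups
#'
#' For groups A and B, restricted to colonies unambiguous for every member
#' of both: B is nested in A when B's support is a strict non-empty subset
#' of A's; A and B are exclusive when their supports are disjoint and both
#' non-empty; supports that cross (overlap without containment) violate the
#' clonal-tree assumption and are recorded as conflicts.
#'
#' @param groups Output of [group_mutations()].
#' @param mat The genotyped [colony_matrix()].
#' @return List with data.frames `nested` (child, parent), `exclusive`
#'   (a, b) and `conflicts` (a, b).
#' @export
infer_relations <- function(groups, mat) {
  stopifnot(length(groups) >= 1)
  calls <- mat$calls
  ids <- mat$colonies$colony_id
  # per-group: colony unambiguous for ALL members; support among those
  g_unamb <- lapply(groups, function(g) {
    cols <- match(g$mutations, mat$variants)
    rowSums(calls[, cols, drop = FALSE] == "AMBIGUOUS") == 0
  })
  nested <- data.frame(child = character(0), parent = character(0))
  exclusive <- data.frame(a = character(0), b = character(0))
  conflicts <- data.frame(a = character(0), b = character(0))
  ng <- length(groups)
  if (ng >= 2) {
    for (i in seq_len(ng - 1)) {
      for (j in (i + 1):ng) {
        ok <- g_unamb[[i]] & g_unamb[[j]]
        si <- intersect(groups[[i]]$support, ids[ok])
        sj <- intersect(groups[[j]]$support, ids[ok])
        if (length(si) == 0 || length(sj) == 0) next
        inter <- intersect(si, sj)
        if (length(inter) == 0) {
          exclusive <- rbind(exclusive, data.frame(a = i, b = j))
        } else if (length(inter) == length(sj) && length(sj) < length(si)) {
          nested <- rbind(nested, data.frame(child = j, parent = i))
        } else if (length(inter) == length(si) && length(si) < length(sj)) {
          nested <- rbind(nested, data.frame(child = i, parent = j))
        } else if (length(inter) == length(si) && length(si) == length(sj)) {
          # identical supports that were not merged (pattern mismatch 0 but
          # union-support equality): treat as conflict to surface it
          conflicts <- rbind(conflicts, data.frame(a = i, b = j))
        } else {
          conflicts <- rbind(conflicts, data.frame(a = i, b = j))
        }
      }
    }
  }
  list(nested = nested, exclusive = exclusive, conflicts = conflicts)
}

#' Estimate clone fractions and assemble the clone model
#'
#' Each clone's BM cell fraction is twice the mean BM VAF over its member
#' mutations (members of one clone should agree; disagreement beyond
#' `vaf_tol` is warned about). Consistency checks: a nested child's
#' fraction must not exceed its parent's by more than `frac_tol`, and the
#' top-level (non-nested) fractions must sum to at most `1 + frac_tol`.
#'
#' @param groups Output of [group_mutations()].
#' @param relations Output of [infer_relations()].
#' @param bm_vaf Named numeric vector: BM VAF per variant key.
#' @param mat The genotyped [colony_matrix()] (for compartment reporting).
#' @param frac_tol Fraction-consistency tolerance (default 0.1).
#' @param vaf_tol Within-clone member VAF agreement tolerance (default 0.05).
#' @return Object of class `clone_model`: `clones` data.frame (clone_id,
#'   mutations, fraction_bm, colony_fraction, n_colonies, compartments),
#'   `relations`, `conflicts`, `delivered_fraction` (sum of doubled VAFs
#'   over maximal clones), `delivered_colony_fraction` (share of
#'   unambiguous colonies carrying any clone), `checks`.
#' @export
estimate_fractions <- function(groups, relations, bm_vaf, mat,
                               frac_tol = 0.1, vaf_tol = 0.05) {
  ng <- length(groups)
  frac <- numeric(ng)
  colony_frac <- numeric(ng)
  comps <- character(ng)
  nc <- integer(ng)
  total_colonies <- nrow(mat$colonies)
  for (g in seq_len(ng)) {
    v <- bm_vaf[groups[[g]]$mutations]
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      warning("clone ", g, " has no BM observation; fraction missing")
      frac[g] <- NA_real_
    } else {
      if (length(v) > 1 && diff(range(v)) > vaf_tol) {
        warning("clone ", g, " member BM VAFs disagree beyond ", vaf_tol)
      }
      frac[g] <- clone_fraction(mean(v))
    }
    sup <- groups[[g]]$support
    nc[g] <- length(sup)
    colony_frac[g] <- if (total_colonies > 0) length(sup) / total_colonies else NA_real_
    comps[g] <- paste(sort(unique(
      mat$colonies$compartment[mat$colonies$colony_id %in% sup])),
      collapse = "+")
  }
  clones <- data.frame(
    clone_id = seq_len(ng),
    mutations = vapply(groups, function(g) paste(g$mutations, collapse = ","), ""),
    fraction_bm = frac, colony_fraction = colony_frac,
    n_colonies = nc, compartments = comps,
    stringsAsFactors = FALSE
  )
  # consistency checks
  checks <- character(0)
  if (nrow(relations$nested) > 0) {
    for (r in seq_len(nrow(relations$nested))) {
      ch <- relations$nested$child[r]; pa <- relations$nested$parent[r]
      if (!is.na(frac[ch]) && !is.na(frac[pa]) &&
          frac[ch] > frac[pa] + frac_tol) {
        checks <- c(checks, sprintf(
          "nested clone %d fraction %.3f exceeds parent %d fraction %.3f + tol",
          ch, frac[ch], pa, frac[pa]))
      }
    }
  }
  top <- setdiff(seq_len(ng), relations$nested$child)
  top_sum <- sum(frac[top], na.rm = TRUE)
  if (top_sum > 1 + frac_tol) {
    checks <- c(checks, sprintf(
      "top-level fractions sum to %.3f > 1 + tol", top_sum))
  }
  any_clone <- unique(unlist(lapply(groups, `[[`, "support")))
  structure(
    list(animal_id = mat$animal_id, clones = clones, relations = relations,
         conflicts = relations$conflicts, frac_tol = frac_tol,
         top_level = top, delivered_fraction = top_sum,
         delivered_colony_fraction =
           if (total_colonies > 0) length(any_clone) / total_colonies else NA_real_,
         checks = checks),
    class = "clone_model"
  )
}

#' Fit the full clone model from a colony matrix and bulk BM VAFs
#'
#' Convenience wrapper: [genotype_colonies()] then [group_mutations()],
#' [infer_relations()] and [estimate_fractions()].
#'
#' @param mat A [colony_matrix()].
#' @param bm_vaf Named numeric vector of bulk BM VAFs per variant key.
#' @param config A [genotype_config()].
#' @param frac_tol,vaf_tol See [estimate_fractions()].
#' @return A `clone_model`.
#' @export
clone_model_fit <- function(mat, bm_vaf, config = genotype_config(),
                            frac_tol = 0.1, vaf_tol = 0.05) {
  mat <- genotype_colonies(mat, config)
  groups <- group_mutations(mat)
  rel <- infer_relations(groups, mat)
  model <- estimate_fractions(groups, rel, bm_vaf, mat,
                              frac_tol = frac_tol, vaf_tol = vaf_tol)
  model$groups <- groups
  model
}

#' Render a clone model as a nested composition tree
#'
#' Machine-readable version of a clonal-composition panel: each top-level
#' clone with its nested children, plus the unassigned remainder
#' `1 - delivered_fraction` (allowed to go slightly negative, down to
#' `-frac_tol`, from VAF noise).
#'
#' @param model A `clone_model`.
#' @return List with `tree` (list of nodes: clone_id, mutations, fraction,
#'   children) and `remainder`.
#' @export
render_composition <- function(model) {
  clones <- model$clones
  nested <- model$relations$nested
  node <- function(i) {
    kids <- if (nrow(nested) > 0) nested$child[nested$parent == i] else integer(0)
    list(clone_id = i,
         mutations = strsplit(clones$mutations[i], ",")[[1]],
         fraction = clones$fraction_bm[i],
         children = lapply(kids, node))
  }
  tree <- lapply(model$top_level, node)
  remainder <- 1 - model$delivered_fraction
  if (remainder < -model$frac_tol) {
    warning("composition remainder ", round(remainder, 3),
            " below -frac_tol; fractions inconsistent")
  }
  list(tree = tree, remainder = remainder)
}

#' @export
print.clone_model <- function(x, ...) {
  cat("Clone model for animal", x$animal_id, "-", nrow(x$clones),
      "clone(s)\n")
  for (i in seq_len(nrow(x$clones))) {
    tag <- if (i %in% x$top_level) "top" else "nested"
    cat(sprintf("  clone %d [%s, %s]: %s  fraction %.2f (%d colonies, %.2f of colonies)\n",
                i, tag, x$clones$compartments[i], x$clones$mutations[i],
                x$clones$fraction_bm[i], x$clones$n_colonies[i],
                x$clones$colony_fraction[i]))
  }
  if (nrow(x$relations$nested) > 0) {
    cat("  nesting:",
        paste(sprintf("%d in %d", x$relations$nested$child,
                      x$relations$nested$parent), collapse = "; "), "\n")
  }
  if (nrow(x$relations$exclusive) > 0) {
    cat("  exclusive pairs:",
        paste(sprintf("%d|%d", x$relations$exclusive$a,
                      x$relations$exclusive$b), collapse = "; "), "\n")
  }
  if (nrow(x$conflicts) > 0) {
    cat("  CONFLICTS:", nrow(x$conflicts), "crossing pair(s)\n")
  }
  cat(sprintf("  delivered fraction (doubled VAFs): %.2f; remainder %.2f\n",
              x$delivered_fraction, 1 - x$delivered_fraction))
  cat(sprintf("  delivered fraction (colony share): %.2f\n",
              x$delivered_colony_fraction))
  if (length(x$checks) > 0) cat("  checks:", paste(x$checks, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.clone_model <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.clone_model <- function(x, ...) {
  comp <- render_composition(x)
  fr <- c(vapply(comp$tree, `[[`, 0, "fraction"), max(comp$remainder, 0))
  labs <- c(vapply(comp$tree, function(n) paste(n$mutations, collapse = "\n"), ""),
            "unassigned")
  graphics::barplot(matrix(fr, ncol = 1),
                    col = c(grDevices::hcl.colors(length(fr) - 1, "Dark 3"),
                            "grey85"),
                    ylab = "fraction of BM nuclear cells",
                    legend.text = labs, ...)
  invisible(x)
}
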