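# Synthetic cohort generator.
#
# Emulates the statistical structure of a whole-body-irradiation CH study:
# embryonic mosaic mutations shared across tissues, hematopoietic-restricted
# CH clones (optionally nested inside an expanded mosaic ancestor), a
# radiation-like spectrum (C>T-dominant SNVs, 1-31 nt deletions with
# optional junction microhomology, clustered multisite events), binomial
# read sampling at configurable depth, and single-HSPC colony draws with
# heterozygous VAFs near 0.5. Ground truth is exported for recovery tests.

.CHROMS <- c(paste0("chr", 1:19), "chrX")

#' Simulation configuration
#'
#' Defaults describe a cohort of 3-Gy whole-body irradiated male mice and
#' non-irradiated controls profiled at 12-18 months of age.
#'
#' @param n_irradiated,n_control Animals per group (defaults 12 and 6).
#' @param tissues Bulk tissues profiled (default the nine-organ panel).
#' @param lineages Sorted BM fractions (default T, B, GRAN, ERY).
#' @param mosaic_rate Mean embryonic mosaic mutations per animal (0.5).
#' @param mosaic_expansion_prob Probability that a mosaic mutation in an
#'   irradiated animal is clonally expanded in the hematopoietic system
#'   (the CH-mosaic channel; default 0.5, 0 in controls).
#' @param ch_rate_irradiated,ch_rate_control Mean CH clones per animal
#'   (defaults 4 and 0).
#' @param clone_fraction_conc Dirichlet concentration for splitting the
#'   delivered cell fraction across clones (default 5).
#' @param clone_fraction_total Range the per-animal total delivered cell
#'   fraction is drawn from (default c(0.2, 0.9)).
#' @param mutations_per_clone_mean Mean of the zero-truncated Poisson number
#'   of mutations per clone (default 2).
#' @param sub_weights Pyrimidine-strand substitution-class weights
#'   (C>T-dominant by default).
#' @param deletion_fraction Fraction of single-site events that are
#'   deletions (default 0.55).
#' @param deletion_length_weights Length law over 1-31 nt (default: mass on
#'   1-3 and 5-31 nt, none on 4).
#' @param microhomology_prob Probability a deletion gets >=2 nt of planted
#'   junction microhomology (default 0.35).
#' @param multisite_prob Probability a clone mutation is a clustered
#'   multisite event instead of a single site (default 0.05).
#' @param depth_bulk,depth_amplicon,depth_colony Sequencing depths: exome
#'   discovery, targeted amplicon validation (used for the emitted tissue
#'   observations), colony genotyping (defaults 500 / 30000 / 100).
#' @param seq_error Per-base error VAF floor added to every sampling
#'   probability (default 0.001).
#' @param t_cell_exclusion_prob Probability a CH clone is absent from the
#'   T lineage (default 0.5).
#' @param n_colony_animals Irradiated animals that also get colony
#'   genotyping (default 2).
#' @param n_colonies Colonies per compartment for those animals (default 20
#'   HSC + 20 MPP).
#' @param colony_beta_shape Shape of the symmetric Beta(s, s) distribution
#'   of heterozygous colony VAFs around 0.5 (default 100).
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_irradiated = 12L, n_control = 6L,
                       tissues = c("BM", "spleen", "thymus", "tail",
                                   "kidney", "liver", "brain", "thyroid",
                                   "testis"),
                       lineages = c("T", "B", "GRAN", "ERY"),
                       mosaic_rate = 0.5, mosaic_expansion_prob = 0.5,
                       ch_rate_irradiated = 4.0, ch_rate_control = 0.0,
                       clone_fraction_conc = 5,
                       clone_fraction_total = c(0.2, 0.9),
                       mutations_per_clone_mean = 2,
                       sub_weights = c("C>A" = 0.08, "C>G" = 0.06,
                                       "C>T" = 0.40, "T>A" = 0.10,
                                       "T>C" = 0.22, "T>G" = 0.14),
                       deletion_fraction = 0.55,
                       deletion_length_weights = NULL,
                       microhomology_prob = 0.35,
                       multisite_prob = 0.05,
                       depth_bulk = 500L, depth_amplicon = 30000L,
                       depth_colony = 100L, seq_error = 0.001,
                       t_cell_exclusion_prob = 0.5,
                       n_colony_animals = 2L, n_colonies = 20L,
                       colony_beta_shape = 100, seed = NULL) {
  if (is.null(deletion_length_weights)) {
    w <- numeric(31)
    w[1:3] <- 0.343 / 3
    w[5:31] <- 0.657 / 27
    deletion_length_weights <- w
  }
  stopifnot(n_irradiated >= 0, n_control >= 0,
            "BM" %in% tissues,
            mosaic_rate >= 0, ch_rate_irradiated >= 0, ch_rate_control >= 0,
            mutations_per_clone_mean >= 1,
            length(deletion_length_weights) == 31,
            clone_fraction_total[1] > 0, clone_fraction_total[2] <= 1,
            depth_amplicon > 0, seq_error >= 0, seq_error < 0.01)
  sub_weights <- sub_weights / sum(sub_weights)
  deletion_length_weights <- deletion_length_weights /
    sum(deletion_length_weights)
  structure(as.list(environment()), class = "sim_config")
}

# zero-truncated Poisson with a given mean >= 1
.rztpois <- function(n, mean) {
  if (n == 0) return(integer(0))
  if (mean <= 1 + 1e-9) return(rep(1L, n))
  lambda <- stats::uniroot(function(l) l / (1 - exp(-l)) - mean,
                           c(1e-8, 100))$root
  out <- stats::rpois(n, lambda)
  while (any(out == 0)) out[out == 0] <- stats::rpois(sum(out == 0), lambda)
  out
}

.random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# one SNV allele pair from pyrimidine-class weights, random strand
.draw_snv <- function(weights) {
  cls <- sample(names(weights), 1, prob = weights)
  ref <- substr(cls, 1, 1); alt <- substr(cls, 3, 3)
  if (stats::runif(1) < 0.5) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ref <- comp[[ref]]; alt <- comp[[alt]]
  }
  c(ref = ref, alt = alt)
}

# one deletion: VCF anchor-base alleles + explicit flank context, with
# microhomology planted at the stated probability
.draw_deletion <- function(len_weights, mh_prob, flank_len = 40L) {
  d <- sample.int(31L, 1, prob = len_weights)
  deleted <- .random_seq(d)
  left <- .random_seq(flank_len)
  right <- .random_seq(flank_len)
  if (stats::runif(1) < mh_prob) {
    mh <- sample(2:min(4L, d), 1)
    # copy the start of the deleted tract onto the start of the right flank
    right <- paste0(substr(deleted, 1, mh), substr(right, mh + 1, flank_len))
  }
  anchor <- substr(left, nchar(left), nchar(left))
  list(ref = paste0(anchor, deleted), alt = anchor, deleted_seq = deleted,
       left_flank = left, right_flank = right, len = d)
}

#' Simulate a cohort of irradiated and control animals
#'
#' Generates per-animal ground-truth clones and mutations, then wide
#' variant profiles with binomially sampled read counts in every tissue and
#' sorted lineage, per-animal covariates with blood indices, and colony
#' genotype matrices for a subset of irradiated animals.
#'
#' Reproducibility: with `config$seed` set, repeated calls return identical
#' output.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_cohort`: `profiles` (wide table with
#'   `vaf_*`/`depth_*` columns and deletion contexts), `animals`,
#'   `colonies` (named list of [colony_matrix()]), `truth` (list with
#'   `mutations` and `clones` data.frames), and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config
  n_tot <- cfg$n_irradiated + cfg$n_control
  animals <- data.frame(
    animal_id = sprintf("m%02d", seq_len(n_tot)),
    group = rep(c("IRRADIATED", "CONTROL"),
                c(cfg$n_irradiated, cfg$n_control)),
    stringsAsFactors = FALSE
  )
  animals$dose_Gy <- ifelse(animals$group == "IRRADIATED", 3, 0)
  animals$sex <- sample(c("M", "F"), n_tot, replace = TRUE)
  animals$age_months <- round(stats::runif(n_tot, 14.5, 19.5), 1)
  # blood indices: irradiation raises myeloid % and RDW, lowers lymphocyte %,
  # with larger residual spread in the irradiated group (heteroskedastic)
  irr <- animals$group == "IRRADIATED"
  sdv <- ifelse(irr, 8, 4)
  mye <- 30 + 15 * irr + 0.8 * (animals$age_months - 17) +
    3 * (animals$sex == "M") + stats::rnorm(n_tot, 0, sdv)
  animals$mye_pct <- pmin(pmax(mye, 2), 98)
  animals$lym_pct <- 100 - animals$mye_pct
  animals$rdw <- 16 + 2.5 * irr + stats::rnorm(n_tot, 0, ifelse(irr, 1.2, 0.6))

  all_cols <- c(cfg$tissues, cfg$lineages)
  mut_list <- list()
  clone_list <- list()
  colonies <- list()
  colony_targets <- head(animals$animal_id[irr], cfg$n_colony_animals)

  for (ai in seq_len(n_tot)) {
    aid <- animals$animal_id[ai]
    is_irr <- irr[ai]
    n_mos <- stats::rpois(1, cfg$mosaic_rate)
    n_clones <- stats::rpois(1, if (is_irr) cfg$ch_rate_irradiated else
      cfg$ch_rate_control)

    # clone bookkeeping for this animal: id, fraction, parent, kind
    a_clones <- data.frame(clone_id = integer(0), fraction = numeric(0),
                           parent = integer(0), kind = character(0))
    next_clone <- 1L
    a_muts <- list()
    used_pos <- new.env()

    draw_pos <- function(k = 1L) {
      chrom <- sample(.CHROMS, 1)
      repeat {
        base <- sample.int(1e8L, 1)
        key <- paste(chrom, base %/% 1000L)
        if (is.null(used_pos[[key]])) { assign(key, TRUE, used_pos); break }
      }
      list(chrom = chrom, pos = base + cumsum(c(0L, sample(10:40, k - 1,
                                                           replace = TRUE))))
    }

    add_mut <- function(kind, clone_id, vafs, event_id) {
      is_ms <- stats::runif(1) < cfg$multisite_prob && !is.na(clone_id)
      n_members <- if (is_ms) sample(2:3, 1) else 1L
      loc <- draw_pos(n_members)
      for (mme in seq_len(n_members)) {
        is_del <- stats::runif(1) <
          (if (is_ms) 0.5 else cfg$deletion_fraction)
        if (is_del) {
          al <- .draw_deletion(cfg$deletion_length_weights,
                               cfg$microhomology_prob)
          ctx <- al[c("deleted_seq", "left_flank", "right_flank")]
        } else {
          al <- as.list(.draw_snv(cfg$sub_weights))
          ctx <- list(deleted_seq = NA_character_,
                      left_flank = NA_character_,
                      right_flank = NA_character_)
        }
        a_muts[[length(a_muts) + 1L]] <<- c(
          list(animal_id = aid, chrom = loc$chrom, pos = loc$pos[mme],
               ref = al$ref, alt = al$alt, true_class = kind,
               clone_id = if (is.na(clone_id)) NA_integer_ else clone_id,
               event_id = event_id,
               event_type = if (is_ms) "MULTISITE" else
                 if (is_del) "DEL" else "SNV"),
          ctx, list(true_vaf = list(vafs)))
      }
    }

    event_counter <- 0L
    ancestor_id <- NA_integer_
    ancestor_frac <- NA_real_

    # embryonic mosaic mutations
    if (n_mos > 0) {
      for (mm in seq_len(n_mos)) {
        expanded <- is_irr && stats::runif(1) < cfg$mosaic_expansion_prob &&
          is.na(ancestor_id)  # at most one expanded ancestor per animal
        event_counter <- event_counter + 1L
        if (expanded) {
          frac <- stats::runif(1, 0.4, 0.65)
          v_bm <- frac / 2
          nh_base <- stats::runif(1, 0.008, 0.02)
          vafs <- stats::setNames(numeric(length(all_cols)), all_cols)
          hem <- c("BM", "spleen")
          vafs[hem] <- v_bm
          nh <- setdiff(cfg$tissues, hem)
          vafs[nh] <- nh_base * exp(stats::rnorm(length(nh), 0, 0.05))
          vafs["thymus"] <- nh_base
          vafs[cfg$lineages] <- v_bm * exp(stats::rnorm(length(cfg$lineages),
                                                        0, 0.1))
          vafs["T"] <- nh_base  # expanded HSPCs contribute little to T cells
          a_clones <- rbind(a_clones, data.frame(
            clone_id = next_clone, fraction = frac, parent = NA_integer_,
            kind = "CH_MOSAIC"))
          ancestor_id <- next_clone
          ancestor_frac <- frac
          add_mut("CH_MOSAIC", next_clone, pmin(vafs, 0.5), event_counter)
          next_clone <- next_clone + 1L
        } else {
          base <- stats::runif(1, 0.03, 0.3)
          vafs <- stats::setNames(
            base * exp(stats::rnorm(length(all_cols), 0, 0.05)), all_cols)
          add_mut("MOSAIC_NOT_CH", NA_integer_, pmin(vafs, 0.5),
                  event_counter)
        }
      }
    }

    # CH clones restricted to the hematopoietic system
    if (n_clones > 0) {
      w <- stats::rgamma(n_clones, cfg$clone_fraction_conc)
      w <- w / sum(w)
      total <- stats::runif(1, cfg$clone_fraction_total[1],
                            cfg$clone_fraction_total[2])
      scale_to <- if (!is.na(ancestor_frac)) ancestor_frac else 1
      fracs <- w * total * scale_to
      for (ci in seq_len(n_clones)) {
        frac <- fracs[ci]
        a_clones <- rbind(a_clones, data.frame(
          clone_id = next_clone, fraction = frac, parent = ancestor_id,
          kind = "CH_NONMOSAIC"))
        n_mut <- .rztpois(1, cfg$mutations_per_clone_mean)
        v_bm <- frac / 2
        t_excluded <- stats::runif(1) < cfg$t_cell_exclusion_prob
        vafs <- stats::setNames(numeric(length(all_cols)), all_cols)
        vafs[c("BM", "spleen")] <- v_bm
        lin <- setdiff(cfg$lineages, "T")
        vafs[lin] <- pmin(v_bm * exp(stats::rnorm(length(lin), 0, 0.2)), 0.5)
        vafs["T"] <- if (t_excluded) 0 else v_bm
        for (mi in seq_len(n_mut)) {
          event_counter <- event_counter + 1L
          add_mut("CH_NONMOSAIC", next_clone, vafs, event_counter)
        }
        next_clone <- next_clone + 1L
      }
    }

    if (nrow(a_clones) > 0) {
      a_clones$animal_id <- aid
      clone_list[[length(clone_list) + 1L]] <- a_clones
    }
    if (length(a_muts) > 0) {
      mut_list[[aid]] <- a_muts
    }

    # colony genotyping for the selected animals
    if (aid %in% colony_targets) {
      ch_rows <- if (nrow(a_clones) > 0) a_clones else NULL
      if (!is.null(ch_rows) && nrow(ch_rows) > 0) {
        keys_by_clone <- lapply(ch_rows$clone_id, function(cid) {
          ms <- Filter(function(m) identical(m$clone_id, cid), a_muts)
          vapply(ms, function(m) variant_key(m$chrom, m$pos, m$ref, m$alt), "")
        })
        colonies[[aid]] <- simulate_colony_matrix(
          fractions = ch_rows$fraction, parent = ch_rows$parent,
          mutations = keys_by_clone, animal_id = aid,
          n_hsc = cfg$n_colonies, n_mpp = cfg$n_colonies,
          depth = cfg$depth_colony, beta_shape = cfg$colony_beta_shape,
          seq_error = cfg$seq_error)
      }
    }
  }

  truth_mut <- if (length(mut_list) > 0) {
    rows <- unlist(mut_list, recursive = FALSE)
    df <- data.frame(
      animal_id = vapply(rows, `[[`, "", "animal_id"),
      chrom = vapply(rows, `[[`, "", "chrom"),
      pos = vapply(rows, function(r) as.integer(r$pos), 1L),
      ref = vapply(rows, `[[`, "", "ref"),
      alt = vapply(rows, `[[`, "", "alt"),
      true_class = vapply(rows, `[[`, "", "true_class"),
      clone_id = vapply(rows, function(r)
        if (is.na(r$clone_id)) NA_integer_ else as.integer(r$clone_id), 1L),
      event_id = vapply(rows, function(r) as.integer(r$event_id), 1L),
      event_type = vapply(rows, `[[`, "", "event_type"),
      deleted_seq = vapply(rows, `[[`, "", "deleted_seq"),
      left_flank = vapply(rows, `[[`, "", "left_flank"),
      right_flank = vapply(rows, `[[`, "", "right_flank"),
      stringsAsFactors = FALSE
    )
    tv <- do.call(rbind, lapply(rows, function(r) r$true_vaf[[1]]))
    colnames(tv) <- paste0("true_vaf_", all_cols)
    df <- cbind(df, as.data.frame(tv))
    rownames(df) <- NULL
    df
  } else {
    data.frame()
  }
  truth_clones <- if (length(clone_list) > 0) do.call(rbind, clone_list)
  else data.frame()

  # read sampling: wide profile table
  profiles <- NULL
  if (nrow(truth_mut) > 0) {
    profiles <- truth_mut[c("animal_id", "chrom", "pos", "ref", "alt",
                            "deleted_seq", "left_flank", "right_flank")]
    profiles$variant_type <- variant_type(profiles$ref, profiles$alt)
    profiles$class_label <- "UNCLASSIFIED"
    nmut <- nrow(profiles)
    for (tc in all_cols) {
      p <- pmin(truth_mut[[paste0("true_vaf_", tc)]] + cfg$seq_error, 1)
      depth <- rep(cfg$depth_amplicon, nmut)
      alt <- stats::rbinom(nmut, depth, p)
      profiles[[paste0("vaf_", tc)]] <- alt / depth
      profiles[[paste0("depth_", tc)]] <- depth
    }
  } else {
    profiles <- data.frame(animal_id = character(0), chrom = character(0),
                           pos = integer(0), ref = character(0),
                           alt = character(0), variant_type = character(0),
                           class_label = character(0))
  }

  structure(
    list(profiles = profiles, animals = animals, colonies = colonies,
         truth = list(mutations = truth_mut, clones = truth_clones),
         config = cfg),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated cohort:", x$config$n_irradiated, "irradiated +",
      x$config$n_control, "control animals;",
      nrow(x$truth$mutations), "true mutations,",
      nrow(x$truth$clones), "clones,",
      length(x$colonies), "colony matrices\n")
  invisible(x)
}

#' Simulate a colony genotype matrix from a clone tree
#'
#' Colonies are sorted single cells: each is either wild type or belongs to
#' exactly one clone of the tree and carries that clone's mutations plus
#' all of its ancestors'. Carried mutations are heterozygous, with VAF drawn
#' from Beta(`beta_shape`, `beta_shape`) around 0.5 and then binomially
#' read-sampled at `depth`; uncarried sites sample at the `seq_error` floor.
#' With `noise = "none"` VAFs are exactly 0.5 / 0 with no read sampling
#' (useful for exact-recovery checks); `assignment = "expected"` allocates
#' colony counts proportionally to clone probabilities (deterministic,
#' every clone with positive probability gets at least one colony)
#' instead of multinomial draws.
#'
#' @param fractions Per-clone total cell fraction (including descendants).
#' @param parent Per-clone parent index, NA for top-level clones.
#' @param mutations List of character vectors: each clone's own variant keys.
#' @param animal_id Label for the resulting matrix.
#' @param n_hsc,n_mpp Colonies per compartment.
#' @param depth Read depth per (colony, variant).
#' @param beta_shape Beta(s, s) concentration of het VAFs around 0.5.
#' @param seq_error Error VAF floor.
#' @param noise "binomial" (default) or "none".
#' @param assignment "multinomial" (default) or "expected".
#' @return A [colony_matrix()] with attribute `truth_assignment` (clone
#'   index per colony, 0 = wild type).
#' @export
simulate_colony_matrix <- function(fractions, parent, mutations,
                                   animal_id = "sim",
                                   n_hsc = 20L, n_mpp = 20L, depth = 100L,
                                   beta_shape = 100, seq_error = 0.001,
                                   noise = c("binomial", "none"),
                                   assignment = c("multinomial", "expected")) {
  noise <- match.arg(noise)
  assignment <- match.arg(assignment)
  k <- length(fractions)
  stopifnot(length(parent) == k, length(mutations) == k)
  # probability a colony is EXACTLY clone c = fraction minus children's
  p_exact <- fractions
  for (c in seq_len(k)) {
    kids <- which(!is.na(parent) & parent == c)
    p_exact[c] <- p_exact[c] - sum(fractions[kids])
  }
  if (any(p_exact < -1e-9)) stop("child fractions exceed parent fraction")
  p_exact <- pmax(p_exact, 0)
  top <- which(is.na(parent))
  p_wt <- max(0, 1 - sum(fractions[top]))
  probs <- c(p_wt, p_exact)

  n_col <- n_hsc + n_mpp
  if (assignment == "multinomial") {
    assign_idx <- sample.int(k + 1L, n_col, replace = TRUE, prob = probs) - 1L
  } else {
    cnt <- floor(probs / sum(probs) * n_col)
    cnt[-1][p_exact > 0 & cnt[-1] == 0] <- 1L
    while (sum(cnt) > n_col) cnt[which.max(cnt)] <- cnt[which.max(cnt)] - 1L
    while (sum(cnt) < n_col) cnt[1] <- cnt[1] + 1L
    assign_idx <- rep(0:k, cnt)
  }
  # carried mutations: own + ancestors'
  ancestry <- lapply(seq_len(k), function(c) {
    path <- c
    while (!is.na(parent[path[1]])) path <- c(parent[path[1]], path)
    path
  })
  keys <- unlist(mutations)
  if (anyDuplicated(keys)) stop("duplicate variant keys across clones")
  m <- length(keys)
  vaf <- matrix(NA_real_, n_col, m, dimnames = list(NULL, keys))
  depth_mat <- matrix(as.integer(depth), n_col, m,
                      dimnames = list(NULL, keys))
  carried <- matrix(FALSE, n_col, m)
  for (i in seq_len(n_col)) {
    if (assign_idx[i] > 0) {
      own <- unlist(mutations[ancestry[[assign_idx[i]]]])
      carried[i, keys %in% own] <- TRUE
    }
  }
  if (noise == "none") {
    vaf[] <- ifelse(carried, 0.5, 0)
  } else {
    p <- matrix(seq_error, n_col, m)
    p[carried] <- stats::rbeta(sum(carried), beta_shape, beta_shape)
    alt <- matrix(stats::rbinom(n_col * m, depth, pmin(p, 1)), n_col, m)
    vaf[] <- alt / depth
  }
  colonies <- data.frame(
    colony_id = sprintf("%s_%s%02d", animal_id,
                        rep(c("H", "P"), c(n_hsc, n_mpp)),
                        c(seq_len(n_hsc), seq_len(n_mpp))),
    compartment = rep(c("HSC", "MPP"), c(n_hsc, n_mpp)),
    stringsAsFactors = FALSE
  )
  out <- colony_matrix(animal_id, colonies, vaf, depth_mat)
  attr(out, "truth_assignment") <- assign_idx
  out
}

#' Melt wide profiles into the long observation format
#'
#' Inverse of [build_profiles()]: one row per (animal, tissue, variant),
#' skipping tissues with missing depth.
#'
#' @param profiles Wide profile table with `vaf_*`/`depth_*` columns.
#' @return Observation data.frame (see [variant_observations()]).
#' @export
profiles_to_observations <- function(profiles) {
  tissues <- profile_tissues(profiles)
  out <- do.call(rbind, lapply(tissues, function(tc) {
    d <- profiles[[paste0("depth_", tc)]]
    v <- profiles[[paste0("vaf_", tc)]]
    keep <- !is.na(d)
    data.frame(animal_id = profiles$animal_id[keep], tissue = tc,
               chrom = profiles$chrom[keep], pos = profiles$pos[keep],
               ref = profiles$ref[keep], alt = profiles$alt[keep],
               alt_reads = as.integer(round(v[keep] * d[keep])),
               depth = as.integer(d[keep]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write a simulated cohort to disk
#'
#' Emits `variants.tsv` (long observation table), `animals.csv`, one
#' `colonies_<animal>.csv` per colony matrix, and `truth.json`.
#'
#' @param sim A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of paths written.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  obs <- profiles_to_observations(sim$profiles)
  p <- file.path(dir, "variants.tsv")
  utils::write.table(obs, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "animals.csv")
  utils::write.csv(sim$animals, p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  for (aid in names(sim$colonies)) {
    p <- file.path(dir, paste0("colonies_", aid, ".csv"))
    write_colony_matrix(sim$colonies[[aid]], p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, p, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
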