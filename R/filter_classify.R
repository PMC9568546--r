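# Candidate filtering and tissue-distribution classification.
#
# Survivor rule (on the bone-marrow sample): VAF in [vaf_min, vaf_max],
# alt-read support >= min_alt_reads, and the variant must not recur across
# most animals of the cohort (panel-of-normals-style artifact filter).
# Surviving variants are then classified by where they sit in the body:
# embryonic mosaic (similar VAFs in non-hematopoietic tissue), CH-associated
# mosaic (present at low VAF outside blood, expanded in BM), or CH-associated
# non-mosaic (hematopoietic only).

#' Filtering and classification thresholds
#'
#' @param vaf_min,vaf_max Inclusive BM VAF band for somatic candidates
#'   (defaults 0.02 and 0.35; above `vaf_max` a variant is treated as likely
#'   germline).
#' @param min_alt_reads Minimum BM alt-read support (default 6, i.e. variants
#'   supported by 5 or fewer reads are dropped).
#' @param recurrence_fraction Variants detected in more than this fraction of
#'   all animals are treated as recurrent artifacts (default 0.5).
#' @param detect_vaf Minimum VAF at which a variant counts as detected in a
#'   tissue (default 0.005).
#' @param similar_fold Maximum BM : non-hematopoietic VAF ratio still
#'   considered "similar" (default 3).
#' @param expanded_fold Minimum BM : non-hematopoietic VAF ratio considered
#'   "substantially expanded" (default 5).
#' @param nh_reference_tissues Non-hematopoietic tissues used as the
#'   mosaicism reference (default tail, brain, testis, thyroid; the
#'   blood-filtering kidney and liver are deliberately excluded).
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(vaf_min = 0.02, vaf_max = 0.35, min_alt_reads = 6L,
                          recurrence_fraction = 0.5, detect_vaf = 0.005,
                          similar_fold = 3.0, expanded_fold = 5.0,
                          nh_reference_tissues = c("tail", "brain", "testis",
                                                   "thyroid")) {
  stopifnot(vaf_min > 0, vaf_min < vaf_max, vaf_max < 0.5,
            min_alt_reads >= 0, recurrence_fraction > 0,
            recurrence_fraction <= 1, detect_vaf > 0,
            similar_fold <= expanded_fold)
  structure(
    list(vaf_min = vaf_min, vaf_max = vaf_max,
         min_alt_reads = as.integer(min_alt_reads),
         recurrence_fraction = recurrence_fraction, detect_vaf = detect_vaf,
         similar_fold = similar_fold, expanded_fold = expanded_fold,
         nh_reference_tissues = nh_reference_tissues),
    class = "filter_config"
  )
}

#' Apply the candidate filters across a cohort
#'
#' A variant survives in an animal iff its BM VAF lies in
#' `[vaf_min, vaf_max]`, its BM alt-read count is at least `min_alt_reads`,
#' and the fraction of animals in which the variant is detected anywhere
#' (max VAF over tissues >= `detect_vaf`) does not exceed
#' `recurrence_fraction`. Rejected variants carry exactly one primary reason
#' with precedence germline_vaf > low_vaf > read_support > recurrence.
#'
#' @param profiles Profile table from [build_profiles()] covering the whole
#'   cohort (needed for the recurrence filter).
#' @param n_animals Number of animals sequenced; defaults to the number of
#'   distinct `animal_id`s in `profiles`.
#' @param config A [filter_config()].
#' @return `profiles` with added columns `survives` (logical) and
#'   `reject_reason` (NA for survivors).
#' @export
filter_candidates <- function(profiles, config = filter_config(),
                              n_animals = NULL) {
  if (nrow(profiles) == 0) stop("empty cohort: no variant profiles")
  if (!"vaf_BM" %in% names(profiles)) {
    stop("profiles must include a BM measurement (vaf_BM column)")
  }
  if (is.null(n_animals)) n_animals <- length(unique(profiles$animal_id))

  key <- variant_key(profiles$chrom, profiles$pos, profiles$ref, profiles$alt)
  vaf_cols <- grep("^vaf_", names(profiles), value = TRUE)
  max_vaf <- do.call(pmax, c(unname(profiles[vaf_cols]), list(na.rm = TRUE)))
  detected <- !is.na(max_vaf) & max_vaf >= config$detect_vaf
  # detected-animal count per variant key (each animal contributes once)
  det_animals <- tapply(profiles$animal_id[detected], key[detected],
                        function(a) length(unique(a)))
  det_frac <- ifelse(key %in% names(det_animals),
                     det_animals[key] / n_animals, 0)

  bm_vaf <- profiles$vaf_BM
  bm_alt <- if ("depth_BM" %in% names(profiles)) {
    round(bm_vaf * profiles$depth_BM)
  } else {
    rep(NA_real_, nrow(profiles))
  }

  reason <- rep(NA_character_, nrow(profiles))
  reason[is.na(bm_vaf)] <- "no_bm_observation"
  reason[is.na(reason) & bm_vaf > config$vaf_max] <- "germline_vaf"
  reason[is.na(reason) & bm_vaf < config$vaf_min] <- "low_vaf"
  reason[is.na(reason) & !is.na(bm_alt) &
           bm_alt < config$min_alt_reads] <- "read_support"
  reason[is.na(reason) &
           det_frac > config$recurrence_fraction] <- "recurrence"

  profiles$survives <- is.na(reason)
  profiles$reject_reason <- reason
  profiles
}

#' Classify one variant profile by its tissue distribution
#'
#' Let `v_bm` be the BM VAF and `v_nh` the maximum VAF over the measured
#' non-hematopoietic reference tissues. The label is:
#' \itemize{
#'   \item `CH_NONMOSAIC` if `v_nh < detect_vaf` (hematopoietic only);
#'   \item `CH_MOSAIC` if `v_nh >= detect_vaf` and
#'     `v_bm / v_nh >= expanded_fold` (embryonic mosaic, expanded in blood);
#'   \item `MOSAIC_NOT_CH` if `v_nh >= detect_vaf` and
#'     `v_bm / v_nh <= similar_fold` (similar VAFs body-wide);
#'   \item `UNCLASSIFIED` otherwise (ratio in the ambiguous band), or when no
#'     non-hematopoietic reference tissue was measured.
#' }
#'
#' @param vaf_by_tissue Named numeric vector of VAFs (names = tissue labels).
#' @param config A [filter_config()].
#' @return Character label.
#' @export
classify_profile <- function(vaf_by_tissue, config = filter_config()) {
  if (!"BM" %in% names(vaf_by_tissue) || is.na(vaf_by_tissue[["BM"]])) {
    stop("profile has no BM VAF")
  }
  v_bm <- vaf_by_tissue[["BM"]]
  nh <- vaf_by_tissue[names(vaf_by_tissue) %in% config$nh_reference_tissues]
  nh <- nh[!is.na(nh)]
  if (length(nh) == 0) return("UNCLASSIFIED")
  v_nh <- max(nh)
  if (v_nh < config$detect_vaf) return("CH_NONMOSAIC")
  ratio <- v_bm / v_nh
  if (ratio >= config$expanded_fold) return("CH_MOSAIC")
  if (ratio <= config$similar_fold) return("MOSAIC_NOT_CH")
  "UNCLASSIFIED"
}

#' Classify all surviving variant profiles
#'
#' Runs [classify_profile()] on every row with `survives == TRUE` (or on all
#' rows if [filter_candidates()] has not been applied) and fills
#' `class_label`.
#'
#' @param profiles Profile data.frame.
#' @param config A [filter_config()].
#' @return `profiles` with `class_label` filled in.
#' @export
classify_variants <- function(profiles, config = filter_config()) {
  rows <- if ("survives" %in% names(profiles)) which(profiles$survives) else
    seq_len(nrow(profiles))
  vaf_cols <- grep("^vaf_", names(profiles), value = TRUE)
  tissues <- sub("^vaf_", "", vaf_cols)
  for (i in rows) {
    v <- as.numeric(profiles[i, vaf_cols])
    names(v) <- tissues
    profiles$class_label[i] <- classify_profile(v, config)
  }
  profiles
}

#' Clone cell fraction from a heterozygous VAF
#'
#' Under the diploid heterozygous assumption a somatic mutation sits on one
#' chromosome of each carrier cell, so the carrier-cell fraction is twice
#' the VAF (a VAF of 0.1 means 20% of cells).
#'
#' @param vaf Numeric vector of VAFs in [0, 0.5].
#' @return `2 * vaf`.
#' @export
clone_fraction <- function(vaf) {
  if (any(!is.na(vaf) & (vaf < 0 | vaf > 0.5))) {
    stop("vaf must lie in [0, 0.5] under the heterozygous-diploid assumption")
  }
  2 * vaf
}

#' Summarize classified mutation counts per animal and group
#'
#' Per animal: counts of each class among survivors, with sub-counts
#' restricted to BM VAF strictly greater than `vaf_high` (default 0.1);
#' per group: arithmetic means of those counts. Also reports how many
#' animals carry at least one CH-associated mutation (CH mosaic +
#' non-mosaic), overall and at BM VAF > `vaf_high`.
#'
#' A clustered multisite event is one mutation: members of a cluster found
#' by [detect_multisite()] (within each animal and class) are counted once.
#'
#' @param profiles Classified profile table ([classify_variants()]).
#' @param animals Animal covariates ([animal_records()]); animals without
#'   mutations still appear with zero counts.
#' @param vaf_high Threshold for the parenthetical sub-counts (default 0.1,
#'   strict inequality).
#' @param collapse_multisite Count each multisite cluster as one mutation
#'   (default TRUE).
#' @return Object of class `cohort_summary` with elements `per_animal`
#'   (data.frame), `group_means` (data.frame), `n_with_ch`,
#'   `n_with_ch_high`, `totals`.
#' @export
summarize_cohort <- function(profiles, animals, vaf_high = 0.1,
                             collapse_multisite = TRUE) {
  animals <- animal_records(animals)
  if ("survives" %in% names(profiles)) {
    profiles <- profiles[profiles$survives, , drop = FALSE]
  }
  if (collapse_multisite && nrow(profiles) > 0) {
    keep <- rep(TRUE, nrow(profiles))
    split_idx <- split(seq_len(nrow(profiles)),
                       paste(profiles$animal_id, profiles$class_label))
    for (idx in split_idx) {
      cl <- detect_multisite(profiles[idx, , drop = FALSE])
      keep[idx][duplicated(cl)] <- FALSE
    }
    profiles <- profiles[keep, , drop = FALSE]
  }
  unknown <- setdiff(unique(profiles$animal_id), animals$animal_id)
  if (length(unknown) > 0) {
    stop("profile references unknown animal(s): ",
         paste(unknown, collapse = ", "))
  }
  classes <- c("MOSAIC_NOT_CH", "CH_MOSAIC", "CH_NONMOSAIC", "UNCLASSIFIED")
  per <- data.frame(animal_id = animals$animal_id, group = animals$group,
                    stringsAsFactors = FALSE)
  for (cl in classes) {
    in_cl <- profiles$class_label == cl
    cnt <- table(factor(profiles$animal_id[in_cl], levels = animals$animal_id))
    hi <- in_cl & !is.na(profiles$vaf_BM) & profiles$vaf_BM > vaf_high
    cnt_hi <- table(factor(profiles$animal_id[hi], levels = animals$animal_id))
    per[[cl]] <- as.integer(cnt)
    per[[paste0(cl, "_high")]] <- as.integer(cnt_hi)
  }
  per$CH_ASSOC <- per$CH_MOSAIC + per$CH_NONMOSAIC
  per$CH_ASSOC_high <- per$CH_MOSAIC_high + per$CH_NONMOSAIC_high

  count_cols <- setdiff(names(per), c("animal_id", "group"))
  gm <- aggregate(per[count_cols], by = list(group = per$group), FUN = mean)
  totals <- colSums(per[count_cols])

  structure(
    list(per_animal = per, group_means = gm,
         n_with_ch = sum(per$CH_ASSOC > 0),
         n_with_ch_high = sum(per$CH_ASSOC_high > 0),
         totals = totals, vaf_high = vaf_high),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, digits = 1, ...) {
  cat("Cohort mutation summary (", nrow(x$per_animal), " animals)\n", sep = "")
  cat("Per-group mean counts (sub-counts at BM VAF > ", x$vaf_high,
      " in parentheses):\n", sep = "")
  gm <- x$group_means
  for (i in seq_len(nrow(gm))) {
    cat(sprintf("  %-11s mosaic-not-CH %s (%s)  CH-mosaic %s (%s)  CH-non-mosaic %s (%s)\n",
                gm$group[i],
                round(gm$MOSAIC_NOT_CH[i], digits),
                round(gm$MOSAIC_NOT_CH_high[i], digits),
                round(gm$CH_MOSAIC[i], digits),
                round(gm$CH_MOSAIC_high[i], digits),
                round(gm$CH_NONMOSAIC[i], digits),
                round(gm$CH_NONMOSAIC_high[i], digits)))
  }
  cat("Animals with >=1 CH-associated mutation:", x$n_with_ch, "\n")
  cat("  ... at BM VAF >", x$vaf_high, ":", x$n_with_ch_high, "\n")
  cat("Total CH-associated non-mosaic mutations:",
      x$totals[["CH_NONMOSAIC"]], "\n")
  invisible(x)
}

#' @export
plot.cohort_summary <- function(x, ...) {
  per <- x$per_animal
  m <- t(as.matrix(per[c("MOSAIC_NOT_CH", "CH_MOSAIC", "CH_NONMOSAIC")]))
  colnames(m) <- per$animal_id
  graphics::barplot(m, las = 2, col = c("grey70", "orange", "firebrick"),
                    ylab = "recurrent mutations",
                    legend.text = c("mosaic not CH", "CH mosaic",
                                    "CH non-mosaic"), ...)
  invisible(x)
}
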