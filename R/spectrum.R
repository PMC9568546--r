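# Mutation-spectrum characterisation: variant typing, pyrimidine-collapsed
# substitution classes, deletion lengths, junction microhomology, and
# clustered (multisite) event detection.

#' Type a variant from its VCF-style alleles
#'
#' SNV when both alleles are single bases; DEL when the alt is a proper
#' prefix of the ref (anchor-base convention); INS symmetrically; anything
#' else is COMPLEX and excluded from the histograms downstream.
#'
#' @param ref,alt Character vectors of alleles.
#' @return Character vector in {"SNV","DEL","INS","COMPLEX"}.
#' @export
variant_type <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  out <- rep("COMPLEX", length(ref))
  out[nchar(ref) == 1 & nchar(alt) == 1 & ref != alt] <- "SNV"
  del <- nchar(ref) > nchar(alt) & substr(ref, 1, nchar(alt)) == alt
  out[del] <- "DEL"
  ins <- nchar(alt) > nchar(ref) & substr(alt, 1, nchar(ref)) == ref
  out[ins] <- "INS"
  out
}

#' Deletion length in nucleotides
#'
#' `nchar(ref) - nchar(alt)` for anchor-base deletions; NA for non-deletions.
#' @param ref,alt Allele vectors.
#' @return Integer vector.
#' @export
deletion_length <- function(ref, alt) {
  ifelse(variant_type(ref, alt) == "DEL",
         nchar(ref) - nchar(alt), NA_integer_)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse-complement a DNA string vector
#' @param x Character vector of ACGT strings.
#' @return Reverse complements.
#' @export
revcomp <- function(x) {
  vapply(strsplit(toupper(x), ""), function(b) {
    paste(rev(unname(.complement[b])), collapse = "")
  }, "")
}

#' Pyrimidine-collapsed substitution class of an SNV
#'
#' Substitutions with a purine reference base are reverse-complemented onto
#' the pyrimidine strand, so a G>A call is reported as C>T. The six classes
#' are C>A, C>G, C>T, T>A, T>C, T>G.
#'
#' @param ref,alt Single-base allele vectors.
#' @return Character vector of classes, e.g. "C>T".
#' @export
substitution_class <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(ref == alt)) stop("ref and alt must differ")
  if (any(nchar(ref) != 1 | nchar(alt) != 1)) stop("SNV alleles required")
  purine <- ref %in% c("A", "G")
  r <- ifelse(purine, .complement[ref], ref)
  a <- ifelse(purine, .complement[alt], alt)
  paste0(r, ">", a)
}

#' Junction microhomology length of a deletion
#'
#' Microhomology-mediated end joining leaves a short identical sequence
#' shared between the deleted segment and its flank. The score is the
#' longer of (a) the longest common prefix of the deleted sequence and the
#' right flank and (b) the longest common suffix of the deleted sequence and
#' the left flank; a deletion is called microhomology-mediated when the
#' score is at least `min_len` (conventionally 2).
#'
#' @param deleted_seq Deleted bases (length >= 1).
#' @param left_flank Reference sequence immediately 5' of the deletion.
#' @param right_flank Reference sequence immediately 3' of the deletion.
#' @return Integer microhomology length.
#' @export
microhomology_length <- function(deleted_seq, left_flank, right_flank) {
  d <- toupper(deleted_seq)
  if (is.na(d) || nchar(d) == 0) stop("deleted_seq must be non-empty")
  lf <- toupper(left_flank); rf <- toupper(right_flank)
  db <- strsplit(d, "")[[1]]
  # common prefix with right flank
  rb <- strsplit(rf, "")[[1]]
  k_right <- 0L
  n <- min(length(db), length(rb))
  while (k_right < n && db[k_right + 1L] == rb[k_right + 1L]) {
    k_right <- k_right + 1L
  }
  # common suffix with left flank
  lb <- strsplit(lf, "")[[1]]
  k_left <- 0L
  n <- min(length(db), length(lb))
  while (k_left < n &&
         db[length(db) - k_left] == lb[length(lb) - k_left]) {
    k_left <- k_left + 1L
  }
  max(k_right, k_left)
}

#' Has a deletion >= min_len of junction microhomology?
#' @inheritParams microhomology_length
#' @param min_len Minimum length to call microhomology (default 2).
#' @return Logical.
#' @export
has_microhomology <- function(deleted_seq, left_flank, right_flank,
                              min_len = 2L) {
  microhomology_length(deleted_seq, left_flank, right_flank) >= min_len
}

#' Detect multisite (clustered) mutation events in one animal
#'
#' Ionizing radiation produces clustered lesions: several SNVs/indels made
#' by one event, close together and carried by the same clone. Variants on
#' the same chromosome are single-linkage clustered with linkage when both
#' the genomic distance is at most `window_bp` and the BM VAFs agree within
#' `vaf_tol` (absolute). Clusters of size >= 2 become one MULTISITE event;
#' their members are removed from the SNV/DEL tallies downstream.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `vaf_BM` (one
#'   animal's variants).
#' @param window_bp Maximum linkage distance in bp (default 100).
#' @param vaf_tol Maximum absolute BM VAF difference for linkage
#'   (default 0.05).
#' @return Integer vector of cluster ids aligned with the rows of
#'   `variants`; singletons keep their own id. Attribute `multisite` is a
#'   logical vector marking members of clusters of size >= 2.
#' @export
detect_multisite <- function(variants, window_bp = 100L, vaf_tol = 0.05) {
  n <- nrow(variants)
  if (is.null(n) || n == 0) {
    return(structure(integer(0), multisite = logical(0)))
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (variants$chrom[i] != variants$chrom[j]) next
      if (abs(variants$pos[i] - variants$pos[j]) > window_bp) next
      vi <- variants$vaf_BM[i]; vj <- variants$vaf_BM[j]
      if (is.na(vi) || is.na(vj) || abs(vi - vj) > vaf_tol) next
      parent[find(i)] <- find(j)
    }
  }
  cl <- vapply(seq_len(n), find, 1L)
  cl <- match(cl, unique(cl))
  sizes <- table(cl)
  structure(cl, multisite = as.vector(sizes[as.character(cl)] >= 2))
}

#' Summarize the mutation spectrum of CH-associated non-mosaic variants
#'
#' Clusters each animal's variants into multisite events, then tallies per
#' animal and in total: deletions, SNVs and multisite events; the
#' six-class substitution histogram over non-multisite SNVs; the deletion
#' length histogram in bins 1-3, 4, 5-31 and >31 nt; and, when deletion
#' contexts are provided, the number of deletions with junction
#' microhomology of at least 2 nt.
#'
#' @param profiles Classified profile table; only rows with
#'   `class_label == "CH_NONMOSAIC"` are summarized (the scope in which CH
#'   spectra are usually reported). Optional context columns `deleted_seq`,
#'   `left_flank`, `right_flank` enable the microhomology tally.
#' @param window_bp,vaf_tol Passed to [detect_multisite()].
#' @return Object of class `spectrum_summary`: `per_animal` data.frame with
#'   DEL/SNV/MULTISITE/COMPLEX counts, `substitutions` named vector,
#'   `deletion_lengths` table over the four bins, `n_microhomology`, and
#'   `totals`.
#' @export
spectrum_summary <- function(profiles, window_bp = 100L, vaf_tol = 0.05) {
  p <- profiles[profiles$class_label == "CH_NONMOSAIC", , drop = FALSE]
  sub_classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  len_bins <- c("1-3", "4", "5-31", ">31")
  empty_subs <- stats::setNames(integer(6), sub_classes)
  empty_lens <- stats::setNames(integer(4), len_bins)
  if (nrow(p) == 0) {
    per <- data.frame(animal_id = character(0), DEL = integer(0),
                      SNV = integer(0), MULTISITE = integer(0),
                      COMPLEX = integer(0))
    return(structure(list(per_animal = per, substitutions = empty_subs,
                          deletion_lengths = empty_lens,
                          n_microhomology = 0L,
                          totals = c(DEL = 0L, SNV = 0L, MULTISITE = 0L,
                                     COMPLEX = 0L)),
                     class = "spectrum_summary"))
  }
  p$variant_type <- variant_type(p$ref, p$alt)
  has_ctx <- all(c("deleted_seq", "left_flank", "right_flank") %in% names(p))

  animals <- unique(p$animal_id)
  per <- data.frame(animal_id = animals, DEL = 0L, SNV = 0L,
                    MULTISITE = 0L, COMPLEX = 0L, stringsAsFactors = FALSE)
  subs <- empty_subs
  lens <- empty_lens
  n_mh <- 0L
  for (a in animals) {
    pa <- p[p$animal_id == a, , drop = FALSE]
    cl <- detect_multisite(pa, window_bp = window_bp, vaf_tol = vaf_tol)
    is_ms <- attr(cl, "multisite")
    i <- match(a, per$animal_id)
    per$MULTISITE[i] <- length(unique(cl[is_ms]))
    single <- pa[!is_ms, , drop = FALSE]
    per$DEL[i] <- sum(single$variant_type == "DEL")
    per$SNV[i] <- sum(single$variant_type == "SNV")
    per$COMPLEX[i] <- sum(single$variant_type == "COMPLEX")
    if (per$COMPLEX[i] > 0) {
      message(per$COMPLEX[i], " complex substitution(s) in animal ", a,
              " excluded from spectrum histograms")
    }
    snv <- single[single$variant_type == "SNV", , drop = FALSE]
    if (nrow(snv) > 0) {
      sc <- table(factor(substitution_class(snv$ref, snv$alt),
                         levels = sub_classes))
      subs <- subs + as.integer(sc)
    }
    del <- single[single$variant_type == "DEL", , drop = FALSE]
    if (nrow(del) > 0) {
      d <- deletion_length(del$ref, del$alt)
      lens <- lens + as.integer(table(cut(d, c(0, 3, 4, 31, Inf),
                                          labels = len_bins)))
      if (has_ctx) {
        for (r in seq_len(nrow(del))) {
          if (!is.na(del$deleted_seq[r]) && nzchar(del$deleted_seq[r])) {
            n_mh <- n_mh + has_microhomology(del$deleted_seq[r],
                                             del$left_flank[r],
                                             del$right_flank[r])
          }
        }
      }
    }
  }
  names(subs) <- sub_classes
  names(lens) <- len_bins
  structure(
    list(per_animal = per, substitutions = subs, deletion_lengths = lens,
         n_microhomology = as.integer(n_mh),
         totals = c(DEL = sum(per$DEL), SNV = sum(per$SNV),
                    MULTISITE = sum(per$MULTISITE),
                    COMPLEX = sum(per$COMPLEX))),
    class = "spectrum_summary"
  )
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat("Mutation spectrum (CH-associated non-mosaic variants)\n")
  cat(sprintf("  totals: %d deletions, %d SNVs, %d multisite events\n",
              x$totals[["DEL"]], x$totals[["SNV"]], x$totals[["MULTISITE"]]))
  cat("  substitution classes:\n")
  print(x$substitutions)
  cat("  deletion lengths (nt):\n")
  print(x$deletion_lengths)
  cat("  deletions with >=2 nt junction microhomology:",
      x$n_microhomology, "\n")
  invisible(x)
}
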