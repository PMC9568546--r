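# Shared data structures and readers/writers.
#
# Variant observations are kept as plain data.frames (one row per
# sample x variant); variant profiles are wide per-animal tables with one
# vaf_<tissue>/depth_<tissue> column pair per tissue; colony genotypes are a
# small S3 container holding VAF and depth matrices.

## ---- tissue vocabulary -----------------------------------------------------

#' Tissue vocabulary
#'
#' The closed set of tissue and sorted-fraction labels the classifier knows
#' about. `BM`, `spleen` and `thymus` plus the four sorted blood fractions
#' (`T`, `B`, `GRAN`, `ERY`) are hematopoietic; `tail`, `brain`, `testis` and
#' `thyroid` form the default non-hematopoietic mosaicism reference; `kidney`
#' and `liver` are non-hematopoietic but blood-filtering, so they are excluded
#' from the mosaicism reference by default.
#'
#' @return Named list with character vectors `hematopoietic`,
#'   `nh_reference`, `nh_other` and `all`.
#' @export
tissue_vocabulary <- function() {
  hem <- c("BM", "spleen", "thymus", "T", "B", "GRAN", "ERY")
  nh_ref <- c("tail", "brain", "testis", "thyroid")
  nh_other <- c("kidney", "liver")
  list(
    hematopoietic = hem,
    nh_reference = nh_ref,
    nh_other = nh_other,
    all = c(hem, nh_ref, nh_other)
  )
}

# case-insensitive alias map -> canonical label
.tissue_aliases <- c(
  bm = "BM", bonemarrow = "BM", bone_marrow = "BM", marrow = "BM",
  spleen = "spleen", spl = "spleen",
  thymus = "thymus", thym = "thymus",
  t = "T", tcell = "T", t_cell = "T", cd3 = "T",
  b = "B", bcell = "B", b_cell = "B", cd19 = "B",
  gran = "GRAN", granulocyte = "GRAN", gr1 = "GRAN",
  ery = "ERY", erythroid = "ERY", ter119 = "ERY",
  tail = "tail",
  brain = "brain", br = "brain",
  testis = "testis", testes = "testis", tes = "testis",
  thyroid = "thyroid", thyr = "thyroid", thyroid_gland = "thyroid",
  kidney = "kidney", kidneys = "kidney", kid = "kidney",
  liver = "liver", liv = "liver"
)

#' Normalize tissue labels to the canonical vocabulary
#'
#' Matching is case-insensitive and alias-aware (e.g. "testes" -> "testis",
#' "Thym" -> "thymus"). Unknown labels pass through unchanged with a warning,
#' so additional sorted fractions can be carried along.
#'
#' @param x Character vector of tissue labels.
#' @return Character vector of canonical labels.
#' @export
normalize_tissue <- function(x) {
  key <- gsub("[^a-z0-9_]", "", tolower(as.character(x)))
  out <- unname(.tissue_aliases[key])
  unknown <- is.na(out)
  if (any(unknown)) {
    warning("unknown tissue label(s) passed through: ",
            paste(unique(x[unknown]), collapse = ", "))
    out[unknown] <- as.character(x[unknown])
  }
  out
}

## ---- variant observations --------------------------------------------------

#' Construct a validated variant-observation table
#'
#' One row per (animal, tissue, variant). The VAF is always recomputed from
#' `alt_reads / depth`; a stored VAF column, if present, is discarded. Rows
#' with `depth == 0` get `vaf = NA` and `vaf_undefined = TRUE`.
#'
#' @param df data.frame with columns `animal_id`, `tissue`, `chrom`, `pos`,
#'   `ref`, `alt`, `alt_reads`, `depth`.
#' @param normalize_tissues Normalize tissue labels (default TRUE).
#' @return data.frame with the seven input columns plus `vaf` and
#'   `vaf_undefined`.
#' @export
variant_observations <- function(df, normalize_tissues = TRUE) {
  required <- c("animal_id", "tissue", "chrom", "pos", "ref", "alt",
                "alt_reads", "depth")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  out <- df[required]
  out$animal_id <- as.character(out$animal_id)
  out$tissue <- as.character(out$tissue)
  if (normalize_tissues) out$tissue <- normalize_tissue(out$tissue)
  out$chrom <- as.character(out$chrom)
  out$pos <- as.integer(out$pos)
  out$ref <- toupper(as.character(out$ref))
  out$alt <- toupper(as.character(out$alt))
  out$alt_reads <- as.integer(out$alt_reads)
  out$depth <- as.integer(out$depth)

  bad_allele <- !grepl("^[ACGT]+$", out$ref) | !grepl("^[ACGT]+$", out$alt) |
    out$ref == out$alt
  if (any(bad_allele)) {
    stop("invalid ref/alt allele(s) at row(s): ",
         paste(utils::head(which(bad_allele), 5), collapse = ", "))
  }
  if (any(is.na(out$pos) | out$pos < 1)) stop("pos must be a positive integer")
  if (any(is.na(out$alt_reads) | out$alt_reads < 0)) {
    stop("alt_reads must be a non-negative integer")
  }
  bad_depth <- is.na(out$depth) | out$depth < out$alt_reads
  if (any(bad_depth)) {
    warning(sum(bad_depth), " row(s) with depth < alt_reads rejected")
    out <- out[!bad_depth, , drop = FALSE]
  }
  out$vaf <- ifelse(out$depth > 0, out$alt_reads / out$depth, NA_real_)
  out$vaf_undefined <- out$depth == 0
  rownames(out) <- NULL
  out
}

#' Canonical variant key
#'
#' `chrom.pos.ref.alt`, used to address variants across tables and as the
#' stem of colony-matrix column names.
#'
#' @param chrom,pos,ref,alt Vectors of equal length.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, toupper(ref), toupper(alt), sep = ".")
}

#' Split variant keys back into their fields
#'
#' @param key Character vector of `chrom.pos.ref.alt` keys.
#' @return data.frame with columns chrom, pos, ref, alt.
#' @export
parse_variant_key <- function(key) {
  parts <- strsplit(key, ".", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 4L
  if (any(bad)) stop("malformed variant key: ", key[bad][1])
  data.frame(
    chrom = vapply(parts, `[[`, "", 1L),
    pos = as.integer(vapply(parts, `[[`, "", 2L)),
    ref = vapply(parts, `[[`, "", 3L),
    alt = vapply(parts, `[[`, "", 4L),
    stringsAsFactors = FALSE
  )
}

#' Read a variant table (TSV or minimal VCF)
#'
#' TSV: tab-separated with header columns `animal_id`, `tissue`, `chrom`,
#' `pos`, `ref`, `alt`, `alt_reads`, `depth`; `#` lines are comments. VCF: a
#' minimal single-sample v4.2 dialect whose genotype FORMAT carries `AD`
#' (ref,alt allelic depths); `animal_id` and `tissue` are taken from the
#' arguments, or parsed from a sample name of the form `<animal>_<tissue>`.
#'
#' VAFs are always recomputed from counts; any VAF column in the file is
#' ignored. Rows with `depth < alt_reads` are dropped with a warning; a
#' malformed row raises an error naming its line.
#'
#' @param path File path.
#' @param format "tsv" or "vcf".
#' @param animal_id,tissue Sample identity for VCF input (optional for TSV).
#' @return Validated observation data.frame (see [variant_observations()]).
#' @export
read_variant_table <- function(path, format = c("tsv", "vcf"),
                               animal_id = NULL, tissue = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- tryCatch(
      utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                        check.names = FALSE),
      error = function(e) stop("malformed TSV ", path, ": ", conditionMessage(e))
    )
    required <- c("animal_id", "tissue", "chrom", "pos", "ref", "alt",
                  "alt_reads", "depth")
    missing <- setdiff(required, names(df))
    if (length(missing) > 0) {
      stop("TSV header missing column(s): ", paste(missing, collapse = ", "))
    }
    num_bad <- which(is.na(suppressWarnings(as.numeric(df$pos))) |
                       is.na(suppressWarnings(as.numeric(df$alt_reads))) |
                       is.na(suppressWarnings(as.numeric(df$depth))))
    if (length(num_bad) > 0) {
      stop("malformed row at data line ", num_bad[1], " of ", path)
    }
    return(variant_observations(df))
  }
  # minimal VCF dialect: single sample, FORMAT containing AD
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad) || ncol(ad) != 1) {
    stop("VCF must be single-sample with an AD genotype field: ", path)
  }
  sample_name <- colnames(ad)
  if (is.null(animal_id) || is.null(tissue)) {
    parts <- strsplit(sample_name, "_", fixed = TRUE)[[1]]
    if (length(parts) < 2) {
      stop("cannot infer animal/tissue from sample name '", sample_name,
           "'; pass animal_id= and tissue=")
    }
    if (is.null(animal_id)) animal_id <- parts[1]
    if (is.null(tissue)) tissue <- paste(parts[-1], collapse = "_")
  }
  counts <- strsplit(ad[, 1], ",", fixed = TRUE)
  ref_n <- as.integer(vapply(counts, `[[`, "", 1L))
  alt_n <- as.integer(vapply(counts, function(x) if (length(x) >= 2) x[2] else "0", ""))
  variant_observations(data.frame(
    animal_id = animal_id, tissue = tissue,
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    alt_reads = alt_n, depth = ref_n + alt_n,
    stringsAsFactors = FALSE
  ))
}

## ---- variant profiles ------------------------------------------------------

#' Pivot observations into per-animal variant profiles
#'
#' Each profile row is one variant in one animal with its VAF/depth across
#' all tissues (`vaf_<tissue>` / `depth_<tissue>` columns, NA where the
#' tissue was not measured), plus `variant_type` and a `class_label` that
#' starts as `"UNCLASSIFIED"` until [classify_variants()] has run.
#'
#' @param obs Observation data.frame (see [variant_observations()]).
#' @return Profile data.frame.
#' @export
build_profiles <- function(obs) {
  obs <- variant_observations(obs, normalize_tissues = FALSE)
  key <- variant_key(obs$chrom, obs$pos, obs$ref, obs$alt)
  id <- paste(obs$animal_id, key, sep = "|")
  tissues <- unique(obs$tissue)
  first <- !duplicated(id)
  prof <- data.frame(
    animal_id = obs$animal_id[first],
    chrom = obs$chrom[first], pos = obs$pos[first],
    ref = obs$ref[first], alt = obs$alt[first],
    stringsAsFactors = FALSE
  )
  prof$variant_type <- variant_type(prof$ref, prof$alt)
  prof$class_label <- "UNCLASSIFIED"
  rownames(prof) <- id[first]
  for (t in tissues) {
    prof[[paste0("vaf_", t)]] <- NA_real_
    prof[[paste0("depth_", t)]] <- NA_integer_
  }
  for (i in seq_len(nrow(obs))) {
    prof[id[i], paste0("vaf_", obs$tissue[i])] <- obs$vaf[i]
    prof[id[i], paste0("depth_", obs$tissue[i])] <- obs$depth[i]
  }
  rownames(prof) <- NULL
  prof
}

#' Tissues present in a profile table
#' @param profiles Profile data.frame.
#' @return Character vector of tissue labels.
#' @export
profile_tissues <- function(profiles) {
  sub("^vaf_", "", grep("^vaf_", names(profiles), value = TRUE))
}

#' Write variant profiles to TSV
#'
#' Round-trips exactly through [read_variant_profiles()]: numeric fields are
#' written at full precision.
#'
#' @param profiles Profile data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_variant_profiles <- function(profiles, path) {
  df <- profiles
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  for (j in which(num)) df[[j]] <- formatC(df[[j]], format = "g", digits = 17)
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write profiles to ", path)
  invisible(path)
}

#' Read variant profiles written by [write_variant_profiles()]
#' @param path File path.
#' @return Profile data.frame.
#' @export
read_variant_profiles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (nm in c("animal_id", "chrom", "ref", "alt", "variant_type", "class_label")) {
    if (nm %in% names(df)) df[[nm]] <- as.character(df[[nm]])
  }
  if ("pos" %in% names(df)) df$pos <- as.integer(df[["pos"]])
  for (nm in grep("^vaf_", names(df), value = TRUE)) df[[nm]] <- as.numeric(df[[nm]])
  for (nm in grep("^depth_", names(df), value = TRUE)) df[[nm]] <- as.integer(df[[nm]])
  df
}

## ---- colony genotype matrix ------------------------------------------------

#' Construct a colony genotype matrix
#'
#' Colonies grown from single sorted HSC/MPP cells, genotyped at a set of
#' candidate variants. VAF and depth are per (colony, variant); presence
#' calls are filled in by [genotype_colonies()].
#'
#' @param animal_id Animal identifier.
#' @param colonies data.frame with columns `colony_id`, `compartment`
#'   ("HSC" or "MPP").
#' @param vaf,depth Numeric/integer matrices, rows = colonies, columns =
#'   variant keys.
#' @return Object of class `colony_matrix`.
#' @export
colony_matrix <- function(animal_id, colonies, vaf, depth) {
  stopifnot(is.data.frame(colonies),
            all(c("colony_id", "compartment") %in% names(colonies)))
  colonies$colony_id <- as.character(colonies$colony_id)
  colonies$compartment <- as.character(colonies$compartment)
  if (anyDuplicated(colonies$colony_id)) {
    stop("duplicated colony_id: ",
         colonies$colony_id[duplicated(colonies$colony_id)][1])
  }
  bad <- !colonies$compartment %in% c("HSC", "MPP")
  if (any(bad)) {
    stop("unknown compartment label: ", colonies$compartment[bad][1])
  }
  vaf <- as.matrix(vaf)
  depth <- as.matrix(depth)
  storage.mode(vaf) <- "double"
  storage.mode(depth) <- "integer"
  stopifnot(nrow(vaf) == nrow(colonies), all(dim(vaf) == dim(depth)))
  rownames(vaf) <- rownames(depth) <- colonies$colony_id
  structure(
    list(animal_id = as.character(animal_id), colonies = colonies,
         variants = colnames(vaf), vaf = vaf, depth = depth, calls = NULL),
    class = "colony_matrix"
  )
}

#' @export
print.colony_matrix <- function(x, ...) {
  cat("Colony genotype matrix: animal", x$animal_id, "-",
      nrow(x$colonies), "colonies x", length(x$variants), "variants\n")
  cat("  compartments:",
      paste(sprintf("%s=%d", names(table(x$colonies$compartment)),
                    table(x$colonies$compartment)), collapse = ", "), "\n")
  if (!is.null(x$calls)) {
    tab <- table(factor(x$calls, c("PRESENT", "ABSENT", "AMBIGUOUS")))
    cat("  calls:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  } else {
    cat("  calls: not yet genotyped\n")
  }
  invisible(x)
}

#' @export
dim.colony_matrix <- function(x) dim(x$vaf)

#' Read a colony genotype CSV
#'
#' Expected columns: `colony_id`, `compartment`, then `<variantkey>_vaf`
#' and `<variantkey>_depth` pairs. Missing cells stay missing (NA).
#'
#' @param path CSV path.
#' @param animal_id Animal the colonies came from (default: file stem).
#' @return A [colony_matrix()].
#' @export
read_colony_matrix <- function(path, animal_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(animal_id)) animal_id <- sub("\\.[^.]+$", "", basename(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("colony_id", "compartment") %in% names(df)))
  vaf_cols <- grep("_vaf$", names(df), value = TRUE)
  keys <- sub("_vaf$", "", vaf_cols)
  depth_cols <- paste0(keys, "_depth")
  missing <- setdiff(depth_cols, names(df))
  if (length(missing) > 0) {
    stop("colony CSV missing depth column(s): ", paste(missing, collapse = ", "))
  }
  n <- nrow(df)
  vaf <- matrix(NA_real_, n, length(keys), dimnames = list(NULL, keys))
  depth <- matrix(NA_integer_, n, length(keys), dimnames = list(NULL, keys))
  for (i in seq_along(keys)) {
    vaf[, i] <- as.numeric(df[[vaf_cols[i]]])
    depth[, i] <- as.integer(df[[depth_cols[i]]])
  }
  colony_matrix(animal_id, df[c("colony_id", "compartment")], vaf, depth)
}

#' Write a colony genotype matrix as CSV
#' @param mat A [colony_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_colony_matrix <- function(mat, path) {
  df <- mat$colonies
  for (k in mat$variants) {
    df[[paste0(k, "_vaf")]] <- mat$vaf[, k]
    df[[paste0(k, "_depth")]] <- mat$depth[, k]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

## ---- animal covariates & config --------------------------------------------

#' Construct the per-animal covariate table
#'
#' @param df data.frame with columns `animal_id`, `group` ("IRRADIATED" or
#'   "CONTROL"), `dose_Gy`, `sex` ("M"/"F"), `age_months`, and optional
#'   blood indices `lym_pct`, `mye_pct`, `rdw`.
#' @return Validated data.frame.
#' @export
animal_records <- function(df) {
  required <- c("animal_id", "group", "dose_Gy", "sex", "age_months")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing animal column(s): ", paste(missing, collapse = ", "))
  }
  df$animal_id <- as.character(df$animal_id)
  df$group <- toupper(as.character(df$group))
  stopifnot(all(df$group %in% c("IRRADIATED", "CONTROL")))
  df$dose_Gy <- as.numeric(df$dose_Gy)
  df$sex <- toupper(as.character(df$sex))
  stopifnot(all(df$sex %in% c("M", "F")))
  df$age_months <- as.numeric(df$age_months)
  bad <- xor(df$dose_Gy == 0, df$group == "CONTROL")
  if (any(bad)) stop("dose_Gy must be 0 exactly for CONTROL animals")
  if (any(df$age_months <= 0)) stop("age_months must be positive")
  if (anyDuplicated(df$animal_id)) stop("duplicated animal_id")
  df
}

#' Read analysis thresholds from a YAML config file
#'
#' Recognised keys mirror the arguments of [filter_config()],
#' [genotype_config()] and [detect_multisite()]; unknown keys are kept and
#' passed through, so callers can override any of them.
#'
#' @param path YAML file.
#' @return Named list of settings.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  cfg
}
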