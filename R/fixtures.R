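# Deterministic reference fixtures.
#
# These encode the published per-mouse mutation counts of a 3-Gy
# whole-body-irradiation mouse cohort (12 irradiated + 6 control males,
# sequenced at 14-19.5 months of age) and the clonal architecture observed
# in the two colony-profiled animals (mice 33 and 85). They are built
# entirely in code, with deterministic variant coordinates and tissue
# patterns shaped so that the pipeline's own filters and classifiers
# reproduce the printed counts end to end.

# per-mouse recurrent-mutation counts: class totals and VAF>0.1 sub-counts
.table1 <- function() {
  irr <- data.frame(
    animal_id = c("11", "12", "21", "22", "23", "31", "32", "33", "85",
                  "91", "92", "94"),
    age_months = c(19.5, 19.5, 19.1, 19.1, 19.1, 19.1, 19.1, 19.1, 16,
                   14.7, 14.7, 14.7),
    mosaic_not_ch = c(1, 0, 1, 0, 1, 0, 1, 0, 0, 0, 0, 0),
    mosaic_not_ch_high = c(1, 0, 0, 0, 1, 0, 1, 0, 0, 0, 0, 0),
    ch_mosaic = c(0, 2, 0, 0, 0, 0, 0, 1, 0, 0, 1, 1),
    ch_mosaic_high = c(0, 2, 0, 0, 0, 0, 0, 1, 0, 0, 1, 1),
    ch_nonmosaic = c(2, 5, 2, 5, 0, 3, 5, 2, 10, 8, 15, 8),
    ch_nonmosaic_high = c(1, 5, 0, 4, 0, 0, 4, 2, 3, 1, 9, 2),
    group = "IRRADIATED", stringsAsFactors = FALSE
  )
  ctl <- data.frame(
    animal_id = c("51", "52", "53", "61", "71", "73"),
    age_months = c(19.1, 19.1, 19.4, 19.2, 17.2, 18.5),
    mosaic_not_ch = c(1, 0, 1, 0, 3, 0),
    mosaic_not_ch_high = c(1, 0, 1, 0, 3, 0),
    ch_mosaic = 0, ch_mosaic_high = 0,
    ch_nonmosaic = 0, ch_nonmosaic_high = 0,
    group = "CONTROL", stringsAsFactors = FALSE
  )
  rbind(irr, ctl)
}

# per-mouse CH-associated non-mosaic event counts by mutation type
.table2 <- function() {
  data.frame(
    animal_id = c("11", "12", "21", "22", "23", "31", "32", "33", "85",
                  "91", "92", "94"),
    deletion = c(2, 2, 2, 1, 0, 2, 3, 1, 6, 3, 9, 4),
    snv = c(0, 3, 0, 4, 0, 1, 2, 1, 3, 4, 6, 3),
    multisite = c(0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 0, 1),
    stringsAsFactors = FALSE
  )
}

# deterministic non-T tract (letters from ACG only), so that all-T flanks
# share no bases with it unless microhomology is planted explicitly
.tract <- function(len) {
  paste(rep_len(c("A", "C", "G"), len), collapse = "")
}

# deletion alleles + flank context; mh = planted junction microhomology
.fixture_del <- function(len, mh = 0L) {
  deleted <- .tract(len)
  left <- strrep("T", 20)
  right <- strrep("T", 20)
  if (mh >= 2) {
    right <- paste0(substr(deleted, 1, mh), substr(right, mh + 1, 20))
  }
  list(ref = paste0("T", deleted), alt = "T", deleted_seq = deleted,
       left_flank = left, right_flank = right)
}

.fixture_snv_cycle <- function() {
  # C>T-dominant cycle used for the 27 non-mosaic SNVs
  c("C>T", "C>T", "T>C", "C>T", "C>A", "C>T", "T>A", "C>T", "C>G",
    "C>T", "T>C", "C>T", "T>G", "C>T", "C>A", "C>T", "T>C", "C>T",
    "C>G", "C>T", "T>A", "C>T", "T>C", "C>T", "C>A", "C>T", "C>T")
}

#' Reference fixtures: published cohort counts and colony architectures
#'
#' Builds, deterministically and entirely in code:
#' \itemize{
#'   \item `cohort`: `profiles` + `animals` for 12 irradiated and 6 control
#'     mice whose per-mouse mutation counts, classes, BM VAF>0.1
#'     sub-counts, mutation types, deletion lengths (12 of 1-3 nt, 23 of
#'     5-31 nt, 8 with >=2 nt junction microhomology) and multisite events
#'     reproduce the published count tables when run through
#'     [filter_candidates()], [classify_variants()], [summarize_cohort()]
#'     and [spectrum_summary()].
#'   \item `mouse33`: colony matrix (20 HSC + 20 MPP) and bulk BM VAFs for
#'     the nested-clone animal: an embryonic Nell2 SNV (BM VAF 0.29)
#'     containing two mutually exclusive CH clones, an Eif3I SNV (0.14, in
#'     HSC and MPP colonies) and a 1700122O11Rik deletion (0.12, MPP only).
#'   \item `mouse85`: colony matrix (26 HSC + 26 MPP) and BM VAFs for the
#'     animal with four mutually exclusive clones carrying 2 + 3 + 4 + 1
#'     mutations, doubled VAFs summing to 0.80 of BM nuclear cells.
#'   \item `table1`, `table2`: the raw per-mouse count tables.
#' }
#'
#' @return Named list as described above.
#' @export
ch_fixtures <- function() {
  t1 <- .table1()
  t2 <- .table2()
  tissues <- c("BM", "spleen", "tail", "brain", "testis")
  depth <- 30000L
  snv_cycle <- .fixture_snv_cycle()
  short_lens <- rep(1:3, 4)           # 12 deletions of 1-3 nt
  long_lens <- 5:27                   # 23 deletions of 5-31 nt
  mh_plan <- c(rep(2L, 8), rep(0L, 15))  # 8 of the long ones with MH >= 2

  rows <- list()
  ev <- 0L; n_del <- 0L; n_snv <- 0L
  add_row <- function(aid, chrom, pos, ref, alt, bm_vaf, pattern, ctx) {
    v <- stats::setNames(numeric(length(tissues)), tissues)
    if (pattern == "mosaic") v[] <- bm_vaf
    if (pattern == "ch_mosaic") {
      v[c("BM", "spleen")] <- bm_vaf
      v[c("tail", "brain", "testis")] <- 0.01
    }
    if (pattern == "ch_nonmosaic") v[c("BM", "spleen")] <- bm_vaf
    row <- data.frame(animal_id = aid, chrom = chrom, pos = pos,
                      ref = ref, alt = alt,
                      deleted_seq = ctx$deleted_seq,
                      left_flank = ctx$left_flank,
                      right_flank = ctx$right_flank,
                      stringsAsFactors = FALSE)
    for (tc in tissues) {
      row[[paste0("vaf_", tc)]] <- v[[tc]]
      row[[paste0("depth_", tc)]] <- depth
    }
    rows[[length(rows) + 1L]] <<- row
  }
  no_ctx <- list(deleted_seq = NA_character_, left_flank = NA_character_,
                 right_flank = NA_character_)
  next_snv <- function() {
    n_snv <<- n_snv + 1L
    cls <- snv_cycle[((n_snv - 1L) %% length(snv_cycle)) + 1L]
    c(ref = substr(cls, 1, 1), alt = substr(cls, 3, 3))
  }
  next_del <- function() {
    n_del <<- n_del + 1L
    if (n_del <= 12L) .fixture_del(short_lens[n_del])
    else .fixture_del(long_lens[n_del - 12L], mh_plan[n_del - 12L])
  }
  ev_loc <- function() {
    ev <<- ev + 1L
    list(chrom = paste0("chr", ((ev - 1L) %% 19L) + 1L),
         pos = 1000000L + ev * 10000L)
  }

  for (i in seq_len(nrow(t1))) {
    aid <- t1$animal_id[i]
    # embryonic mosaic, not CH (mouse 23's is the one mosaic deletion)
    nm <- t1$mosaic_not_ch[i]; nm_hi <- t1$mosaic_not_ch_high[i]
    for (k in seq_len(nm)) {
      loc <- ev_loc()
      bm <- if (k <= nm_hi) 0.2 else 0.05
      if (aid == "23" && k == 1L) {
        d <- .fixture_del(3L)
        add_row(aid, loc$chrom, loc$pos, d$ref, d$alt, bm, "mosaic", d)
      } else {
        s <- next_snv()
        add_row(aid, loc$chrom, loc$pos, s[["ref"]], s[["alt"]], bm,
                "mosaic", no_ctx)
      }
    }
    # CH-associated mosaic (mouse 94's is the other mosaic deletion)
    cm <- t1$ch_mosaic[i]; cm_hi <- t1$ch_mosaic_high[i]
    for (k in seq_len(cm)) {
      loc <- ev_loc()
      bm <- if (k <= cm_hi) 0.2 else 0.05
      if (aid == "94" && k == 1L) {
        d <- .fixture_del(2L)
        add_row(aid, loc$chrom, loc$pos, d$ref, d$alt, bm, "ch_mosaic", d)
      } else {
        s <- next_snv()
        add_row(aid, loc$chrom, loc$pos, s[["ref"]], s[["alt"]], bm,
                "ch_mosaic", no_ctx)
      }
    }
    # CH-associated non-mosaic events, typed per the mutation-type table
    j <- match(aid, t2$animal_id)
    if (!is.na(j)) {
      kinds <- c(rep("DEL", t2$deletion[j]), rep("SNV", t2$snv[j]),
                 rep("MS", t2$multisite[j]))
      n_hi <- t1$ch_nonmosaic_high[i]
      for (k in seq_along(kinds)) {
        loc <- ev_loc()
        bm <- if (k <= n_hi) 0.2 else 0.05
        if (kinds[k] == "DEL") {
          d <- next_del()
          add_row(aid, loc$chrom, loc$pos, d$ref, d$alt, bm,
                  "ch_nonmosaic", d)
        } else if (kinds[k] == "SNV") {
          s <- next_snv()
          add_row(aid, loc$chrom, loc$pos, s[["ref"]], s[["alt"]], bm,
                  "ch_nonmosaic", no_ctx)
        } else {
          # one clustered event = two SNVs 30 bp apart at the same VAF
          s1 <- next_snv(); s2 <- next_snv()
          add_row(aid, loc$chrom, loc$pos, s1[["ref"]], s1[["alt"]], bm,
                  "ch_nonmosaic", no_ctx)
          add_row(aid, loc$chrom, loc$pos + 30L, s2[["ref"]], s2[["alt"]],
                  bm, "ch_nonmosaic", no_ctx)
        }
      }
    }
  }
  profiles <- do.call(rbind, rows)
  profiles$variant_type <- variant_type(profiles$ref, profiles$alt)
  profiles$class_label <- "UNCLASSIFIED"
  animals <- data.frame(
    animal_id = t1$animal_id, group = t1$group,
    dose_Gy = ifelse(t1$group == "IRRADIATED", 3, 0),
    sex = "M", age_months = t1$age_months, stringsAsFactors = FALSE
  )

  list(cohort = list(profiles = profiles, animals = animals),
       mouse33 = .mouse33_fixture(), mouse85 = .mouse85_fixture(),
       table1 = t1, table2 = t2)
}

# mouse 33: embryonic Nell2 SNV containing two exclusive CH clones
.mouse33_fixture <- function() {
  keys <- c(Nell2 = "chr15.95432868.A.G",
            Eif3I = "chr15.79076783.C.T",
            Rik_del = "chr17.48036757.GAT.G")
  ids <- c(sprintf("H%02d", 1:20), sprintf("P%02d", 1:20))
  colonies <- data.frame(colony_id = ids,
                         compartment = rep(c("HSC", "MPP"), each = 20),
                         stringsAsFactors = FALSE)
  present <- list(
    Nell2 = c(sprintf("H%02d", 1:13), sprintf("P%02d", 1:9)),
    Eif3I = c(sprintf("H%02d", 1:3), sprintf("P%02d", 1:3)),
    Rik_del = sprintf("P%02d", 4:8)
  )
  vaf <- matrix(0, 40, 3, dimnames = list(ids, unname(keys)))
  for (nm in names(present)) vaf[present[[nm]], keys[[nm]]] <- 0.5
  depth <- matrix(1000L, 40, 3, dimnames = dimnames(vaf))
  bm_vaf <- stats::setNames(c(0.29, 0.14, 0.12), unname(keys))
  lineage_vaf <- stats::setNames(c(0.15, 0.24, 0.34, 0.30),
                                 c("T", "B", "GRAN", "ERY"))
  list(matrix = colony_matrix("33", colonies, vaf, depth),
       bm_vaf = bm_vaf, keys = keys, nell2_lineage_vaf = lineage_vaf)
}

# mouse 85: four mutually exclusive clones, doubled VAFs summing to 0.80
.mouse85_fixture <- function() {
  groups <- list(
    A = c(Fcgr2b = "chr1.170961340.C.T", Rik6430 = "chr8.36512373.G.A"),
    B = c(Slc39a9 = "chr12.80649329.T.C", Stam2 = "chr2.52720990.C.A",
          Snx33 = "chr9.56918333.TACGAC.T"),
    C = c(Susd3 = "chr13.49239072.C.T", Gkap1 = "chr13.58259599.TAC.T",
          Olfr736 = "chr14.50392765.G.A", Pkd1 = "chr17.24594785.C.G"),
    D = c(Zfp738 = "chr13.67673456.TACGA.T")
  )
  group_vaf <- c(A = 0.16, B = 0.10, C = 0.09, D = 0.05)
  ids <- c(sprintf("H%02d", 1:26), sprintf("P%02d", 1:26))
  colonies <- data.frame(colony_id = ids,
                         compartment = rep(c("HSC", "MPP"), each = 26),
                         stringsAsFactors = FALSE)
  support <- list(
    A = c(sprintf("H%02d", 1:8), sprintf("P%02d", 1:6)),  # HSC + MPP
    B = "H09",                                            # one HSC colony
    C = sprintf("P%02d", 7:12),                           # MPP only
    D = sprintf("P%02d", 13:15)                           # MPP only
  )
  keys <- unname(unlist(groups))
  vaf <- matrix(0, 52, length(keys), dimnames = list(ids, keys))
  for (g in names(groups)) vaf[support[[g]], groups[[g]]] <- 0.5
  depth <- matrix(1000L, 52, length(keys), dimnames = dimnames(vaf))
  bm_vaf <- stats::setNames(
    rep(group_vaf, lengths(groups)), keys)
  list(matrix = colony_matrix("85", colonies, vaf, depth),
       bm_vaf = bm_vaf, groups = groups, group_vaf = group_vaf)
}
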