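# helper: one-row profile with given tissue VAFs at fixed depth
prof_row <- function(animal, vafs, depth = 30000L, pos = 1000L) {
  row <- data.frame(animal_id = animal, chrom = "chr1", pos = pos,
                    ref = "C", alt = "T", variant_type = "SNV",
                    class_label = "UNCLASSIFIED", stringsAsFactors = FALSE)
  for (tc in names(vafs)) {
    row[[paste0("vaf_", tc)]] <- vafs[[tc]]
    row[[paste0("depth_", tc)]] <- depth
  }
  row
}

test_that("filter boundaries are inclusive and rejection reasons take precedence", {
  rows <- rbind(
    prof_row("a1", c(BM = 0.40, tail = 0), pos = 1000),   # germline band
    prof_row("a1", c(BM = 0.02, tail = 0), pos = 2000),   # lower boundary
    prof_row("a1", c(BM = 0.35, tail = 0), pos = 3000),   # upper boundary
    prof_row("a1", c(BM = 0.01, tail = 0), pos = 4000),   # below band
    prof_row("a1", c(BM = 5 / 30000, tail = 0), pos = 5000),  # 5 alt reads
    prof_row("a1", c(BM = 6 / 30000, tail = 0), pos = 6000)   # 6 alt reads
  )
  # 6/30000 = 2e-4 is below vaf_min; to isolate the read-support filter use
  # a shallow depth where 5-6 reads sit inside the VAF band
  rows$depth_BM[5:6] <- 100L
  rows$vaf_BM[5] <- 0.05; rows$depth_BM[5] <- 100L   # 5 reads at depth 100
  rows$vaf_BM[6] <- 0.06; rows$depth_BM[6] <- 100L   # 6 reads
  out <- filter_candidates(rows, n_animals = 18)
  expect_equal(out$reject_reason[1], "germline_vaf")
  expect_true(out$survives[2])   # VAF exactly 0.02 survives
  expect_true(out$survives[3])   # VAF exactly 0.35 survives
  expect_equal(out$reject_reason[4], "low_vaf")
  expect_equal(out$reject_reason[5], "read_support")  # 5 reads rejected
  expect_true(out$survives[6])                        # 6 reads survive
})

test_that("recurrence filter drops variants detected in most animals", {
  # same variant in 17 of 18 animals, plus a private variant in one
  rows <- do.call(rbind, lapply(sprintf("a%02d", 1:17), function(a)
    prof_row(a, c(BM = 0.05, tail = 0), pos = 1000)))
  rows <- rbind(rows, prof_row("a18", c(BM = 0.05, tail = 0), pos = 9000))
  out <- filter_candidates(rows, n_animals = 18)
  shared <- out$pos == 1000
  expect_true(all(out$reject_reason[shared] == "recurrence"))  # 17/18 > 0.5
  expect_true(out$survives[!shared])
  expect_error(filter_candidates(rows[0, ]), "empty cohort")
})

test_that("filter is monotone: shrinking the VAF band never adds survivors", {
  set.seed(1)
  rows <- do.call(rbind, lapply(1:60, function(i)
    prof_row("a1", c(BM = runif(1, 0, 0.5), tail = 0), pos = i * 1000)))
  wide <- filter_candidates(rows, filter_config(vaf_min = 0.02, vaf_max = 0.35),
                            n_animals = 100)
  narrow <- filter_candidates(rows, filter_config(vaf_min = 0.05, vaf_max = 0.2),
                              n_animals = 100)
  expect_true(all(which(narrow$survives) %in% which(wide$survives)))
})

test_that("tissue-distribution classification matches its defining cases", {
  cfg <- filter_config()
  # expanded in BM, detected at low VAF in embryonic-lineage tissues
  expect_equal(classify_profile(
    c(BM = 0.29, brain = 0.012, testis = 0.015, thyroid = 0.012), cfg),
    "CH_MOSAIC")
  # hematopoietic only
  expect_equal(classify_profile(
    c(BM = 0.14, brain = 0, testis = 0, tail = 0.001), cfg),
    "CH_NONMOSAIC")
  # similar VAFs everywhere: embryonic mosaic without CH
  expect_equal(classify_profile(
    c(BM = 0.10, tail = 0.10, brain = 0.10), cfg),
    "MOSAIC_NOT_CH")
  # ratio inside the ambiguous band between similar and expanded
  expect_equal(classify_profile(c(BM = 0.08, brain = 0.02), cfg),
               "UNCLASSIFIED")
  # no non-hematopoietic reference tissue measured
  expect_equal(classify_profile(c(BM = 0.2, spleen = 0.2), cfg),
               "UNCLASSIFIED")
  expect_error(classify_profile(c(tail = 0.1), cfg), "no BM")
})

test_that("every survivor receives exactly one of the four labels", {
  sim <- simulate_cohort(sim_config(seed = 5))
  p <- classify_variants(filter_candidates(sim$profiles))
  surv <- p[p$survives, ]
  expect_true(all(surv$class_label %in%
                    c("MOSAIC_NOT_CH", "CH_MOSAIC", "CH_NONMOSAIC",
                      "UNCLASSIFIED")))
  counts <- table(surv$class_label)
  expect_equal(sum(counts), nrow(surv))
})

test_that("clone fraction doubles the VAF and rejects super-heterozygous input", {
  expect_equal(clone_fraction(0.29), 0.58)
  expect_equal(clone_fraction(0.1), 0.2)
  expect_equal(clone_fraction(0), 0)
  expect_equal(clone_fraction(0.5), 1)
  expect_error(clone_fraction(0.51), "0.5")
})

test_that("cohort summary reproduces per-group means and flags unknown animals", {
  fx <- ch_fixtures()
  p <- classify_variants(filter_candidates(fx$cohort$profiles))
  s <- summarize_cohort(p, fx$cohort$animals)
  gm <- s$group_means
  irr <- gm[gm$group == "IRRADIATED", ]
  ctl <- gm[gm$group == "CONTROL", ]
  expect_equal(s$totals[["CH_NONMOSAIC"]], 65)
  expect_equal(irr$CH_NONMOSAIC, 65 / 12)
  expect_equal(irr$CH_ASSOC, 70 / 12)
  expect_equal(irr$MOSAIC_NOT_CH, 4 / 12)
  expect_equal(irr$CH_MOSAIC, 5 / 12)
  expect_equal(ctl$MOSAIC_NOT_CH, 5 / 6)
  expect_equal(s$n_with_ch, 11)
  expect_equal(s$n_with_ch_high, 9)
  # sub-counts can never exceed the full counts
  per <- s$per_animal
  for (cl in c("MOSAIC_NOT_CH", "CH_MOSAIC", "CH_NONMOSAIC")) {
    expect_true(all(per[[paste0(cl, "_high")]] <= per[[cl]]))
  }
  bad <- p
  bad$animal_id[1] <- "ghost"
  expect_error(summarize_cohort(bad, fx$cohort$animals), "unknown animal")
  # empty cohort: all-zero counts
  s0 <- summarize_cohort(p[0, ], fx$cohort$animals)
  expect_true(all(s0$per_animal$CH_NONMOSAIC == 0))
  expect_equal(s0$n_with_ch, 0)
})
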