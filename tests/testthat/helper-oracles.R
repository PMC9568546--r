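# Independent oracles and small generators shared across test files.

# brute-force microhomology: scan every overlap length at both junctions
mh_oracle <- function(deleted, left, right) {
  d <- nchar(deleted)
  best <- 0L
  for (k in seq_len(min(d, nchar(right)))) {
    if (substr(deleted, 1, k) == substr(right, 1, k)) best <- max(best, k)
  }
  for (k in seq_len(min(d, nchar(left)))) {
    if (substr(deleted, d - k + 1, d) ==
        substr(left, nchar(left) - k + 1, nchar(left))) best <- max(best, k)
  }
  best
}

# brute-force conditional-binomial p-values by full pmf enumeration,
# using explicit binomial coefficients rather than pbinom/dbinom tails
rate_test_oracle <- function(y1, n1, y0, n0) {
  T <- y1 + y0
  if (T == 0) return(list(one = 1, two = 1))
  p <- n1 / (n1 + n0)
  k <- 0:T
  pmf <- exp(lchoose(T, k) + k * log(p) + (T - k) * log1p(-p))
  list(one = sum(pmf[k >= y1]),
       two = min(1, sum(pmf[pmf <= pmf[y1 + 1] * (1 + 1e-07)])))
}

# weighted normal equations, the textbook closed form
wls_oracle <- function(X, y, w) {
  W <- diag(w)
  solve(t(X) %*% W %*% X, t(X) %*% W %*% y)[, 1]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random one-level clone forest for recovery tests: k top-level clones
# sharing a 0.8 delivered fraction, some with one nested child; every
# clone gets its own mutations
random_clone_tree <- function() {
  k_top <- sample(1:4, 1)
  top_frac <- rep(0.8 / k_top, k_top)
  fractions <- numeric(0)
  parent <- integer(0)
  for (i in seq_len(k_top)) {
    fractions <- c(fractions, top_frac[i])
    parent <- c(parent, NA_integer_)
    if (runif(1) < 0.5 && top_frac[i] >= 0.1) {
      fractions <- c(fractions, top_frac[i] / 2)
      parent <- c(parent, length(fractions) - 1L)
    }
  }
  k <- length(fractions)
  muts <- lapply(seq_len(k), function(c) {
    n <- sample(1:3, 1)
    sprintf("chr%d.%d.A.G", c, seq_len(n) * 1000L + c)
  })
  list(fractions = fractions, parent = parent, mutations = muts)
}

# run the filter+classify pipeline on a simulated cohort and join truth
classify_sim <- function(sim, config = filter_config()) {
  p <- filter_candidates(sim$profiles, config)
  p <- classify_variants(p, config)
  tr <- sim$truth$mutations
  m <- match(
    paste(p$animal_id, variant_key(p$chrom, p$pos, p$ref, p$alt)),
    paste(tr$animal_id, variant_key(tr$chrom, tr$pos, tr$ref, tr$alt)))
  p$true_class <- tr$true_class[m]
  p$event_id <- tr$event_id[m]
  p
}
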