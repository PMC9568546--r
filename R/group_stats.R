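# Group statistics: exact two-group Poisson rate comparison via the
# conditional binomial reduction, weighted least squares with age/sex
# adjustment, and the Breusch-Pagan heteroskedasticity check.

#' Exact two-group Poisson rate test (conditional binomial)
#'
#' Compares per-animal mutation rates between an exposed group (count `y1`
#' over `n1` animals) and a reference group (`y0` over `n0`). Under equal
#' rates, conditional on the total T = y1 + y0, y1 is Binomial(T,
#' n1/(n1+n0)); this is the exact-Poisson-regression test in the two-group
#' equal-offset design. The one-sided p is the upper tail P(X >= y1); the
#' two-sided p sums P(X = k) over all outcomes no more likely than the
#' observed one (minimum-likelihood method).
#'
#' @param y1,y0 Event counts in each group (non-negative integers).
#' @param n1,n0 Group sizes / exposures (positive).
#' @param sided "two" (default) or "one".
#' @return Object of class `rate_test` with fields `y1,n1,y0,n0`,
#'   `rate_ratio_mle` (Inf when y0 = 0 and y1 > 0; NA flag when T = 0),
#'   `p_one_sided`, `p_two_sided`, `p_value` (the requested side), and
#'   `method = "conditional-binomial-exact"`.
#' @export
exact_rate_test <- function(y1, n1, y0, n0, sided = c("two", "one")) {
  sided <- match.arg(sided)
  stopifnot(y1 >= 0, y0 >= 0, n1 > 0, n0 > 0)
  T <- y1 + y0
  p1 <- n1 / (n1 + n0)
  if (T == 0) {
    out <- list(y1 = y1, n1 = n1, y0 = y0, n0 = n0,
                rate_ratio_mle = NA_real_, ratio_undefined = TRUE,
                p_one_sided = 1, p_two_sided = 1, p_value = 1,
                sided = sided, method = "conditional-binomial-exact")
    return(structure(out, class = "rate_test"))
  }
  p_one <- stats::pbinom(y1 - 1, T, p1, lower.tail = FALSE)
  pmf <- stats::dbinom(0:T, T, p1)
  # numeric slack so ties at the observed likelihood are included
  p_two <- sum(pmf[pmf <= pmf[y1 + 1] * (1 + 1e-07)])
  p_two <- min(1, p_two)
  ratio <- if (y0 == 0) {
    if (y1 == 0) NA_real_ else Inf
  } else {
    (y1 / n1) / (y0 / n0)
  }
  structure(
    list(y1 = y1, n1 = n1, y0 = y0, n0 = n0,
         rate_ratio_mle = ratio, ratio_undefined = y0 == 0 && y1 == 0,
         p_one_sided = p_one, p_two_sided = p_two,
         p_value = if (sided == "one") p_one else p_two,
         sided = sided, method = "conditional-binomial-exact"),
    class = "rate_test"
  )
}

#' @export
print.rate_test <- function(x, ...) {
  cat("Exact conditional Poisson rate test (", x$method, ")\n", sep = "")
  cat(sprintf("  counts: %d events / %g animals vs %d events / %g animals\n",
              x$y1, x$n1, x$y0, x$n0))
  cat("  rate ratio (MLE):",
      if (isTRUE(x$ratio_undefined)) "undefined (no events)"
      else format(x$rate_ratio_mle, digits = 4), "\n")
  cat(sprintf("  p (one-sided upper) = %.3g; p (two-sided, min-likelihood) = %.3g\n",
              x$p_one_sided, x$p_two_sided))
  invisible(x)
}

#' Weighted least squares with optional feasible two-step weights
#'
#' Linear regression for blood indices (lymphocyte %, myeloid %, RDW)
#' against exposure with age and sex adjustment. When `weights` is NULL and
#' `group_var` names a factor column, weights are estimated in two steps:
#' an unweighted fit first, then weights = inverse of the residual variance
#' within each level of `group_var` (observations from the less variable
#' group count more). Rows with missing outcome values are dropped with a
#' message. A Breusch-Pagan check on the final fit is attached.
#'
#' @param formula Model formula, e.g. `mye_pct ~ group + age_months + sex`.
#' @param data data.frame of covariates and outcome.
#' @param weights Optional positive case weights.
#' @param group_var Column used for two-step variance estimation when
#'   `weights` is NULL (default "group"); set NULL for ordinary least
#'   squares.
#' @return Object of class `wls_fit`: `coefficients` (matrix with estimate,
#'   SE, t, p), `weights`, `fit` (the underlying `lm`), `bp_stat`, `bp_p`,
#'   `n_dropped`.
#' @export
wls_fit <- function(formula, data, weights = NULL, group_var = "group") {
  outcome <- all.vars(formula)[1]
  miss <- is.na(data[[outcome]])
  n_dropped <- sum(miss)
  if (n_dropped > 0) {
    message(n_dropped, " row(s) with missing ", outcome, " dropped")
    data <- data[!miss, , drop = FALSE]
  }
  if (!is.null(weights)) {
    stopifnot(length(weights) == nrow(data) + n_dropped ||
                length(weights) == nrow(data))
    if (length(weights) == nrow(data) + n_dropped) weights <- weights[!miss]
    if (any(weights <= 0)) stop("weights must be positive")
  }
  X <- stats::model.matrix(formula, data)
  if (qr(X)$rank < ncol(X)) {
    stop("singular design; collinear column(s): ",
         paste(colnames(X)[-seq_len(qr(X)$rank)], collapse = ", "))
  }
  if (is.null(weights)) {
    if (!is.null(group_var) && group_var %in% names(data)) {
      fit0 <- stats::lm(formula, data = data)
      g <- as.factor(data[[group_var]])
      v <- tapply(stats::residuals(fit0), g, stats::var)
      v[is.na(v) | v == 0] <- min(v[v > 0], na.rm = TRUE)
      weights <- 1 / as.numeric(v[g])
    } else {
      weights <- rep(1, nrow(data))
    }
  }
  data$.w <- weights
  fit <- stats::lm(formula, data = data, weights = .w)
  sm <- summary(fit)
  bp <- breusch_pagan(stats::residuals(fit), X)
  structure(
    list(coefficients = sm$coefficients, weights = weights, fit = fit,
         formula = formula, bp_stat = bp$bp_stat, bp_p = bp$bp_p,
         n = nrow(data), n_dropped = n_dropped),
    class = "wls_fit"
  )
}

#' @export
print.wls_fit <- function(x, ...) {
  cat("Weighted least squares fit:", deparse(x$formula), "\n")
  cat("  n =", x$n,
      if (x$n_dropped > 0) paste0("(", x$n_dropped, " dropped)"), "\n")
  stats::printCoefmat(x$coefficients, digits = 4)
  cat(sprintf("  Breusch-Pagan: stat %.3f, p = %.3g\n", x$bp_stat, x$bp_p))
  invisible(x)
}

#' @export
coef.wls_fit <- function(object, ...) object$coefficients[, 1]

#' @export
residuals.wls_fit <- function(object, ...) stats::residuals(object$fit)

#' @export
predict.wls_fit <- function(object, newdata = NULL, ...) {
  stats::predict(object$fit, newdata = newdata, ...)
}

#' Breusch-Pagan heteroskedasticity test
#'
#' Regresses the squared residuals on the design; the statistic is
#' n times the R-squared of that auxiliary regression, referred to a
#' chi-square with (k - 1) degrees of freedom, where k is the number of
#' design columns including the intercept.
#'
#' @param residuals Residuals from a prior fit.
#' @param design Design matrix of that fit (with intercept column).
#' @return List with `bp_stat` and `bp_p`.
#' @export
breusch_pagan <- function(residuals, design) {
  design <- as.matrix(design)
  stopifnot(length(residuals) == nrow(design))
  r2sq <- residuals^2
  if (stats::var(r2sq) == 0) return(list(bp_stat = 0, bp_p = 1))
  aux <- stats::lm.fit(design, r2sq)
  rss <- sum(aux$residuals^2)
  tss <- sum((r2sq - mean(r2sq))^2)
  r2 <- 1 - rss / tss
  n <- length(residuals)
  k <- ncol(design)
  stat <- n * r2
  list(bp_stat = stat, bp_p = stats::pchisq(stat, df = k - 1,
                                            lower.tail = FALSE))
}
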