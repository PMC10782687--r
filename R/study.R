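#' Packaged fixtures of the published triticale study tables
#'
#' The study's raw 37-regenerant table is not public; everything the ML fit
#' needs is carried by the printed descriptive statistics (means, sample
#' SDs), the 9 x 9 Pearson correlation matrix, and the printed parameter
#' estimates.  These loaders return the packaged transcriptions and verify a
#' few anchor cells so that a corrupted installation fails loudly.
#'
#' @return `triticale_descriptives()`: data frame with one row per variable
#'   (minimum, maximum, mean, sd, variance, skewness, kurtosis);
#'   `triticale_correlations()`: list with the 9 x 9 correlation matrix `r`
#'   and the character matrix `flags` of printed significance marks;
#'   `triticale_estimates()`: data frame of the printed path/variance/
#'   covariance estimates (b, se, critical_ratio, std);
#'   `triticale_fit_summary()`: named numeric vector of the printed fit
#'   indices; `triticale_effects()`: data frame of the printed
#'   direct/indirect/total effect entries.
#' @export
triticale_descriptives <- function() {
  d <- read_fixture("table1_descriptives.csv")
  if (nrow(d) != 9 || abs(d$mean[d$variable == "GPRE"] - 2.5563) > 1e-9)
    stop("packaging error: descriptive-statistics fixture fails its checksum")
  d
}

#' @rdname triticale_descriptives
#' @export
triticale_correlations <- function() {
  r <- read_fixture("table2_correlations.csv")
  fl <- read_fixture("table2_flags.csv", all_character = TRUE)
  vars <- r$variable
  R <- as.matrix(r[, -1]); dimnames(R) <- list(vars, vars)
  flags <- as.matrix(fl[, -1]); dimnames(flags) <- list(vars, vars)
  flags[is.na(flags)] <- ""
  if (any(abs(R - t(R)) > 0) || any(diag(R) != 1) ||
      abs(R["Cu", "GPRE"] - 0.807) > 1e-9)
    stop("packaging error: correlation fixture fails its checksum")
  list(r = R, flags = flags)
}

#' @rdname triticale_descriptives
#' @export
triticale_estimates <- function() {
  d <- read_fixture("table4_estimates.csv")
  if (nrow(d) != 20 || abs(d$b[d$label == "lambda1"] - 1.4717) > 1e-9)
    stop("packaging error: estimates fixture fails its checksum")
  d
}

#' @rdname triticale_descriptives
#' @export
triticale_fit_summary <- function() {
  d <- read_fixture("table3_indices.csv")
  stats::setNames(d$value, d$index)
}

#' @rdname triticale_descriptives
#' @export
triticale_effects <- function() {
  read_fixture("table5_effects.csv")
}

read_fixture <- function(name, all_character = FALSE) {
  path <- system.file("extdata", name, package = "gpresem")
  if (!nzchar(path)) stop("packaging error: fixture ", name, " not found")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  colClasses = if (all_character) "character" else NA)
}

#' Reconstruct the sample covariance from SDs and a correlation matrix
#'
#' `S = D R D` with `D = diag(sd)`, optionally rescaled by `(N - 1)/N` to
#' the ML (biased) form.  By default uses the packaged study fixtures,
#' restricted to the seven model variables (Ag(I) and culture time enter no
#' path and are dropped).
#'
#' @param sds named vector of sample (N-1) standard deviations; default:
#'   Table-1 fixture values for the model variables.
#' @param R correlation matrix with matching dimnames; default: the fixture
#'   matrix restricted to `names(sds)`.
#' @param n sample size (default 37 regenerants).
#' @param divisor `"nm1"` keeps the unbiased scale; `"n"` multiplies by
#'   `(n - 1)/n`, the convention under which the published exogenous
#'   variances (e.g. 12.4414 for Cu) are reported.
#' @return a [sample_moments()].
#' @export
#' @examples
#' mom <- reconstruct_covariance(n = 37, divisor = "n")
#' mom$S["Cu", "Cu"]   # 12.4414
reconstruct_covariance <- function(sds = NULL, R = NULL, n = 37,
                                   divisor = c("nm1", "n")) {
  divisor <- match.arg(divisor)
  if (is.null(sds)) {
    d <- triticale_descriptives()
    keep <- triticale_gpre_model()$variables
    sds <- stats::setNames(d$sd, d$variable)[keep]
  }
  if (is.null(names(sds))) stop("'sds' must be named")
  if (any(sds <= 0)) stop("standard deviations must be positive")
  if (is.null(R)) R <- triticale_correlations()$r[names(sds), names(sds)]
  R <- as.matrix(R)
  if (is.null(rownames(R))) dimnames(R) <- list(names(sds), names(sds))
  else if (!identical(rownames(R), names(sds)))
    R <- R[names(sds), names(sds)]
  S <- diag(sds) %*% R %*% diag(sds)
  if (divisor == "n") S <- S * (n - 1) / n
  dimnames(S) <- list(names(sds), names(sds))
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("reconstructed covariance is not positive definite ",
         "(smallest eigenvalue ", format(min(ev)), ")")
  sample_moments(S, n, divisor = divisor)
}

#' Descriptive statistics of a sample, small-sample-corrected
#'
#' Matches the conventions of the published Table-1 battery: sample (N-1)
#' standard deviation; adjusted Fisher-Pearson skewness
#' `G1 = n/((n-1)(n-2)) * sum(z^3)`; small-sample-corrected excess kurtosis
#' `G2 = n(n+1)/((n-1)(n-2)(n-3)) * sum(z^4) - 3(n-1)^2/((n-2)(n-3))`,
#' with `z = (x - mean)/sd`.
#'
#' @param x numeric vector; skewness/kurtosis need `length(x) >= 4`.
#' @param name variable name carried into the output row.
#' @return one-row data frame with columns `variable`, `minimum`, `maximum`,
#'   `mean`, `sd`, `variance`, `skewness`, `kurtosis`.  For constant input
#'   the sd is 0 and skewness/kurtosis are `NA`.
#' @export
descriptive_stats <- function(x, name = deparse(substitute(x))) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("missing values in 'x'")
  n <- length(x)
  m <- mean(x)
  s <- stats::sd(x)
  g1 <- g2 <- NA_real_
  if (s > 0 && n >= 4) {
    z <- (x - m) / s
    g1 <- n / ((n - 1) * (n - 2)) * sum(z^3)
    g2 <- n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(z^4) -
      3 * (n - 1)^2 / ((n - 2) * (n - 3))
  }
  data.frame(variable = name, minimum = min(x), maximum = max(x),
             mean = m, sd = s, variance = s^2,
             skewness = g1, kurtosis = g2, stringsAsFactors = FALSE)
}

#' Pairwise Pearson correlations with two-tailed significance flags
#'
#' Two-tailed p-values from `t = r sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom; flags `"*"` at p <= 0.05 and `"**"` at p <= 0.01.
#'
#' @param X numeric data frame or matrix (rows = observations, at least 3).
#' @return list with matrices `r`, `p` and character matrix `flags`.
#'   Zero-variance columns yield `NA` correlations and empty flags.
#' @export
pearson_tests <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 complete rows")
  sds <- apply(X, 2, stats::sd)
  r <- suppressWarnings(stats::cor(X))
  r[sds == 0, ] <- NA; r[, sds == 0] <- NA
  diag(r)[sds > 0] <- 1
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[is.infinite(tstat)] <- 0      # |r| = 1 exactly
  diag(p) <- NA
  flags <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  flags[!is.na(p) & p <= 0.05] <- "*"
  flags[!is.na(p) & p <= 0.01] <- "**"
  list(r = r, p = p, flags = flags)
}

#' One-command reproduction of the published model results
#'
#' Runs the whole pipeline on the packaged fixtures: reconstruct the
#' 7-variable covariance from the printed SDs and correlations (ML divisor
#' N, N = 37), fit the GPRE path model by maximum likelihood, compute the
#' fit-index battery, and decompose effects in both metrics.  The result
#' bundles the computed tables with per-cell comparisons against the printed
#' values.
#'
#' @param moments optional [sample_moments()] overriding the reconstructed
#'   covariance (e.g. the model-implied covariance, for a self-consistency
#'   check in which the residual matrix is identically zero).
#' @return an object of class `gpre_reproduction`: `fit`, `indices`,
#'   `effects_unstd`, `effects_std`, `effects` (long table),
#'   `residuals` (`S - Sigma_hat`), and `comparison` (list of data frames
#'   `indices`, `parameters`, `effects` with computed vs printed values and
#'   absolute deviations).
#' @export
reproduce_tables <- function(moments = NULL) {
  model <- triticale_gpre_model()
  if (is.null(moments)) moments <- reconstruct_covariance(n = 37, divisor = "n")
  fit <- fit_ml(model, moments)
  indices <- fit_indices(fit)
  dec_b <- effect_decomposition(
    model, stats::setNames(fit$estimates, names(fit$estimates)))
  dec_std <- effect_decomposition(model, fit$standardized)
  eff <- effects_table(dec_b, dec_std)
  residuals <- moments$S[model$variables, model$variables] - fit$implied

  printed_idx <- triticale_fit_summary()
  keys <- intersect(names(printed_idx),
                    c("chi_square", "chi_square_over_df", "rmr", "gfi",
                      "agfi", "pgfi", "nfi", "rfi", "ifi", "tli", "cfi",
                      "pnfi", "pcfi", "rmsea", "rmsea_lo90", "rmsea_hi90",
                      "pclose", "srmr", "ecvi", "ecvi_lo90", "ecvi_hi90",
                      "hoelter_05"))
  computed_idx <- vapply(keys, function(k) as.numeric(indices[[k]]),
                         numeric(1))
  cmp_idx <- data.frame(index = keys, computed = computed_idx,
                        printed = printed_idx[keys],
                        deviation = abs(computed_idx - printed_idx[keys]),
                        row.names = NULL, stringsAsFactors = FALSE)

  est <- triticale_estimates()
  cmp_par <- data.frame(
    label = est$label,
    b_computed = fit$estimates[est$label],
    b_printed = est$b,
    std_computed = fit$standardized[est$label],
    std_printed = est$std,
    row.names = NULL, stringsAsFactors = FALSE)
  cmp_par$b_deviation <- abs(cmp_par$b_computed - cmp_par$b_printed)
  cmp_par$std_deviation <- abs(cmp_par$std_computed - cmp_par$std_printed)

  printed_eff <- triticale_effects()
  cmp_eff <- printed_eff[, c("target", "source")]
  cmp_eff$total_beta_computed <- mapply(function(s, tg)
    dec_std$total[s, tg], printed_eff$source, printed_eff$target)
  cmp_eff$total_beta_printed <- printed_eff$total_beta
  cmp_eff$deviation <- abs(cmp_eff$total_beta_computed -
                             cmp_eff$total_beta_printed)

  structure(list(fit = fit, indices = indices,
                 effects_unstd = dec_b, effects_std = dec_std,
                 effects = eff, residuals = residuals,
                 comparison = list(indices = cmp_idx, parameters = cmp_par,
                                   effects = cmp_eff)),
            class = "gpre_reproduction")
}

#' @export
print.gpre_reproduction <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$indices)
  cat("\nEffects (b and beta metric):\n")
  effects_report(x$effects)
  cat("\nLargest |computed - printed| standardized total effect:",
      format(max(x$comparison$effects$deviation, na.rm = TRUE), digits = 3),
      "\n")
  invisible(x)
}
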