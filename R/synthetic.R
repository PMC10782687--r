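#' The eight-trial anther-culture design
#'
#' The study grew 37 regenerants across eight induction-medium trials (A-H)
#' differing in Cu(II) concentration (0.1-10), Ag(I) concentration (0-60)
#' and culture time (35-49 days), with three to ten regenerants per trial.
#' The per-trial composition is not itemised in print; this default spreads
#' the design levels evenly over the printed ranges and allocates 37
#' regenerants in group sizes between 3 and 10.
#'
#' @return data frame with columns `trial`, `cu`, `ag`, `time_days`, `n`;
#'   `sum(n)` is 37.
#' @export
trial_design <- function() {
  data.frame(
    trial = LETTERS[1:8],
    cu = c(0.1, 1.0, 2.5, 4.0, 5.5, 7.0, 8.5, 10.0),
    ag = c(0, 10, 20, 30, 40, 50, 60, 0),
    time_days = c(35, 37, 39, 41, 43, 45, 47, 49),
    n = c(5, 5, 5, 5, 4, 5, 4, 4),
    stringsAsFactors = FALSE)
}

# Minimal eigenvalue clipping to the nearest PD matrix; used only when a
# transcribed correlation matrix is numerically indefinite.
clip_to_pd <- function(M, eps = 1e-8) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (min(e$values) > 0) return(M)
  message("covariance not positive definite; clipping ",
          sum(e$values <= 0), " eigenvalue(s) to ", eps)
  v <- pmax(e$values, eps)
  out <- e$vectors %*% diag(v) %*% t(e$vectors)
  dimnames(out) <- dimnames(M)
  (out + t(out)) / 2
}

mvn_draw <- function(n, mean, sigma) {
  p <- length(mean)
  L <- chol(sigma)
  Z <- matrix(stats::rnorm(n * p), n, p)
  X <- Z %*% L + matrix(mean, n, p, byrow = TRUE)
  colnames(X) <- names(mean)
  X
}

#' Generate a synthetic regenerant-level dataset
#'
#' Draws multivariate-normal samples emulating the unavailable raw
#' 37 x 9 regenerant table.  Default generating moments are the printed
#' means with covariance `diag(sd) R diag(sd)` from the packaged
#' descriptive-statistics and correlation fixtures.  In `"design"` mode the
#' three design variables (Cu, Ag, Time) are fixed at the eight-trial grid
#' of [trial_design()] (replicated to the per-trial group sizes) and the six
#' response variables are drawn from their conditional normal distribution
#' given the design values.
#'
#' The generator matches first and second moments only: the printed skewness
#' and kurtosis are not reproduced (a multivariate normal has none), which
#' is the approximation the source analysis itself relies on.
#'
#' @param n number of rows (ignored in `"design"` mode, which always yields
#'   the 37-row design).
#' @param mean named mean vector (default: fixture means).
#' @param covariance covariance matrix (default: fixture SDs x correlations;
#'   minimally eigenvalue-clipped with a message if indefinite).
#' @param seed integer seed for reproducibility; `NULL` leaves the RNG state
#'   alone.
#' @param mode `"paper"` (joint MVN over all 9 variables) or `"design"`.
#' @return data frame of draws with the generator's `seed`, `mean` and
#'   `covariance` attached as attributes.
#' @export
#' @examples
#' X <- generate_dataset(n = 37, seed = 1)
#' colnames(X)
generate_dataset <- function(n = 37, mean = NULL, covariance = NULL,
                             seed = NULL, mode = c("paper", "design")) {
  mode <- match.arg(mode)
  if (is.null(mean) || is.null(covariance)) {
    d <- triticale_descriptives()
    if (is.null(mean)) mean <- stats::setNames(d$mean, d$variable)
    if (is.null(covariance)) {
      R <- triticale_correlations()$r[d$variable, d$variable]
      covariance <- diag(d$sd) %*% R %*% diag(d$sd)
      dimnames(covariance) <- list(d$variable, d$variable)
    }
  }
  if (n < 2) stop("n must be at least 2")
  covariance <- clip_to_pd(covariance[names(mean), names(mean)])
  if (!is.null(seed)) set.seed(seed)

  if (mode == "paper") {
    X <- mvn_draw(n, mean, covariance)
  } else {
    des <- trial_design()
    fixed <- c("Cu", "Ag", "Time")
    if (!all(fixed %in% names(mean)))
      stop("design mode needs Cu, Ag and Time among the variables")
    resp <- setdiff(names(mean), fixed)
    Sdd <- covariance[fixed, fixed]
    Srd <- covariance[resp, fixed]
    cond_cov <- covariance[resp, resp] - Srd %*% solve(Sdd) %*% t(Srd)
    cond_cov <- (cond_cov + t(cond_cov)) / 2
    Xd <- des[rep(seq_len(nrow(des)), des$n), c("cu", "ag", "time_days")]
    names(Xd) <- fixed
    n <- nrow(Xd)
    shift <- t(Srd %*% solve(Sdd) %*% t(as.matrix(Xd) -
                 matrix(mean[fixed], n, 3, byrow = TRUE)))
    Xr <- mvn_draw(n, stats::setNames(rep(0, length(resp)), resp), cond_cov)
    Xr <- Xr + shift + matrix(mean[resp], n, length(resp), byrow = TRUE)
    X <- cbind(as.matrix(Xd), Xr)[, names(mean)]
  }
  out <- as.data.frame(X)
  attr(out, "seed") <- seed
  attr(out, "mean") <- mean
  attr(out, "covariance") <- covariance
  out
}

#' Generate data from a path model's implied covariance
#'
#' @param model a [path_model()].
#' @param theta parameter vector (ordered as `to_ram(model)$free`, or named
#'   by parameter label).
#' @param n number of rows.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param mean optional named mean vector (default zero).
#' @return data frame of draws, with generator attributes as in
#'   [generate_dataset()].
#' @export
generate_from_model <- function(model, theta, n, seed = NULL, mean = NULL) {
  ram <- to_ram(model)
  if (!is.null(names(theta))) theta <- theta[ram$free$label]
  sigma <- implied_covariance(ram, theta)
  if (is.null(mean)) mean <- stats::setNames(rep(0, ram$p), ram$variables)
  generate_dataset(n = n, mean = mean, covariance = sigma, seed = seed)
}

#' Parameter-recovery study for the ML estimator
#'
#' Simulates datasets from a known path-model solution over a grid of sample
#' sizes, refits each, and summarises bias and root-mean-square error per
#' parameter — the estimator-consistency surface standing in for the
#' study's unavailable raw data.
#'
#' @param model a [path_model()].
#' @param theta_true generating parameter vector (free-parameter order or
#'   named by label).
#' @param n_grid vector of sample sizes.
#' @param reps replicates per sample size.
#' @param seed integer seed.
#' @return data frame with one row per parameter x n: `mean_bias`, `rmse`
#'   for the unstandardized estimates, `std_bias` (standardized-estimate
#'   bias, paths only, `NA` otherwise), and `n_fail` non-convergent
#'   replicates (excluded from the summaries).
#' @export
parameter_recovery <- function(model, theta_true, n_grid = c(50, 200, 1000),
                               reps = 100, seed = 1) {
  ram <- to_ram(model)
  if (!is.null(names(theta_true))) theta_true <- theta_true[ram$free$label]
  sigma <- implied_covariance(ram, theta_true)
  std_true <- standardize(list(ram = ram,
                               estimates = stats::setNames(theta_true,
                                                           ram$free$label)))
  mean0 <- stats::setNames(rep(0, ram$p), ram$variables)
  set.seed(seed)
  is_path <- ram$free$matrix == "A"
  out <- list()
  for (n in n_grid) {
    est <- matrix(NA_real_, reps, ram$q)
    std <- matrix(NA_real_, reps, ram$q)
    fails <- 0L
    for (r in seq_len(reps)) {
      X <- mvn_draw(n, mean0, sigma)
      fit <- tryCatch(
        suppressWarnings(fit_ml(model, sample_moments_from_data(X, divisor = "n"))),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged) { fails <- fails + 1L; next }
      est[r, ] <- fit$estimates[ram$free$label]
      std[r, ] <- fit$standardized[ram$free$label]
    }
    ok <- stats::complete.cases(est)
    for (k in seq_len(ram$q)) {
      e <- est[ok, k]
      out[[length(out) + 1L]] <- data.frame(
        parameter = ram$free$label[k], n = n,
        mean_bias = mean(e) - theta_true[k],
        rmse = sqrt(mean((e - theta_true[k])^2)),
        std_bias = if (is_path[k])
          mean(std[ok, k]) - std_true[[ram$free$label[k]]] else NA_real_,
        n_fail = fails, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
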