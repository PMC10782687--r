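#' Sample moments for covariance-structure estimation
#'
#' Wraps a sample covariance matrix together with the sample size and the
#' divisor convention under which it was computed.  The maximum-likelihood
#' discrepancy is conventionally evaluated against the biased (divisor N)
#' covariance; the model chi-square uses the multiplier (N - 1) either way.
#'
#' @param S symmetric positive-definite covariance matrix with dimnames, or
#'   an unnamed matrix plus `variable_names`.
#' @param n sample size (number of regenerants / rows of the raw table).
#' @param divisor `"nm1"` if `S` was computed with divisor N - 1 (unbiased),
#'   `"n"` for the ML (biased) form.
#' @param variable_names optional character vector overriding dimnames.
#' @return an object of class `sample_moments`.
#' @export
sample_moments <- function(S, n, divisor = c("nm1", "n"),
                           variable_names = NULL) {
  divisor <- match.arg(divisor)
  S <- as.matrix(S)
  if (!is.null(variable_names)) dimnames(S) <- list(variable_names,
                                                    variable_names)
  if (is.null(rownames(S)))
    dimnames(S) <- list(paste0("V", seq_len(nrow(S))),
                        paste0("V", seq_len(nrow(S))))
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-8 * max(abs(S), 1))
    stop("S must be a symmetric square matrix")
  S <- (S + t(S)) / 2
  if (any(diag(S) <= 0)) stop("S must have strictly positive diagonal")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("S is not positive definite (smallest eigenvalue ",
         format(min(ev)), ")")
  if (n < 2) stop("n must be at least 2")
  structure(list(S = S, n = as.integer(n), divisor = divisor,
                 variable_names = rownames(S), p = nrow(S)),
            class = "sample_moments")
}

#' @export
print.sample_moments <- function(x, ...) {
  cat("Sample moments: p =", x$p, ", N =", x$n,
      ", divisor =", if (x$divisor == "nm1") "N-1" else "N", "\n")
  print(round(x$S, 4))
  invisible(x)
}

#' Moments from a raw sample table
#'
#' @param X numeric data frame or matrix, rows = observations.
#' @inheritParams sample_moments
#' @return a [sample_moments()].
#' @export
sample_moments_from_data <- function(X, divisor = c("nm1", "n")) {
  divisor <- match.arg(divisor)
  X <- as.matrix(X)
  n <- nrow(X)
  S <- stats::cov(X)
  if (divisor == "n") S <- S * (n - 1) / n
  sample_moments(S, n, divisor = divisor)
}

#' Model-implied covariance matrix
#'
#' Evaluates `(I - A)^-1 S (I - A)^-T` with the free entries of the RAM
#' patterns filled from `theta` (ordered as `ram$free`).
#'
#' @param ram a [to_ram()] compilation.
#' @param theta numeric vector of length `ram$q`.
#' @return symmetric p x p matrix with variable dimnames.
#' @export
implied_covariance <- function(ram, theta) {
  stopifnot(inherits(ram, "ram"))
  m <- fill_ram(ram, theta)
  IA <- diag(ram$p) - m$A
  # unit-triangular under a topological order: always invertible for a DAG
  B <- solve(IA)
  sigma <- B %*% m$S %*% t(B)
  sigma <- (sigma + t(sigma)) / 2
  dimnames(sigma) <- list(ram$variables, ram$variables)
  sigma
}

#' Maximum-likelihood discrepancy between two covariance matrices
#'
#' `F = log|Sigma| - log|S| + tr(S Sigma^-1) - p`: nonnegative, zero iff
#' `Sigma == S`.  The model chi-square is `(N - 1) * F` at the minimum.
#'
#' @param S sample covariance (symmetric positive definite).
#' @param sigma model-implied covariance of the same order.
#' @return scalar discrepancy.
#' @export
ml_discrepancy <- function(S, sigma) {
  p <- nrow(S)
  chS <- tryCatch(chol(S), error = function(e)
    stop("sample covariance 'S' is not positive definite"))
  chSig <- tryCatch(chol(sigma), error = function(e)
    stop("implied covariance 'sigma' is not positive definite"))
  logdetS <- 2 * sum(log(diag(chS)))
  logdetSig <- 2 * sum(log(diag(chSig)))
  tr <- sum(diag(chol2inv(chSig) %*% S))
  max(logdetSig - logdetS + tr - p, 0)
}

# Per-equation least-squares starting values (exact ML for DAG models whose
# exogenous block is saturated): regress each endogenous variable on its
# parents using the sample covariance.
start_values <- function(ram, S) {
  model <- ram$model
  f <- ram$free
  theta <- numeric(ram$q)
  resid_var <- stats::setNames(diag(S)[model$endogenous], model$endogenous)
  for (y in model$endogenous) {
    pa <- model$paths$from[model$paths$to == y]
    b <- solve(S[pa, pa, drop = FALSE], S[pa, y])
    resid_var[y] <- max(S[y, y] - sum(b * S[pa, y]), 1e-8 * S[y, y])
    for (i in seq_along(pa)) {
      k <- which(f$matrix == "A" & f$row == y & f$col == pa[i])
      theta[k] <- b[i]
    }
  }
  for (k in seq_len(nrow(f))) {
    if (f$matrix[k] == "S") {
      r <- f$row[k]; cl <- f$col[k]
      theta[k] <- if (r == cl) {
        if (r %in% model$endogenous) resid_var[[r]] else S[r, r]
      } else S[r, cl]
    }
  }
  theta
}

# Analytic gradient of F at theta; also returns pieces reused elsewhere.
ml_gradient <- function(ram, theta, S) {
  m <- fill_ram(ram, theta)
  p <- ram$p
  B <- solve(diag(p) - m$A)
  sigma <- B %*% m$S %*% t(B)
  W <- tryCatch(chol2inv(chol((sigma + t(sigma)) / 2)),
                error = function(e) NULL)
  if (is.null(W)) return(NULL)
  M <- W - W %*% S %*% W          # dF = tr(M dSigma)
  f <- ram$free
  g <- numeric(ram$q)
  SigMB <- sigma %*% M %*% B
  BtMB <- t(B) %*% M %*% B
  idx <- stats::setNames(seq_len(p), ram$variables)
  for (k in seq_len(nrow(f))) {
    i <- idx[[f$row[k]]]; j <- idx[[f$col[k]]]
    g[k] <- if (f$matrix[k] == "A") 2 * SigMB[j, i]
            else if (i == j) BtMB[i, i] else 2 * BtMB[i, j]
  }
  list(gradient = g, sigma = sigma, W = W, B = B)
}

# dSigma/dtheta_k as a list of p x p matrices (used for expected information).
sigma_derivatives <- function(ram, theta) {
  m <- fill_ram(ram, theta)
  p <- ram$p
  B <- solve(diag(p) - m$A)
  sigma <- B %*% m$S %*% t(B)
  f <- ram$free
  idx <- stats::setNames(seq_len(p), ram$variables)
  lapply(seq_len(nrow(f)), function(k) {
    i <- idx[[f$row[k]]]; j <- idx[[f$col[k]]]
    if (f$matrix[k] == "A") {
      E <- matrix(0, p, p); E[i, j] <- 1
      X <- B %*% E %*% sigma
      X + t(X)
    } else {
      D <- matrix(0, p, p); D[i, j] <- 1; D[j, i] <- 1
      B %*% D %*% t(B)
    }
  })
}

#' Fit a path model by maximum likelihood
#'
#' Minimises the ML discrepancy between the sample covariance and the
#' model-implied covariance over the free RAM parameters, starting from
#' per-equation least-squares values and polishing with a quasi-Newton
#' optimiser using the analytic gradient.  Standard errors come from the
#' inverse expected information,
#' `I_jk = ((N - 1)/2) tr(Sigma^-1 dSigma_j Sigma^-1 dSigma_k)`.
#'
#' Variables are internally rescaled to unit sample variance before
#' optimisation and results are back-transformed; this keeps the problem
#' well-conditioned when variable scales differ by orders of magnitude (the
#' glutathione band variance is ~1.6e-7 while Ag(I) would be ~700).
#'
#' @param model a [path_model()].
#' @param moments a [sample_moments()].
#' @param control list: `rel_tol` (change-in-F stop, default 1e-12),
#'   `grad_tol` (infinity-norm gradient stop, default 1e-8),
#'   `max_iter` (default 500).
#' @return an object of class `sem_fit`: `estimates`, `se`,
#'   `critical_ratio`, `p_value` (all named by parameter label),
#'   `standardized` (see [standardize()]), `F_min`, `chi_square`, `df`,
#'   `chi_square_over_df`, `p_value_model`, `implied`, `converged`,
#'   `n_iterations`, `gradient_norm`, `heywood`, plus the inputs.
#' @export
#' @examples
#' m <- triticale_gpre_model()
#' mom <- reconstruct_covariance(n = 37, divisor = "n")
#' fit <- fit_ml(m, mom)
#' fit$chi_square
fit_ml <- function(model, moments, control = list()) {
  stopifnot(inherits(model, "path_model"), inherits(moments, "sample_moments"))
  ctl <- utils::modifyList(
    list(rel_tol = 1e-12, grad_tol = 1e-8, max_iter = 500), control)
  ram <- to_ram(model)
  if (!setequal(ram$variables, moments$variable_names))
    stop("model variables and moment names differ")
  S0 <- moments$S[ram$variables, ram$variables]
  n <- moments$n
  p <- ram$p

  # rescale to unit sample variance
  d <- sqrt(diag(S0))
  S <- S0 / tcrossprod(d)

  theta0 <- start_values(ram, S)
  obj <- function(th) {
    g <- ml_gradient(ram, th, S)
    if (is.null(g)) return(1e10)
    ml_discrepancy_quiet(S, g$sigma)
  }
  grad <- function(th) {
    g <- ml_gradient(ram, th, S)
    if (is.null(g)) return(rep(0, length(th)))
    g$gradient
  }
  opt <- stats::nlminb(theta0, obj, gradient = grad,
                       control = list(rel.tol = ctl$rel_tol,
                                      iter.max = ctl$max_iter,
                                      eval.max = 4L * ctl$max_iter))
  theta <- opt$par
  gr <- ml_gradient(ram, theta, S)
  gnorm <- max(abs(gr$gradient))
  # near-singular implied covariances inflate the gradient's floating-point
  # noise by ~|Sigma^-1|^2, so judge the gradient relative to that scale
  gscale <- 1 + max(abs(gr$W))
  converged <- opt$convergence == 0 || gnorm < ctl$grad_tol ||
    gnorm / gscale < 1e-6
  if (!converged && gnorm / gscale > 1e-4)
    stop("ML fit did not converge: gradient infinity-norm ", format(gnorm),
         " after ", opt$iterations, " iterations")

  F_min <- ml_discrepancy(S, gr$sigma)

  # expected information and SEs on the scaled problem
  dS <- sigma_derivatives(ram, theta)
  W <- gr$W
  q <- ram$q
  info <- matrix(0, q, q)
  WD <- lapply(dS, function(Dk) W %*% Dk)
  for (j in seq_len(q)) for (k in j:q) {
    info[j, k] <- info[k, j] <- ((n - 1) / 2) * sum(WD[[j]] * t(WD[[k]]))
  }
  se_scaled <- tryCatch(sqrt(diag(solve(info))),
                        error = function(e) rep(NA_real_, q))

  # back-transform: path j->i scales by d_i/d_j; (co)variance (i,j) by d_i d_j
  f <- ram$free
  scale_fac <- vapply(seq_len(q), function(k) {
    di <- d[[f$row[k]]]; dj <- d[[f$col[k]]]
    if (f$matrix[k] == "A") di / dj else di * dj
  }, numeric(1))
  estimates <- stats::setNames(theta * scale_fac, f$label)
  se <- stats::setNames(se_scaled * scale_fac, f$label)
  cr <- estimates / se
  p_par <- 2 * stats::pnorm(-abs(cr))

  implied <- implied_covariance(ram, estimates)
  df <- ram$df
  chi2 <- (n - 1) * F_min
  heywood <- any(theta[f$matrix == "S" & f$row == f$col] < 0)
  if (heywood)
    warning("Heywood case: negative variance estimate at the optimum")

  fit <- structure(list(
    model = model, ram = ram, moments = moments,
    estimates = estimates, se = se, critical_ratio = cr, p_value = p_par,
    F_min = F_min, chi_square = chi2, df = df,
    chi_square_over_df = if (df > 0) chi2 / df else NA_real_,
    p_value_model = if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE)
                    else NA_real_,
    implied = implied, converged = converged,
    n_iterations = opt$iterations, gradient_norm = gnorm,
    heywood = heywood), class = "sem_fit")
  fit$standardized <- standardize(fit)
  fit
}

# chol-based discrepancy that returns a big penalty instead of erroring,
# for use inside the optimiser line search.
ml_discrepancy_quiet <- function(S, sigma) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  p <- nrow(S)
  2 * sum(log(diag(ch))) - determinant_log(S) + sum(diag(chol2inv(ch) %*% S)) - p
}

determinant_log <- function(S) as.numeric(determinant(S, logarithm = TRUE)$modulus)

#' Standardized solution of a fitted path model
#'
#' Path coefficients are standardized with the model-implied (not sample)
#' standard deviations, `beta(j -> i) = b * sd(j) / sd(i)`; free covariances
#' become implied correlations; variances are expressed as proportions of
#' the implied variance of their variable (so a standardized residual
#' variance is `1 - R^2`).
#'
#' @param fit a [fit_ml()] result (or any list with `ram` and `estimates`).
#' @return named numeric vector of standardized estimates, one per free
#'   parameter label.
#' @export
standardize <- function(fit) {
  ram <- fit$ram
  implied <- implied_covariance(ram, fit$estimates)
  sdv <- sqrt(diag(implied))
  if (any(sdv <= 0)) stop("zero implied variance; cannot standardize")
  f <- ram$free
  out <- vapply(seq_len(ram$q), function(k) {
    b <- fit$estimates[[k]]
    i <- f$row[k]; j <- f$col[k]
    if (f$matrix[k] == "A") b * sdv[[j]] / sdv[[i]]
    else b / (sdv[[i]] * sdv[[j]])
  }, numeric(1))
  stats::setNames(out, f$label)
}

#' @export
print.sem_fit <- function(x, digits = 4, ...) {
  cat("ML path-model fit: chi-square =", round(x$chi_square, digits),
      "on", x$df, "df (p =",
      format.pval(x$p_value_model, digits = 3), ")\n")
  cat("  F_min =", format(x$F_min, digits = 6),
      "| iterations:", x$n_iterations,
      "| gradient norm:", format(x$gradient_norm, digits = 3), "\n\n")
  f <- x$ram$free
  tab <- data.frame(
    parameter = f$label,
    effect = ifelse(f$matrix == "A",
                    paste(f$col, "->", f$row),
                    ifelse(f$row == f$col, paste("var", f$row),
                           paste(f$row, "<->", f$col))),
    b = round(x$estimates, digits),
    SE = round(x$se, digits),
    CR = round(x$critical_ratio, digits),
    beta = round(x$standardized, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}
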