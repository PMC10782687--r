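# Independent oracles used across the suite.  These deliberately avoid the
# package's RAM/optimiser code paths.

# Random acyclic path model over p variables: each pair (i < j in a random
# order) gets a directed edge with probability p_edge; the first n_exo
# variables in that order are exogenous and covary freely.
random_dag_model <- function(p, p_edge = 0.5) {
  vars <- paste0("V", seq_len(p))
  ord <- sample(vars)
  from <- character(0); to <- character(0)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (stats::runif(1) < p_edge) {
      from <- c(from, ord[i]); to <- c(to, ord[j])
    }
  }
  if (!length(from)) {        # force at least one edge
    from <- ord[1]; to <- ord[2]
  }
  exo <- setdiff(vars, unique(to))
  covs <- NULL
  if (length(exo) > 1) {
    pairs <- utils::combn(exo, 2)
    covs <- data.frame(a = pairs[1, ], b = pairs[2, ],
                       stringsAsFactors = FALSE)
  }
  path_model(vars, paths = data.frame(from = from, to = to,
                                      stringsAsFactors = FALSE),
             covariances = covs)
}

# Random parameter vector for a model: paths ~ U(-0.9, 0.9) in a
# unit-variance-ish scale, residual/exogenous variances in (0.3, 1.3),
# exogenous correlations mild.
random_theta <- function(model) {
  ram <- to_ram(model)
  f <- ram$free
  theta <- numeric(ram$q)
  for (k in seq_len(ram$q)) {
    theta[k] <- if (f$matrix[k] == "A") stats::runif(1, -0.9, 0.9)
    else if (f$row[k] == f$col[k]) stats::runif(1, 0.3, 1.3)
    else stats::runif(1, -0.2, 0.2)
  }
  stats::setNames(theta, f$label)
}

# Sum over all directed paths of the product of edge coefficients —
# exhaustive depth-first enumeration, the brute-force total-effect oracle.
enumerate_total_effect <- function(model, coefficients, source, target) {
  edges <- model$paths
  total <- 0
  walk <- function(node, prod) {
    out <- which(edges$from == node)
    for (k in out) {
      p2 <- prod * coefficients[[edges$label[k]]]
      if (edges$to[k] == target) total <<- total + p2
      else walk(edges$to[k], p2)
    }
  }
  walk(source, 1)
  total
}

# Closed-form Gaussian-DAG maximum likelihood: for a recursive model with
# uncorrelated residuals and a saturated exogenous block the likelihood
# factorises into per-equation regressions of each endogenous variable on
# its parents, so the MLE (and hence F_min) needs no iteration.  This is an
# independent route to the same estimand as fit_ml's quasi-Newton RAM
# minimisation.
dag_ml_oracle <- function(model, S) {
  vars <- model$variables
  S <- S[vars, vars]
  p <- length(vars)
  A <- matrix(0, p, p, dimnames = list(vars, vars))
  Sp <- matrix(0, p, p, dimnames = list(vars, vars))
  for (x in model$exogenous) Sp[x, x] <- S[x, x]
  for (k in seq_len(nrow(model$covariances))) {
    a <- model$covariances$a[k]; b <- model$covariances$b[k]
    Sp[a, b] <- Sp[b, a] <- S[a, b]
  }
  for (y in model$endogenous) {
    pa <- model$paths$from[model$paths$to == y]
    b <- solve(S[pa, pa, drop = FALSE], S[pa, y])
    A[y, pa] <- b
    Sp[y, y] <- S[y, y] - sum(b * S[pa, y])
  }
  B <- solve(diag(p) - A)
  sigma <- B %*% Sp %*% t(B)
  F_min <- log(det(sigma)) - log(det(S)) +
    sum(diag(S %*% solve(sigma))) - p
  list(A = A, S = Sp, sigma = sigma, F_min = max(F_min, 0))
}

# Is every free covariance pair present, i.e. the exogenous block saturated?
has_saturated_exo_block <- function(model) {
  exo <- model$exogenous
  if (length(exo) < 2) return(TRUE)
  pairs <- utils::combn(sort(exo), 2)
  declared <- apply(as.matrix(model$covariances[, c("a", "b")]), 1,
                    function(r) paste(sort(r), collapse = "~"))
  all(paste(pairs[1, ], pairs[2, ], sep = "~") %in% declared)
}

# plain Cholesky MVN sampler (kept local so tests do not depend on the
# package's generator when probing the estimator)
mvn_from_sigma <- function(n, sigma) {
  p <- nrow(sigma)
  X <- matrix(stats::rnorm(n * p), n, p) %*% chol(sigma)
  colnames(X) <- colnames(sigma)
  X
}

triticale_beta <- function() {
  est <- triticale_estimates()
  stats::setNames(est$std, est$label)[paste0("lambda", 1:12)]
}

triticale_b <- function() {
  est <- triticale_estimates()
  stats::setNames(est$b, est$label)[paste0("lambda", 1:12)]
}
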