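#' Direct, indirect and total effects of a path model
#'
#' For a recursive model with endogenous coefficient block `B` (entry
#' \[i, j\] = coefficient of endogenous j on endogenous i) and exogenous
#' block `G` (endogenous on exogenous), the total effects are
#' `(I - B)^-1 G` (on exogenous sources) and `(I - B)^-1 - I` (on
#' endogenous sources); indirect = total - direct.  `B` is nilpotent for a
#' DAG, so the inverse is exact (the geometric series terminates) and every
#' entry equals the sum over directed paths of the product of path
#' coefficients along the path.
#'
#' @param model a [path_model()].
#' @param coefficients named numeric vector covering every path label of the
#'   model (either unstandardized `b` or standardized `beta` values — the
#'   algebra is metric-agnostic).
#' @return an object of class `effect_tables`: matrices `direct`, `indirect`
#'   and `total`, each sources (rows: all model variables, exogenous first)
#'   by targets (columns: endogenous variables); `total = direct + indirect`
#'   holds exactly.
#' @export
#' @examples
#' m <- triticale_gpre_model()
#' est <- triticale_estimates()
#' beta <- stats::setNames(est$std, est$label)[paste0("lambda", 1:12)]
#' effect_decomposition(m, beta)$total["Cu", "GPRE"]
effect_decomposition <- function(model, coefficients) {
  stopifnot(inherits(model, "path_model"))
  missing_lab <- setdiff(model$paths$label, names(coefficients))
  if (length(missing_lab))
    stop("missing coefficient(s) for path label(s): ",
         paste(missing_lab, collapse = ", "))
  endo <- model$endogenous
  exo <- model$exogenous
  sources <- c(exo, endo)
  ne <- length(endo)

  direct <- matrix(0, length(sources), ne,
                   dimnames = list(sources, endo))
  for (k in seq_len(nrow(model$paths)))
    direct[model$paths$from[k], model$paths$to[k]] <-
      coefficients[[model$paths$label[k]]]

  B <- t(direct[endo, , drop = FALSE])        # [i, j]: j -> i, endo block
  G <- t(direct[exo, , drop = FALSE])         # endo x exo
  Tinv <- if (ne) solve(diag(ne) - B) else B
  total_exo <- Tinv %*% G                     # endo x exo
  total_endo <- Tinv - diag(ne)               # endo x endo
  total <- rbind(t(total_exo), t(total_endo))
  dimnames(total) <- dimnames(direct)
  indirect <- total - direct

  structure(list(direct = direct, indirect = indirect, total = total,
                 sources = sources, targets = endo, model = model),
            class = "effect_tables")
}

#' @export
print.effect_tables <- function(x, digits = 4, ...) {
  cat("Effect decomposition (sources x targets)\n\nDirect:\n")
  print(round(x$direct, digits))
  cat("\nIndirect:\n")
  print(round(x$indirect, digits))
  cat("\nTotal:\n")
  print(round(x$total, digits))
  invisible(x)
}

#' Long-format effects table for reporting
#'
#' Combines an unstandardized and a standardized [effect_decomposition()]
#' into one long table listing, per endogenous target and per source with a
#' nonzero total effect, the direct/indirect/total effects in both metrics.
#'
#' @param unstd an [effect_tables()] computed from b-metric coefficients.
#' @param std an [effect_tables()] computed from standardized coefficients
#'   of the same model (may be `NULL`).
#' @return data frame with columns `target`, `source`, `direct_b`,
#'   `indirect_b`, `total_b` and, when `std` is given, `direct_beta`,
#'   `indirect_beta`, `total_beta`.
#' @export
effects_table <- function(unstd, std = NULL) {
  stopifnot(inherits(unstd, "effect_tables"))
  rows <- list()
  for (tg in rev(unstd$targets)) {          # last-formed endogenous first
    for (src in unstd$sources) {
      if (src == tg) next
      tot <- unstd$total[src, tg]
      stot <- if (!is.null(std)) std$total[src, tg] else 0
      if (tot == 0 && stot == 0) next
      row <- data.frame(target = tg, source = src,
                        direct_b = unstd$direct[src, tg],
                        indirect_b = unstd$indirect[src, tg],
                        total_b = tot,
                        stringsAsFactors = FALSE)
      if (!is.null(std)) {
        row$direct_beta <- std$direct[src, tg]
        row$indirect_beta <- std$indirect[src, tg]
        row$total_beta <- std$total[src, tg]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) {
    out <- data.frame(target = character(), source = character(),
                      direct_b = numeric(), indirect_b = numeric(),
                      total_b = numeric())
    return(out)
  }
  do.call(rbind, rows)
}

#' Print an effects table at four decimals
#'
#' @param tab a data frame from [effects_table()].
#' @return the formatted character matrix, invisibly; printed as a side
#'   effect.
#' @export
effects_report <- function(tab) {
  if (!nrow(tab)) {
    cat("(no effects)\n")
    return(invisible(tab))
  }
  num <- vapply(tab, is.numeric, logical(1))
  shown <- tab
  shown[num] <- lapply(tab[num], function(col) sprintf("%.4f", col))
  print(shown, row.names = FALSE)
  invisible(shown)
}
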