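#' Define a recursive path model over observed variables
#'
#' A path model is a directed acyclic graph of regression paths among named
#' observed variables, plus free covariances among exogenous variables.
#' Endogenous variables (those with at least one incoming path) each carry a
#' free residual variance; exogenous variables carry free variances.  This is
#' the model class of classical path analysis: no latent variables, no mean
#' structure, uncorrelated residuals.
#'
#' @param variables character vector of unique variable names; their order is
#'   the canonical row/column order of every matrix derived from the model.
#' @param paths directed edges, either a data frame with columns
#'   `from`, `to` and optionally `label`, or a character vector of lines in
#'   the form `"from -> to [label]"`.
#' @param covariances free covariances among exogenous variables, either a
#'   data frame with columns `a`, `b` and optionally `label`, or lines in the
#'   form `"a <-> b [label]"`.  May be `NULL`.
#' @return an object of class `path_model` with the validated edge lists, the
#'   endogenous/exogenous partition, a topological order, and residual /
#'   variance parameter labels.  Residual labels (`delta1`, `delta2`, ...)
#'   are assigned in the order each endogenous variable first appears as a
#'   path target, unless the input supplies labels explicitly.
#' @export
#' @examples
#' m <- path_model(c("X", "M", "Y"),
#'                 paths = c("X -> M [a]", "M -> Y [b]", "X -> Y [c]"))
#' m$endogenous
path_model <- function(variables, paths = NULL, covariances = NULL) {
  if (length(variables) == 0L || anyNA(variables) || any(!nzchar(variables)))
    stop("'variables' must be a nonempty vector of nonempty names")
  variables <- as.character(variables)
  if (anyDuplicated(variables))
    stop("duplicate variable names: ",
         paste(unique(variables[duplicated(variables)]), collapse = ", "))

  paths <- normalize_edges(paths, c("from", "to"), "->")
  covariances <- normalize_edges(covariances, c("a", "b"), "<->")

  check_names <- function(x, what) {
    bad <- setdiff(x, variables)
    if (length(bad))
      stop("unknown variable name(s) in ", what, ": ",
           paste(bad, collapse = ", "))
  }
  check_names(c(paths$from, paths$to), "paths")
  check_names(c(covariances$a, covariances$b), "covariances")

  if (any(paths$from == paths$to))
    stop("self-loop path(s) not allowed: ",
         paste(paths$from[paths$from == paths$to], collapse = ", "))
  if (anyDuplicated(paste(paths$from, paths$to)))
    stop("duplicate directed edge")

  # default labels
  if (is.null(paths$label)) paths$label <- character(nrow(paths))
  need <- !nzchar(paths$label)
  paths$label[need] <- paste0("b_", paths$from[need], "_", paths$to[need])
  if (nrow(covariances)) {
    if (is.null(covariances$label)) covariances$label <- character(nrow(covariances))
    need <- !nzchar(covariances$label)
    covariances$label[need] <-
      paste0("cov_", covariances$a[need], "_", covariances$b[need])
  }

  order <- topological_order(variables, paths)   # errors on a cycle

  endogenous <- variables[variables %in% paths$to]
  exogenous <- setdiff(variables, endogenous)

  if (nrow(covariances)) {
    bad <- union(covariances$a, covariances$b)
    bad <- bad[!bad %in% exogenous]
    if (length(bad))
      stop("free covariances are only allowed among exogenous variables; ",
           "endogenous: ", paste(bad, collapse = ", "))
    if (any(covariances$a == covariances$b))
      stop("a variance must not be declared as a covariance")
  }

  # residual labels in order of first appearance as a path target
  first_as_target <- unique(paths$to)
  residual_labels <- if (length(first_as_target))
    stats::setNames(paste0("delta", seq_along(first_as_target)),
                    first_as_target)
  else stats::setNames(character(0), character(0))
  variance_labels <- stats::setNames(paste0("v_", exogenous), exogenous)

  labels <- c(paths$label, covariances$label, residual_labels, variance_labels)
  if (anyDuplicated(labels))
    stop("parameter labels must be unique; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))

  structure(list(
    variables = variables,
    paths = paths,
    covariances = covariances,
    endogenous = endogenous,
    exogenous = exogenous,
    topological_order = order,
    residual_labels = residual_labels,
    variance_labels = variance_labels
  ), class = "path_model")
}

# Accept data.frame or "a -> b [lab]" / "a <-> b [lab]" lines.
normalize_edges <- function(x, cols, arrow) {
  if (is.null(x))
    return(stats::setNames(data.frame(character(), character(), character(),
                                      stringsAsFactors = FALSE),
                           c(cols, "label")))
  if (is.character(x)) {
    pat <- paste0("^\\s*(\\S+)\\s*", arrow,
                  "\\s*(\\S+)\\s*(\\[([^]]+)\\])?\\s*$")
    m <- regmatches(x, regexec(pat, x))
    bad <- vapply(m, length, 1L) == 0L
    if (any(bad)) stop("cannot parse edge line(s): ",
                       paste(x[bad], collapse = "; "))
    x <- data.frame(a = vapply(m, `[`, "", 2L),
                    b = vapply(m, `[`, "", 3L),
                    label = vapply(m, `[`, "", 5L),
                    stringsAsFactors = FALSE)
    names(x) <- c(cols, "label")
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!all(cols %in% names(x)))
    stop("edge table must have columns ", paste(cols, collapse = ", "))
  for (cl in intersect(c(cols, "label"), names(x))) x[[cl]] <- as.character(x[[cl]])
  x
}

# Kahn's algorithm; on failure, name one cycle.
topological_order <- function(variables, paths) {
  n <- length(variables)
  idx <- stats::setNames(seq_len(n), variables)
  indeg <- integer(n)
  adj <- vector("list", n)
  for (k in seq_len(nrow(paths))) {
    i <- idx[[paths$from[k]]]; j <- idx[[paths$to[k]]]
    adj[[i]] <- c(adj[[i]], j)
    indeg[j] <- indeg[j] + 1L
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (w in adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) < n) {
    left <- setdiff(seq_len(n), out)
    cyc <- find_cycle(left, adj)
    stop("path model contains a cycle: ",
         paste(variables[cyc], collapse = " -> "))
  }
  variables[out]
}

find_cycle <- function(left, adj) {
  v <- left[1L]
  seen <- integer(0)
  while (!(v %in% seen)) {
    seen <- c(seen, v)
    v <- intersect(adj[[v]], left)[1L]
  }
  c(seen[which(seen == v):length(seen)], v)
}

#' @export
print.path_model <- function(x, ...) {
  cat("Recursive path model:", length(x$variables), "variables,",
      nrow(x$paths), "paths,", nrow(x$covariances), "free covariance(s)\n")
  cat("  endogenous:", paste(x$endogenous, collapse = ", "), "\n")
  cat("  exogenous: ", paste(x$exogenous, collapse = ", "), "\n")
  for (k in seq_len(nrow(x$paths)))
    cat(sprintf("  %s -> %s [%s]\n", x$paths$from[k], x$paths$to[k],
                x$paths$label[k]))
  for (k in seq_len(nrow(x$covariances)))
    cat(sprintf("  %s <-> %s [%s]\n", x$covariances$a[k], x$covariances$b[k],
                x$covariances$label[k]))
  invisible(x)
}

#' Compile a path model to RAM matrices
#'
#' The reticular-action-model (RAM) form of a path model over observed
#' variables: a square coefficient matrix pattern `A` (entry \[i, j\] is the
#' coefficient of the path j -> i) and a symmetric variance/covariance
#' pattern `S` holding residual variances for endogenous variables and free
#' variances/covariances for exogenous variables.  The model-implied
#' covariance is `(I - A)^-1 S (I - A)^-T`.
#'
#' @param model a [path_model()].
#' @return a list of class `ram` with elements `A` and `S` (numeric patterns,
#'   zero where fixed), `free` (a data frame enumerating the free parameters:
#'   matrix, row, col, label, in a deterministic order — paths, covariances,
#'   residual variances, exogenous variances), `p` (number of observed
#'   variables), `q` (number of free parameters) and `df`
#'   (`p(p+1)/2 - q`, the model degrees of freedom).
#' @export
to_ram <- function(model) {
  stopifnot(inherits(model, "path_model"))
  v <- model$variables
  p <- length(v)
  A <- S <- matrix(0, p, p, dimnames = list(v, v))

  free <- data.frame(matrix = character(), row = character(),
                     col = character(), label = character(),
                     stringsAsFactors = FALSE)
  add <- function(mat, r, cl, lab)
    rbind(free, data.frame(matrix = mat, row = r, col = cl, label = lab,
                           stringsAsFactors = FALSE))
  for (k in seq_len(nrow(model$paths)))
    free <- add("A", model$paths$to[k], model$paths$from[k],
                model$paths$label[k])
  for (k in seq_len(nrow(model$covariances)))
    free <- add("S", model$covariances$a[k], model$covariances$b[k],
                model$covariances$label[k])
  for (nm in names(model$residual_labels))
    free <- add("S", nm, nm, model$residual_labels[[nm]])
  for (nm in names(model$variance_labels))
    free <- add("S", nm, nm, model$variance_labels[[nm]])

  q <- nrow(free)
  df <- p * (p + 1L) / 2L - q
  if (df < 0)
    stop("model has more free parameters (", q, ") than observed moments (",
         p * (p + 1L) / 2L, ")")
  structure(list(A = A, S = S, free = free, p = p, q = q, df = df,
                 variables = v, model = model),
            class = "ram")
}

# Fill A and S patterns from a parameter vector ordered like ram$free.
fill_ram <- function(ram, theta) {
  stopifnot(length(theta) == ram$q)
  A <- ram$A; S <- ram$S
  f <- ram$free
  for (k in seq_len(nrow(f))) {
    if (f$matrix[k] == "A") {
      A[f$row[k], f$col[k]] <- theta[k]
    } else {
      S[f$row[k], f$col[k]] <- theta[k]
      S[f$col[k], f$row[k]] <- theta[k]
    }
  }
  list(A = A, S = S)
}

#' The triticale GPRE path model
#'
#' The seven-variable recursive model linking Cu(II) concentration in the
#' induction medium and the low-methylated-pectin FTIR band (exogenous,
#' freely covarying) to the SAM and glutathione FTIR bands, de novo CHH
#' methylation (CHH_DNMV), CHH sequence variation (CHH_SV) and green plant
#' regeneration efficiency (GPRE): twelve paths, one covariance, five
#' residuals.
#'
#' Paths: LMP -> SAM (lambda1); Cu -> CHH_DNMV (lambda2); SAM -> CHH_DNMV
#' (lambda3); Cu -> GSH (lambda4); CHH_DNMV -> CHH_SV (lambda5); SAM -> GSH
#' (lambda6); Cu -> CHH_SV (lambda7); Cu -> GPRE (lambda8); GSH -> GPRE
#' (lambda9); SAM -> GPRE (lambda10); CHH_DNMV -> GPRE (lambda11);
#' CHH_SV -> GPRE (lambda12); covariance Cu <-> LMP.
#'
#' @return a [path_model()] with variables in the order
#'   Cu, LMP, SAM, GSH, CHH_DNMV, CHH_SV, GPRE.
#' @export
#' @examples
#' m <- triticale_gpre_model()
#' to_ram(m)$df   # 8
triticale_gpre_model <- function() {
  path_model(
    variables = c("Cu", "LMP", "SAM", "GSH", "CHH_DNMV", "CHH_SV", "GPRE"),
    paths = c(
      "LMP -> SAM [lambda1]",
      "Cu -> CHH_DNMV [lambda2]",
      "SAM -> CHH_DNMV [lambda3]",
      "Cu -> GSH [lambda4]",
      "CHH_DNMV -> CHH_SV [lambda5]",
      "SAM -> GSH [lambda6]",
      "Cu -> CHH_SV [lambda7]",
      "Cu -> GPRE [lambda8]",
      "GSH -> GPRE [lambda9]",
      "SAM -> GPRE [lambda10]",
      "CHH_DNMV -> GPRE [lambda11]",
      "CHH_SV -> GPRE [lambda12]"),
    covariances = "Cu <-> LMP [cov_Cu_LMP]")
}

#' Read / write a path model as JSON
#'
#' The on-disk form has keys `variables`, `paths` and `covariances`; each
#' edge is an object with `from`/`to` (or `a`/`b`) and `label`.
#'
#' @param model a [path_model()].
#' @param path file path.
#' @return `read_path_model` returns a validated [path_model()];
#'   `write_path_model` returns `path` invisibly.
#' @export
write_path_model <- function(model, path) {
  stopifnot(inherits(model, "path_model"))
  obj <- list(variables = model$variables,
              paths = model$paths,
              covariances = model$covariances)
  jsonlite::write_json(obj, path, dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname write_path_model
#' @export
read_path_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  covs <- obj$covariances
  if (is.null(covs) || NROW(covs) == 0L) covs <- NULL
  path_model(obj$variables, paths = obj$paths, covariances = covs)
}
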