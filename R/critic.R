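#' Bundle raw indicator matrices for CRITIC weighting
#'
#' Each indicator is an \eqn{h \times h} matrix of raw values for ordered
#' region pairs (entry \eqn{(m, s)} describes the pair from region m to
#' region s). Every indicator carries a risk direction: `"proportional"`
#' (larger raw value means more transmission risk, e.g. personnel flow) or
#' `"inverse"` (larger raw value means less risk, e.g. geographic distance).
#'
#' @param matrices a named list of numeric `h x h` matrices, all the same
#'   shape, finite entries.
#' @param directions character vector, one of `"proportional"`/`"inverse"`
#'   per indicator (recycled names from `matrices` if named).
#' @return an object of class `indicator_data`: list with `matrices`,
#'   `directions`, `h`, `t`.
#' @seealso [critic_weights()], [generate_synthetic_indicators()]
#' @export
indicator_data <- function(matrices,
                           directions = rep("proportional", length(matrices))) {
  if (!is.list(matrices) || length(matrices) == 0)
    stop("`matrices` must be a nonempty list of matrices", call. = FALSE)
  dims <- unique(lapply(matrices, dim))
  if (length(dims) != 1 || dims[[1]][1] != dims[[1]][2])
    stop("all indicator matrices must be square and share the same shape",
         call. = FALSE)
  if (!all(vapply(matrices, function(m) all(is.finite(m)), logical(1))))
    stop("indicator matrices must contain only finite values", call. = FALSE)
  directions <- match.arg(directions, c("proportional", "inverse"),
                          several.ok = TRUE)
  directions <- rep_len(directions, length(matrices))
  if (is.null(names(matrices)))
    names(matrices) <- paste0("indicator_", seq_along(matrices))
  names(directions) <- names(matrices)
  structure(list(matrices = matrices, directions = directions,
                 h = dims[[1]][1], t = length(matrices)),
            class = "indicator_data")
}

#' @export
print.indicator_data <- function(x, ...) {
  cat("Indicator data:", x$t, "indicators over", x$h, "regions\n")
  for (nm in names(x$matrices))
    cat("  -", nm, sprintf("(%s)\n", x$directions[[nm]]))
  invisible(x)
}

#' Min-max normalisation of one indicator matrix
#'
#' Maps raw values onto \eqn{[0, 1]} so that 1 always means "most risk".
#' For a proportional indicator \eqn{s = (b - \min b) / (\max b - \min b)};
#' for an inverse one \eqn{s = (\max b - b) / (\max b - \min b)}. The
#' minimum and maximum are taken over the entries of the whole matrix.
#'
#' @param B numeric matrix of raw values.
#' @param direction `"proportional"` or `"inverse"`.
#' @param include_diag include the diagonal in the min/max range (default
#'   `TRUE`); with `FALSE` the diagonal is ignored and returned as `NA`.
#' @return matrix of normalised values in \eqn{[0, 1]}.
#' @export
normalize_indicator <- function(B, direction = c("proportional", "inverse"),
                                include_diag = TRUE) {
  direction <- match.arg(direction)
  stopifnot(is.matrix(B), all(is.finite(B)))
  vals <- if (include_diag) B else B[row(B) != col(B)]
  lo <- min(vals); hi <- max(vals)
  if (hi == lo)
    stop("degenerate indicator: all entries equal, cannot normalise",
         call. = FALSE)
  S <- if (direction == "proportional") (B - lo) / (hi - lo)
       else (hi - B) / (hi - lo)
  if (!include_diag) S[row(S) == col(S)] <- NA_real_
  pmin(pmax(S, 0), 1)
}

#' Dispersion (contrast intensity) of a normalised indicator
#'
#' The sample standard deviation over all \eqn{h^2} entries of the
#' normalised matrix (denominator \eqn{h^2 - 1}). In CRITIC a larger
#' dispersion means the indicator discriminates more between region pairs
#' and so carries more information.
#'
#' @param S normalised indicator matrix (entries in \eqn{[0, 1]}; `NA`
#'   entries, e.g. an excluded diagonal, are dropped).
#' @return the standard deviation, a single nonnegative number.
#' @export
indicator_dispersion <- function(S) {
  v <- as.vector(S)
  v <- v[!is.na(v)]
  if (length(v) < 2)
    stop("need at least two entries to compute a dispersion", call. = FALSE)
  stats::sd(v)
}

#' Inter-indicator correlations and conflict measures
#'
#' The conflict of indicator i is \eqn{R_i = \sum_j (1 - r_{ij})} where
#' \eqn{r_{ij}} is the Pearson correlation between the flattened normalised
#' matrices of indicators i and j (the j = i term contributes 0). Indicators
#' that are strongly correlated with the others duplicate information and
#' receive low conflict.
#'
#' @param S_list list of normalised indicator matrices, same shape.
#' @return list with `r` (the \eqn{t \times t} correlation matrix) and
#'   `conflict` (vector of \eqn{R_i}).
#' @export
conflict_measures <- function(S_list) {
  if (!is.list(S_list) || length(S_list) < 2)
    stop("need at least two indicators to measure conflict", call. = FALSE)
  mat <- vapply(S_list, function(S) as.vector(S), numeric(length(S_list[[1]])))
  keep <- stats::complete.cases(mat)
  mat <- mat[keep, , drop = FALSE]
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0))
    stop("degenerate indicator: zero variance, correlation undefined",
         call. = FALSE)
  r <- stats::cor(mat)
  conflict <- rowSums(1 - r)
  if (!is.null(names(S_list))) names(conflict) <- names(S_list)
  list(r = r, conflict = conflict)
}

#' CRITIC objective weights from dispersion and conflict
#'
#' The information content of indicator i is \eqn{C_i = P_i R_i}
#' (dispersion times conflict) and its objective weight is
#' \eqn{w_i = C_i / \sum_j C_j}.
#'
#' @param dispersion vector of per-indicator dispersions \eqn{P_i}.
#' @param conflict vector of per-indicator conflicts \eqn{R_i}.
#' @return vector of weights summing to 1.
#' @export
critic_objective_weights <- function(dispersion, conflict) {
  stopifnot(length(dispersion) == length(conflict))
  C <- dispersion * conflict
  if (any(!is.finite(C)))
    stop("non-finite information content", call. = FALSE)
  if (sum(C) <= 0)
    stop("no information: all indicators have zero dispersion-conflict product",
         call. = FALSE)
  C / sum(C)
}

#' Correlation function between regions
#'
#' The correlation strength for each region pair is the weighted sum of the
#' normalised indicator values, \eqn{L_{m,s} = \sum_i w_i s_{i(ms)}}. As a
#' convex combination of values in \eqn{[0, 1]} it stays in \eqn{[0, 1]}.
#'
#' @param S_list list of normalised indicator matrices.
#' @param weights vector of CRITIC weights summing to 1.
#' @return the \eqn{h \times h} matrix of correlation strengths.
#' @export
correlation_function <- function(S_list, weights) {
  if (length(S_list) != length(weights))
    stop("one weight per indicator required", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-8 || any(weights < 0))
    stop("weights must be nonnegative and sum to 1", call. = FALSE)
  dims <- unique(lapply(S_list, dim))
  if (length(dims) != 1)
    stop("normalised matrices must share the same shape", call. = FALSE)
  L <- Reduce(`+`, Map(function(S, w) w * S, S_list, as.list(weights)))
  L
}

#' Derive correlation strengths from raw indicators via CRITIC
#'
#' Runs the full CRITIC pipeline: min-max normalisation of each indicator
#' (respecting its risk direction), per-indicator dispersion, pairwise
#' Pearson correlations and conflict, information content
#' \eqn{C_i = P_i R_i}, objective weights \eqn{w_i = C_i / \sum C_i}, and
#' finally the correlation-strength matrix
#' \eqn{L_{m,s} = \sum_i w_i s_{i(ms)}} used as edge weights in a
#' [risk_network()].
#'
#' Degenerate indicators (all raw entries equal) carry no information and
#' an undefined correlation; they are dropped with a warning and reported
#' with weight 0.
#'
#' @param data an [indicator_data()] object.
#' @param include_diag include diagonal entries (self-pairs) in the
#'   normalisation and dispersion statistics (default `TRUE`). Diagonal
#'   values of `L` are never used downstream either way (no self-loops).
#' @return an object of class `critic_result`: list with `S` (normalised
#'   matrices for the retained indicators), `dispersion`, `r`, `conflict`,
#'   `info` (\eqn{C_i}), `weights` (over all original indicators; dropped
#'   ones get 0), `L`, and `dropped` (names of dropped indicators).
#' @export
#' @examples
#' ind <- generate_synthetic_indicators(h = 6, seed = 1)
#' cw <- critic_weights(ind)
#' round(cw$weights, 3)
critic_weights <- function(data, include_diag = TRUE) {
  stopifnot(inherits(data, "indicator_data"))
  nm <- names(data$matrices)
  degenerate <- vapply(data$matrices, function(B) {
    vals <- if (include_diag) B else B[row(B) != col(B)]
    max(vals) == min(vals)
  }, logical(1))
  if (any(degenerate))
    warning("dropping degenerate (constant) indicator(s): ",
            paste(nm[degenerate], collapse = ", "), call. = FALSE)
  keep <- nm[!degenerate]
  if (length(keep) < 2)
    stop("need at least two non-degenerate indicators", call. = FALSE)
  S <- Map(function(B, d) normalize_indicator(B, d, include_diag),
           data$matrices[keep], data$directions[keep])
  P <- vapply(S, indicator_dispersion, numeric(1))
  cm <- conflict_measures(S)
  w_keep <- critic_objective_weights(P, cm$conflict)
  weights <- stats::setNames(numeric(length(nm)), nm)
  weights[keep] <- w_keep
  L <- correlation_function(S, w_keep)
  structure(list(S = S, dispersion = P, r = cm$r, conflict = cm$conflict,
                 info = P * cm$conflict, weights = weights, L = L,
                 dropped = nm[degenerate]),
            class = "critic_result")
}

#' @export
print.critic_result <- function(x, digits = 4, ...) {
  cat("CRITIC objective weights over", length(x$weights), "indicator(s):\n")
  print(round(x$weights, digits))
  if (length(x$dropped))
    cat("dropped (degenerate):", paste(x$dropped, collapse = ", "), "\n")
  cat("correlation strengths L in [",
      round(min(x$L, na.rm = TRUE), digits), ",",
      round(max(x$L, na.rm = TRUE), digits), "]\n")
  invisible(x)
}
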