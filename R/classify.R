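#' Risk-level thresholds
#'
#' The three-level scale: a node is high risk when its (rounded) risk value
#' is at least `p_s1`, medium when it is at least `p_s2` but below `p_s1`,
#' and low otherwise. Both bounds are closed from below.
#'
#' @param p_s1 high-risk lower bound, in \eqn{(0, 1]}. Default 0.7.
#' @param p_s2 medium-risk lower bound, in \eqn{(0, p_s1)}. Default 0.4.
#' @return object of class `risk_thresholds`.
#' @export
risk_thresholds <- function(p_s1 = 0.7, p_s2 = 0.4) {
  p_s1 <- as.numeric(p_s1); p_s2 <- as.numeric(p_s2)
  if (length(p_s1) != 1 || length(p_s2) != 1 ||
      !is.finite(p_s1) || !is.finite(p_s2) ||
      !(0 < p_s2 && p_s2 < p_s1 && p_s1 <= 1))
    stop("thresholds must satisfy 0 < p_s2 < p_s1 <= 1", call. = FALSE)
  structure(list(p_s1 = p_s1, p_s2 = p_s2), class = "risk_thresholds")
}

#' @export
print.risk_thresholds <- function(x, ...) {
  cat(sprintf("Risk thresholds: high >= %.4g, medium >= %.4g, low below\n",
              x$p_s1, x$p_s2))
  invisible(x)
}

# round-half-up to `dp` decimals (base round() is round-half-even);
# dp = NULL disables rounding
round_half_up <- function(x, dp) {
  if (is.null(dp)) return(x)
  f <- 10^dp
  floor(x * f + 0.5) / f
}

#' Classify risk values into high / medium / low
#'
#' Risk values are first rounded half-up to `round_dp` decimals, then
#' compared against the thresholds with closed lower bounds (a rounded
#' value exactly equal to `p_s1` is high; exactly `p_s2` is medium). The
#' default 2-decimal rounding matches how reported risk values are usually
#' read off; set `round_dp = NULL` for strict full-precision comparison.
#'
#' @param p numeric vector of risk values in \eqn{[0, 1]}.
#' @param thresholds a [risk_thresholds()] object (or anything coercible by
#'   `risk_thresholds(p_s1, p_s2)` given as a length-2 numeric vector).
#' @param round_dp decimals for half-up rounding before comparison
#'   (default 2), or `NULL` for no rounding.
#' @return factor with levels `high`, `medium`, `low`.
#' @export
#' @examples
#' classify_risk(c(1, 0.7117, 0.39972, 0.39), risk_thresholds(0.7, 0.4))
classify_risk <- function(p, thresholds = risk_thresholds(), round_dp = 2) {
  if (is.numeric(thresholds) && length(thresholds) == 2)
    thresholds <- risk_thresholds(thresholds[1], thresholds[2])
  stopifnot(inherits(thresholds, "risk_thresholds"))
  check_unit("p", p)
  q <- round_half_up(p, round_dp)
  lev <- ifelse(q >= thresholds$p_s1, "high",
                ifelse(q >= thresholds$p_s2, "medium", "low"))
  factor(lev, levels = c("high", "medium", "low"))
}

#' Summarise per-node levels into a risk report
#'
#' @param node integer vector of node IDs.
#' @param level factor (or character) of levels `high`/`medium`/`low`, one
#'   per node.
#' @param thresholds the [risk_thresholds()] used.
#' @param round_dp the rounding precision used (or `NULL`).
#' @return object of class `risk_report`: list with `levels` (named lists
#'   of node IDs per level, sorted), `counts`, `thresholds`, `round_dp`.
#' @export
risk_report <- function(node, level, thresholds = risk_thresholds(),
                        round_dp = 2) {
  level <- factor(as.character(level), levels = c("high", "medium", "low"))
  if (anyNA(level) || length(level) != length(node))
    stop("every node needs one level among high/medium/low", call. = FALSE)
  node <- as.integer(node)
  lists <- lapply(split(node, level), sort)
  structure(list(levels = lists,
                 counts = vapply(lists, length, integer(1)),
                 thresholds = thresholds, round_dp = round_dp),
            class = "risk_report")
}

#' @export
print.risk_report <- function(x, ...) {
  cat("Risk report (high >=", x$thresholds$p_s1,
      "| medium >=", x$thresholds$p_s2, "):\n")
  for (lv in names(x$levels))
    cat(sprintf("  %-6s %3d  %s\n", lv, x$counts[[lv]],
                paste(x$levels[[lv]], collapse = " ")))
  invisible(x)
}
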