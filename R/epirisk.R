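#' Fit the regional epidemic risk-classification model
#'
#' The central entry point: given a weighted region network and a set of
#' outbreak source regions, `epirisk()` (i) layers the network by
#' shortest-path distance to the nearest source, (ii) orients every edge
#' along the direction of spread, (iii) propagates risk values outward with
#' the single-parent / multi-parent attenuation rules and the two-pass
#' loop-node rule, and (iv) grades every region high / medium / low against
#' the thresholds. The result is a classed object with the usual
#' `print()`, `summary()`, `plot()` and `as.data.frame()` methods.
#'
#' @param net a [risk_network()] with all edge weights set.
#' @param sources outbreak source node IDs (risk fixed at 1).
#' @param thresholds a [risk_thresholds()] object or length-2 numeric
#'   `c(p_s1, p_s2)`. Default `(0.7, 0.4)`.
#' @param round_dp decimals of half-up rounding applied before
#'   classification (default 2; `NULL` for none). See [classify_risk()].
#' @return an object of class `epirisk`: list with `network`, `sources`,
#'   `layers`, `oriented`, `propagation` ([propagate()] result), `values`
#'   (data frame `node`, `layer`, `p_pre`, `p_final`, `level`), `report`
#'   ([risk_report()]), `thresholds`, `round_dp`.
#' @export
#' @examples
#' bm <- benchmark_network(1)
#' fit <- epirisk(bm, sources = 1)
#' fit
#' summary(fit)
epirisk <- function(net, sources, thresholds = risk_thresholds(),
                    round_dp = 2) {
  stopifnot(inherits(net, "risk_network"))
  if (is.numeric(thresholds) && length(thresholds) == 2)
    thresholds <- risk_thresholds(thresholds[1], thresholds[2])
  layers <- assign_layers(net, sources)
  oriented <- orient_edges(net, layers)
  prop <- propagate(oriented)
  values <- prop$values
  values$level <- classify_risk(values$p_final, thresholds, round_dp)
  report <- risk_report(values$node, values$level, thresholds, round_dp)
  structure(list(network = net, sources = layers$sources, layers = layers,
                 oriented = oriented, propagation = prop, values = values,
                 report = report, thresholds = thresholds,
                 round_dp = round_dp),
            class = "epirisk")
}

#' @export
print.epirisk <- function(x, ...) {
  cat("Regional epidemic risk classification\n")
  cat("  network :", length(x$network$nodes), "regions,",
      nrow(x$network$edges), "edges\n")
  cat("  sources :", paste(x$sources, collapse = ", "), "\n")
  cat("  levels  : high", x$report$counts[["high"]],
      "| medium", x$report$counts[["medium"]],
      "| low", x$report$counts[["low"]], "\n")
  invisible(x)
}

#' @export
summary.epirisk <- function(object, ...) {
  structure(list(fit = object), class = "summary.epirisk")
}

#' @export
print.summary.epirisk <- function(x, ...) {
  fit <- x$fit
  print(fit)
  print(fit$thresholds)
  cat("  rounding:",
      if (is.null(fit$round_dp)) "none" else paste0(fit$round_dp, " dp"),
      "\n\n")
  print(fit$report)
  v <- fit$values
  reached <- !is.na(v$layer)
  cat(sprintf("\nLayers: %d (max); unreached regions: %d\n",
              if (any(reached)) max(v$layer[reached]) else 0L,
              sum(!reached)))
  invisible(x)
}

#' @export
as.data.frame.epirisk <- function(x, ...) x$values

#' Extract per-node risk values or levels
#'
#' @param fit an [epirisk()] object.
#' @return `risk_values()`: named numeric vector of final risk values;
#'   `risk_levels()`: named factor of levels.
#' @export
risk_values <- function(fit) {
  stopifnot(inherits(fit, "epirisk"))
  stats::setNames(fit$values$p_final, fit$values$node)
}

#' @rdname risk_values
#' @export
risk_levels <- function(fit) {
  stopifnot(inherits(fit, "epirisk"))
  stats::setNames(fit$values$level, fit$values$node)
}

#' Plot per-region risk values
#'
#' Draws the final risk value of every region against its ID, coloured by
#' risk level, with horizontal lines at the two thresholds.
#'
#' @param x an [epirisk()] object.
#' @param ... passed on to [graphics::plot()].
#' @export
plot.epirisk <- function(x, ...) {
  v <- x$values
  cols <- c(high = "#d73027", medium = "#fc8d59", low = "#4575b4")
  graphics::plot(v$node, v$p_final, pch = 19, col = cols[as.character(v$level)],
                 xlab = "region", ylab = "risk value p", ylim = c(0, 1), ...)
  graphics::abline(h = c(x$thresholds$p_s1, x$thresholds$p_s2), lty = 2,
                   col = "grey40")
  graphics::legend("topright", legend = names(cols), col = cols, pch = 19,
                   bty = "n")
  invisible(x)
}
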