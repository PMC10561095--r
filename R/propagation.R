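#' Risk transmitted through a single parent
#'
#' A node influenced by exactly one upstream region inherits its risk
#' attenuated by the correlation strength of the connecting edge:
#' \eqn{p_s = p_m L_{m,s}}.
#'
#' @param p_m risk value of the transmitting node, in \eqn{[0, 1]}.
#' @param L correlation strength of the edge, in \eqn{[0, 1]}.
#' @return the receiving node's risk value.
#' @export
#' @examples
#' single_parent_risk(1, 0.7117)
single_parent_risk <- function(p_m, L) {
  check_unit("p_m", p_m)
  check_unit("L", L)
  p_m * L
}

#' Risk transmitted through multiple parents
#'
#' When several upstream regions influence a node, each parent's
#' contribution is scaled by its normalised association weight
#' \eqn{l_n = L_n / \sum_k L_k}, and the node's risk is
#' \eqn{p_s = \sum_n p_n l_n L_n}. With a single parent this reduces to
#' [single_parent_risk()]. The result is a convex combination of the
#' \eqn{p_n L_n} terms and never exceeds the largest parent risk.
#'
#' @param p vector of parent risk values in \eqn{[0, 1]}.
#' @param L vector of parent correlation strengths in \eqn{[0, 1]},
#'   not all zero.
#' @return the receiving node's risk value.
#' @export
#' @examples
#' multi_parent_risk(c(1, 1), c(0.7117, 0.8179))
multi_parent_risk <- function(p, L) {
  if (length(p) == 0 || length(p) != length(L))
    stop("`p` and `L` must be nonempty vectors of equal length", call. = FALSE)
  check_unit("p", p)
  check_unit("L", L)
  sL <- sum(L)
  if (sL == 0)
    stop("degenerate parent set: all correlation strengths are zero",
         call. = FALSE)
  sum(p * (L / sL) * L)
}

check_unit <- function(name, x) {
  if (anyNA(x) || any(!is.finite(x) | x < 0 | x > 1))
    stop("`", name, "` must lie in [0, 1]", call. = FALSE)
  invisible(x)
}

#' Propagate epidemic risk outward from the outbreak sources
#'
#' Sources carry risk 1. Risk then flows layer by layer along the downhill
#' orientation: a node with one lower-layer parent gets
#' \eqn{p_s = p_m L_{m,s}} and a node with several gets the weighted
#' combination of [multi_parent_risk()]. Same-layer ("loop") edges are
#' bidirectional and handled in a second pass: first every node's pre-loop
#' risk is computed ignoring loop edges, then each node with loop partners
#' is re-evaluated over its lower-layer parents plus its loop partners,
#' the partners contributing their pre-loop values. This two-pass loop rule
#' is a reconstruction (the underlying method leaves the same-layer case
#' open); see the package vignette for the rationale and the alternatives
#' that were rejected. Nodes unreachable from every source get risk 0.
#'
#' @param oriented an [orient_edges()] result (which carries its
#'   [assign_layers()] result).
#' @param sources optional; must match the source set the orientation was
#'   built from (defaults to it).
#' @return an object of class `propagation_result`: list with `values`
#'   (data frame `node`, `layer`, `p_pre`, `p_final`), `parents` (per-node
#'   list of data frames `parent`, `L`, `l` giving the normalised
#'   association weights actually used in the final evaluation), `order`
#'   (node evaluation order) and `sources`.
#' @export
#' @examples
#' bm <- benchmark_network(1)
#' pr <- propagate(orient_edges(bm, assign_layers(bm, 1)))
#' head(pr$values)
propagate <- function(oriented, sources = NULL) {
  stopifnot(inherits(oriented, "oriented_network"))
  layers <- oriented$layers
  if (is.null(sources)) sources <- layers$sources
  sources <- sort(unique(as.integer(sources)))
  if (!identical(sources, layers$sources))
    stop("`sources` disagree with the source set the orientation was built from",
         call. = FALSE)
  if (anyNA(oriented$edges$weight))
    stop("all edge weights must be set before propagation", call. = FALSE)
  nodes <- oriented$nodes
  lay <- layers$layer
  ord <- nodes[order(lay[as.character(nodes)], nodes, na.last = TRUE)]
  p_pre <- stats::setNames(numeric(length(nodes)), nodes)
  # pass 1: layered evaluation over downhill edges only
  for (v in ord) {
    key <- as.character(v)
    if (v %in% sources) { p_pre[key] <- 1; next }
    if (is.na(lay[key])) { p_pre[key] <- 0; next }
    par <- layers$parents[[key]]
    if (length(par) == 0) { p_pre[key] <- 0; next }
    Lp <- edge_weight(oriented, rep(v, length(par)), par)
    p_pre[key] <- combine_parent_risk(p_pre[as.character(par)], Lp)
  }
  # pass 2: re-evaluate loop-edge endpoints with partners at pre-loop values
  p_final <- p_pre
  used <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) {
    key <- as.character(v)
    lp <- layers$loop_partners[[key]]
    par <- layers$parents[[key]]
    if (v %in% sources || is.na(lay[key])) next
    if (length(lp) > 0) {
      all_par <- c(par, lp)
      Lp <- edge_weight(oriented, rep(v, length(all_par)), all_par)
      p_in <- p_pre[as.character(all_par)]
      p_final[key] <- combine_parent_risk(p_in, Lp)
      used[[key]] <- parent_table(all_par, Lp)
    } else if (length(par) > 0) {
      Lp <- edge_weight(oriented, rep(v, length(par)), par)
      used[[key]] <- parent_table(par, Lp)
    }
  }
  values <- data.frame(node = nodes,
                       layer = unname(lay[as.character(nodes)]),
                       p_pre = unname(p_pre[as.character(nodes)]),
                       p_final = unname(p_final[as.character(nodes)]))
  structure(list(values = values, parents = used, order = ord,
                 sources = sources),
            class = "propagation_result")
}

# Eq-style combination with the zero-strength degenerate case mapped to 0
# (a node whose only connections carry L = 0 is reachable but receives
# nothing)
combine_parent_risk <- function(p, L) {
  if (sum(L) == 0) return(0)
  multi_parent_risk(p, L)
}

parent_table <- function(par, L) {
  l <- if (sum(L) > 0) L / sum(L) else rep(0, length(L))
  data.frame(parent = par, L = L, l = l)
}

#' @export
print.propagation_result <- function(x, digits = 4, ...) {
  v <- x$values
  cat("Risk propagation from source(s)",
      paste(x$sources, collapse = ", "), "->",
      nrow(v), "nodes\n")
  cat("  risk range [", round(min(v$p_final), digits), ",",
      round(max(v$p_final), digits), "]\n")
  invisible(x)
}
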