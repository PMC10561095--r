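#' Construct a region risk network
#'
#' A risk network represents regions as nodes and social connections between
#' regions as undirected weighted edges. The edge weight is the correlation
#' strength \eqn{L_{m,s} \in [0, 1]} between the two regions, which acts as
#' the attenuation factor for epidemic risk transmitted along the edge.
#'
#' @param edges a data frame with columns `source`, `target` and optionally
#'   `weight`. Each row is one undirected edge; `source`/`target` are positive
#'   integer region IDs. Weights, when present, must lie in \eqn{[0, 1]}.
#'   Missing weights are stored as `NA` and must be set (see
#'   [set_edge_weights()]) before risk propagation.
#' @param nodes optional integer vector of node IDs. Defaults to the IDs
#'   referenced by `edges`; extra isolated nodes may be listed here.
#'
#' @return an object of class `risk_network`: a list with elements `nodes`
#'   (sorted integer vector) and `edges` (data frame `source`, `target`,
#'   `weight` with `source < target`).
#' @seealso [generate_scale_free()], [read_edge_csv()], [benchmark_network()]
#' @export
#' @examples
#' net <- risk_network(data.frame(source = c(1, 1), target = c(2, 3),
#'                                weight = c(0.8, 0.3)))
#' net
risk_network <- function(edges, nodes = NULL) {
  if (!is.data.frame(edges) || !all(c("source", "target") %in% names(edges)))
    stop("`edges` must be a data frame with columns `source` and `target`",
         call. = FALSE)
  src <- as.integer(edges$source)
  tgt <- as.integer(edges$target)
  if (nrow(edges) > 0 && (anyNA(src) || anyNA(tgt) || any(src < 1) || any(tgt < 1)))
    stop("node IDs must be positive integers", call. = FALSE)
  if (any(src == tgt))
    stop("self-loops are not allowed", call. = FALSE)
  w <- if ("weight" %in% names(edges)) as.numeric(edges$weight)
       else rep(NA_real_, nrow(edges))
  bad <- !is.na(w) & (!is.finite(w) | w < 0 | w > 1)
  if (any(bad))
    stop("edge weights must be finite and in [0, 1]; offending rows: ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  # canonical order source < target so duplicate undirected pairs collide
  lo <- pmin(src, tgt)
  hi <- pmax(src, tgt)
  key <- paste(lo, hi)
  if (anyDuplicated(key))
    stop("duplicate undirected edge(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  nodes <- if (is.null(nodes)) sort(unique(c(lo, hi)))
           else sort(unique(as.integer(nodes)))
  if (anyNA(nodes) || any(nodes < 1))
    stop("node IDs must be positive integers", call. = FALSE)
  if (!all(c(lo, hi) %in% nodes))
    stop("edges reference node IDs absent from the node set", call. = FALSE)
  ed <- data.frame(source = lo, target = hi, weight = w)
  ed <- ed[order(ed$source, ed$target), , drop = FALSE]
  rownames(ed) <- NULL
  structure(list(nodes = nodes, edges = ed), class = "risk_network")
}

#' @export
print.risk_network <- function(x, ...) {
  nw <- sum(!is.na(x$edges$weight))
  cat("Region risk network:", length(x$nodes), "nodes,",
      nrow(x$edges), "undirected edges",
      sprintf("(%d weighted)\n", nw))
  invisible(x)
}

#' Replace or assign correlation-strength edge weights
#'
#' @param net a [risk_network()].
#' @param L either a square numeric matrix of correlation strengths indexed
#'   by node ID (e.g. the `L` component of [critic_weights()]), or a numeric
#'   vector with one weight per edge of `net` (in the order of `net$edges`).
#' @return `net` with the `weight` column filled in.
#' @export
set_edge_weights <- function(net, L) {
  stopifnot(inherits(net, "risk_network"))
  e <- net$edges
  if (is.matrix(L)) {
    if (nrow(L) != ncol(L) || max(net$nodes) > nrow(L))
      stop("`L` matrix does not cover all node IDs", call. = FALSE)
    w <- L[cbind(e$source, e$target)]
  } else {
    w <- as.numeric(L)
    if (length(w) != nrow(e))
      stop("need one weight per edge (", nrow(e), ")", call. = FALSE)
  }
  if (anyNA(w) || any(!is.finite(w) | w < 0 | w > 1))
    stop("weights must be finite and in [0, 1]", call. = FALSE)
  net$edges$weight <- w
  net
}

# run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a scale-free network by preferential attachment
#'
#' Grows a network from a two-node seed: each new node attaches to
#' `edges_per_new_node` distinct existing nodes, sampled without replacement
#' with probability proportional to current degree
#' \eqn{P(k_s) = k_s / \sum_m k_m} (probabilities renormalised after each
#' draw). The resulting degree distribution is right-skewed, approximating
#' the power-law degree distribution of real social contact networks.
#'
#' Edge weights are left unset; attach correlation strengths with
#' [set_edge_weights()] (for example from [critic_weights()]).
#'
#' @param n_nodes number of regions, at least 2.
#' @param edges_per_new_node edges added with each new node, at least 1.
#'   When a new node arrives, it attaches to
#'   `min(edges_per_new_node, current node count)` targets. With the default
#'   1 the result is a tree with `n_nodes - 1` edges.
#' @param seed optional integer; the same seed always yields the same
#'   network, and the caller's RNG state is left untouched.
#' @return a [risk_network()] with `NA` weights.
#' @export
#' @examples
#' net <- generate_scale_free(50, seed = 1)
#' net
generate_scale_free <- function(n_nodes, edges_per_new_node = 1, seed = NULL) {
  n_nodes <- as.integer(n_nodes)
  m <- as.integer(edges_per_new_node)
  if (is.na(n_nodes) || n_nodes < 2)
    stop("`n_nodes` must be an integer >= 2", call. = FALSE)
  if (is.na(m) || m < 1)
    stop("`edges_per_new_node` must be an integer >= 1", call. = FALSE)
  with_seed(seed, {
    deg <- integer(n_nodes)
    deg[1:2] <- 1L
    from <- integer(0); to <- integer(0)
    from[1] <- 1L; to[1] <- 2L
    for (v in seq_len(n_nodes)[-(1:2)]) {
      existing <- seq_len(v - 1L)
      k <- min(m, v - 1L)
      targets <- if (length(existing) == 1L) existing
                 else sample(existing, k, replace = FALSE, prob = deg[existing])
      from <- c(from, rep(v, k))
      to <- c(to, targets)
      deg[targets] <- deg[targets] + 1L
      deg[v] <- k
    }
    risk_network(data.frame(source = from, target = to),
                 nodes = seq_len(n_nodes))
  })
}

# adjacency list: for each node (by ID), integer vector of neighbour IDs
adjacency_list <- function(net) {
  n <- max(net$nodes)
  adj <- vector("list", n)
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$source[i]; b <- net$edges$target[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# weight lookup for an unordered pair; vectorised over (a, b)
edge_weight <- function(net, a, b) {
  key <- paste(pmin(a, b), pmax(a, b))
  idx <- match(key, paste(net$edges$source, net$edges$target))
  net$edges$weight[idx]
}

#' Assign propagation layers by distance to the nearest outbreak source
#'
#' Layers order the network for risk propagation: sources sit in layer 0 and
#' every other node's layer is its shortest-path distance (in edges) to the
#' nearest source, found by multi-source breadth-first search. A node's
#' parents are all its neighbours in strictly lower layers (the nodes that
#' transmit risk to it); its loop partners are neighbours in the same layer,
#' where transmission is bidirectional and handled by a dedicated rule
#' (see [propagate()]).
#'
#' @param net a [risk_network()].
#' @param sources nonempty vector of outbreak source node IDs.
#' @return an object of class `layer_assignment`: list with `layer` (integer
#'   vector named by node ID, `NA` for nodes unreachable from every source),
#'   `parents` and `loop_partners` (lists of integer vectors named by node
#'   ID), and `sources`.
#' @export
assign_layers <- function(net, sources) {
  stopifnot(inherits(net, "risk_network"))
  sources <- sort(unique(as.integer(sources)))
  if (length(sources) == 0)
    stop("`sources` must be a nonempty set of node IDs", call. = FALSE)
  if (!all(sources %in% net$nodes))
    stop("unknown source node(s): ",
         paste(setdiff(sources, net$nodes), collapse = ", "), call. = FALSE)
  adj <- adjacency_list(net)
  layer <- rep(NA_integer_, max(net$nodes))
  layer[sources] <- 0L
  frontier <- sources
  d <- 0L
  while (length(frontier) > 0) {
    d <- d + 1L
    nxt <- integer(0)
    for (v in frontier) {
      for (u in adj[[v]]) {
        if (is.na(layer[u])) {
          layer[u] <- d
          nxt <- c(nxt, u)
        }
      }
    }
    frontier <- nxt
  }
  layer <- layer[net$nodes]
  names(layer) <- net$nodes
  parents <- loops <- stats::setNames(vector("list", length(net$nodes)),
                                      net$nodes)
  for (v in net$nodes) {
    key <- as.character(v)
    nb <- adj[[v]]
    if (is.null(nb) || is.na(layer[key])) {
      parents[[key]] <- integer(0); loops[[key]] <- integer(0)
      next
    }
    lv <- layer[key]
    lnb <- layer[as.character(nb)]
    parents[[key]] <- sort(nb[!is.na(lnb) & lnb < lv])
    loops[[key]] <- sort(nb[!is.na(lnb) & lnb == lv])
  }
  structure(list(layer = layer, parents = parents, loop_partners = loops,
                 sources = sources),
            class = "layer_assignment")
}

#' @export
print.layer_assignment <- function(x, ...) {
  reached <- !is.na(x$layer)
  cat("Layer assignment from", length(x$sources), "source(s):",
      sum(reached), "reached nodes,", sum(!reached), "unreached;",
      "max layer", if (any(reached)) max(x$layer[reached]) else NA, "\n")
  invisible(x)
}

#' Orient edges along the direction of epidemic spread
#'
#' Risk flows from lower layers to higher layers, so every edge joining
#' nodes of different layers is directed from the lower-layer endpoint to
#' the higher-layer endpoint ("downhill"). Edges joining nodes of the same
#' layer are labelled `loop`: transmission across them is bidirectional and
#' the plain layered rules do not apply (see [propagate()]). The downhill
#' edge set is acyclic by construction. The orientation depends on the
#' outbreak sources and is recomputed for every source set.
#'
#' @param net a [risk_network()].
#' @param layers a [assign_layers()] result computed on `net`.
#' @return an object of class `oriented_network`: the network plus a
#'   data frame `arcs` with columns `from`, `to`, `weight` and `kind`
#'   (`"downhill"` or `"loop"`; loop arcs keep `from < to` but carry risk
#'   both ways). Edges with an unreached endpoint get kind `"unreached"`.
#' @export
orient_edges <- function(net, layers) {
  stopifnot(inherits(net, "risk_network"), inherits(layers, "layer_assignment"))
  e <- net$edges
  la <- layers$layer[as.character(e$source)]
  lb <- layers$layer[as.character(e$target)]
  from <- e$source; to <- e$target
  kind <- rep("downhill", nrow(e))
  swap <- !is.na(la) & !is.na(lb) & la > lb
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  kind[!is.na(la) & !is.na(lb) & la == lb] <- "loop"
  kind[is.na(la) | is.na(lb)] <- "unreached"
  arcs <- data.frame(from = from, to = to, weight = e$weight, kind = kind)
  structure(list(nodes = net$nodes, edges = e, arcs = arcs,
                 layers = layers),
            class = c("oriented_network", "risk_network"))
}

#' @export
print.oriented_network <- function(x, ...) {
  cat("Oriented risk network:", length(x$nodes), "nodes;",
      sum(x$arcs$kind == "downhill"), "downhill arcs,",
      sum(x$arcs$kind == "loop"), "loop edges\n")
  invisible(x)
}

#' Degree and strength metrics for network nodes
#'
#' Degree \eqn{k_m} is the number of edges incident to node \eqn{m};
#' strength \eqn{s_m} is the sum of their weights. On an oriented network
#' the in-degree/in-strength count arcs ending at the node and the
#' out-degree/out-strength arcs starting from it; a bidirectional loop edge
#' contributes to both directions.
#'
#' @param net a [risk_network()] or [orient_edges()] result.
#' @param nodes node IDs to report (default all).
#' @return a data frame with one row per node: `node`, `degree`, `strength`,
#'   and on an oriented network also `in_degree`, `out_degree`,
#'   `in_strength`, `out_strength`.
#' @export
node_metrics <- function(net, nodes = net$nodes) {
  stopifnot(inherits(net, "risk_network"))
  nodes <- as.integer(nodes)
  if (!all(nodes %in% net$nodes))
    stop("unknown node(s): ", paste(setdiff(nodes, net$nodes), collapse = ", "),
         call. = FALSE)
  e <- net$edges
  w <- ifelse(is.na(e$weight), 0, e$weight)
  deg <- function(ids) tabulate(ids, nbins = max(net$nodes))
  k <- deg(e$source) + deg(e$target)
  s <- rowsum_by(e$source, w, max(net$nodes)) + rowsum_by(e$target, w, max(net$nodes))
  out <- data.frame(node = nodes, degree = k[nodes], strength = s[nodes])
  if (inherits(net, "oriented_network")) {
    a <- net$arcs
    down <- a[a$kind == "downhill", , drop = FALSE]
    loop <- a[a$kind == "loop", , drop = FALSE]
    aw <- ifelse(is.na(a$weight), 0, a$weight)
    dn_w <- ifelse(is.na(down$weight), 0, down$weight)
    lp_w <- ifelse(is.na(loop$weight), 0, loop$weight)
    n <- max(net$nodes)
    k_in <- deg(down$to) + deg(loop$from) + deg(loop$to)
    k_out <- deg(down$from) + deg(loop$from) + deg(loop$to)
    s_in <- rowsum_by(down$to, dn_w, n) +
      rowsum_by(loop$from, lp_w, n) + rowsum_by(loop$to, lp_w, n)
    s_out <- rowsum_by(down$from, dn_w, n) +
      rowsum_by(loop$from, lp_w, n) + rowsum_by(loop$to, lp_w, n)
    out$in_degree <- k_in[nodes]
    out$out_degree <- k_out[nodes]
    out$in_strength <- s_in[nodes]
    out$out_strength <- s_out[nodes]
  }
  rownames(out) <- NULL
  out
}

rowsum_by <- function(ids, vals, n) {
  out <- numeric(n)
  if (length(ids)) {
    agg <- rowsum(vals, ids)
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out
}
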