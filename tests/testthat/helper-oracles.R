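# Independent oracles used across the suite. They deliberately share no code
# with the package internals: layers come from igraph's shortest-path
# machinery and risk values from a plain recursive evaluator.

# random connected network: spanning tree over n nodes plus up to
# `extra_edges` additional edges, uniform weights
random_network <- function(n, extra_edges = 2) {
  stopifnot(n >= 2)
  from <- to <- integer(0)
  for (v in 2:n) {
    from <- c(from, sample(v - 1L, 1))
    to <- c(to, v)
  }
  pairs <- paste(pmin(from, to), pmax(from, to))
  all_pairs <- t(utils::combn(n, 2))
  avail <- !(paste(all_pairs[, 1], all_pairs[, 2]) %in% pairs)
  k <- min(extra_edges, sum(avail))
  if (k > 0) {
    pick <- which(avail)[sample(sum(avail), sample(0:k, 1))]
    from <- c(from, all_pairs[pick, 1])
    to <- c(to, all_pairs[pick, 2])
  }
  risk_network(data.frame(source = from, target = to,
                          weight = round(runif(length(from)), 4)))
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("source", "target")], directed = FALSE,
    vertices = data.frame(name = net$nodes))
}

# layers by igraph all-pairs shortest paths (oracle for assign_layers)
oracle_layers <- function(net, sources) {
  g <- as_igraph(net)
  d <- igraph::distances(g, v = as.character(sources))
  lay <- apply(d, 2, min)
  lay[!is.finite(lay)] <- NA
  lay[as.character(net$nodes)]
}

# recursive two-pass risk evaluation (oracle for propagate)
oracle_propagate <- function(net, sources) {
  lay <- oracle_layers(net, sources)
  wt <- function(a, b) {
    e <- net$edges
    i <- which((e$source == a & e$target == b) | (e$source == b & e$target == a))
    e$weight[i]
  }
  nbrs <- function(v) {
    e <- net$edges
    c(e$target[e$source == v], e$source[e$target == v])
  }
  combine <- function(p, L) if (sum(L) == 0) 0 else sum(p * (L / sum(L)) * L)
  pre <- function(v) {
    if (v %in% sources) return(1)
    lv <- lay[[as.character(v)]]
    if (is.na(lv)) return(0)
    par <- Filter(function(u) {
      lu <- lay[[as.character(u)]]
      !is.na(lu) && lu < lv
    }, nbrs(v))
    if (length(par) == 0) return(0)
    combine(vapply(par, pre, numeric(1)),
            vapply(par, function(u) wt(u, v), numeric(1)))
  }
  final <- function(v) {
    if (v %in% sources) return(1)
    lv <- lay[[as.character(v)]]
    if (is.na(lv)) return(0)
    nb <- nbrs(v)
    lnb <- lay[as.character(nb)]
    par <- nb[!is.na(lnb) & lnb < lv]
    loop <- nb[!is.na(lnb) & lnb == lv]
    if (length(loop) == 0) return(pre(v))
    allp <- c(par, loop)
    combine(c(vapply(par, pre, numeric(1)), vapply(loop, pre, numeric(1))),
            vapply(allp, function(u) wt(u, v), numeric(1)))
  }
  vapply(net$nodes, final, numeric(1))
}

# single-pass CRITIC recomputation with explicit loops (oracle for
# critic_weights on non-degenerate input)
oracle_critic <- function(mats, directions) {
  t <- length(mats)
  S <- vector("list", t)
  for (i in seq_len(t)) {
    B <- mats[[i]]
    lo <- min(B); hi <- max(B)
    S[[i]] <- if (directions[i] == "proportional") (B - lo) / (hi - lo)
              else (hi - B) / (hi - lo)
  }
  P <- numeric(t)
  for (i in seq_len(t)) {
    v <- as.vector(S[[i]])
    m <- sum(v) / length(v)
    P[i] <- sqrt(sum((v - m)^2) / (length(v) - 1))
  }
  R <- numeric(t)
  for (i in seq_len(t)) {
    for (j in seq_len(t)) {
      x <- as.vector(S[[i]]); y <- as.vector(S[[j]])
      mx <- mean(x); my <- mean(y)
      r <- sum((x - mx) * (y - my)) /
        sqrt(sum((x - mx)^2) * sum((y - my)^2))
      R[i] <- R[i] + (1 - r)
    }
  }
  C <- P * R
  w <- C / sum(C)
  L <- 0 * mats[[1]]
  for (i in seq_len(t)) L <- L + w[i] * S[[i]]
  list(S = S, P = P, R = R, w = w, L = L)
}

# evaluate `expr` under set.seed(seed) without disturbing the ambient stream
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# weight of the undirected edge {a, b}
edge_w <- function(net, a, b) {
  e <- net$edges
  e$weight[e$source == min(a, b) & e$target == max(a, b)]
}

tiny_net <- function() {
  # path 1-2-3 plus triangle edge 3-4, 2-4: layers from 1 are 0,1,2,2
  risk_network(data.frame(source = c(1, 2, 3, 2),
                          target = c(2, 3, 4, 4),
                          weight = c(0.9, 0.5, 0.6, 0.3)))
}
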