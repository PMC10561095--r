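test_that("risk_network validates its invariants", {
  expect_error(risk_network(data.frame(source = 1, target = 1)),
               "self-loops")
  expect_error(risk_network(data.frame(source = c(1, 2), target = c(2, 1),
                                       weight = c(0.5, 0.5))),
               "duplicate")
  expect_error(risk_network(data.frame(source = 1, target = 2, weight = 1.2)),
               "\\[0, 1\\]")
  expect_error(risk_network(data.frame(source = 1, target = 2), nodes = 1),
               "absent")
  net <- risk_network(data.frame(source = 2, target = 1, weight = 0.3))
  expect_equal(net$edges$source, 1)  # canonicalised order
  expect_equal(net$nodes, 1:2)
})

test_that("preferential attachment with one edge per node yields a connected tree", {
  for (seed in 1:5) {
    net <- generate_scale_free(50, 1, seed = seed)
    expect_equal(length(net$nodes), 50)
    expect_equal(nrow(net$edges), 49)
    # connected: BFS from node 1 reaches everything
    lay <- assign_layers(net, 1)
    expect_false(anyNA(lay$layer))
  }
  expect_identical(generate_scale_free(30, 1, seed = 11)$edges,
                   generate_scale_free(30, 1, seed = 11)$edges)
  base <- generate_scale_free(2, 1, seed = 1)
  expect_equal(base$edges[, c("source", "target")],
               data.frame(source = 1L, target = 2L))
  expect_error(generate_scale_free(1, 1), ">= 2")
  expect_error(generate_scale_free(10, 0), ">= 1")
})

test_that("generated degree sequences are right-skewed (hub formation)", {
  hits <- 0
  for (seed in 1:20) {
    net <- generate_scale_free(200, 1, seed = seed)
    deg <- node_metrics(net)$degree
    if (max(deg) > 5 * median(deg)) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("denser attachment keeps every new node on min(m, existing) targets", {
  net <- generate_scale_free(40, 3, seed = 4)
  # nodes 1..3 contribute 1+2 edges, every later node 3
  expect_equal(nrow(net$edges), 1 + 2 + 37 * 3)
  lay <- assign_layers(net, 1)
  expect_false(anyNA(lay$layer))
})

test_that("layer assignment is multi-source shortest-path distance", {
  bm <- benchmark_network(1)
  la <- assign_layers(bm, 1)
  expect_equal(unname(la$layer[c("1", "2", "22", "8")]), c(0L, 1L, 2L, 3L))
  expect_equal(la$parents[["1"]], integer(0))
  la2 <- assign_layers(bm, c(1, 22))
  expect_equal(unname(la2$layer[c("22", "8")]), c(0L, 1L))
  expect_equal(la2$parents[["2"]], c(1L, 22L))
  # all nodes sources: everything layer 0, all edges loops
  la3 <- assign_layers(bm, bm$nodes)
  expect_true(all(la3$layer == 0))
  expect_true(all(lengths(la3$parents) == 0))
  orc <- orient_edges(bm, la3)
  expect_true(all(orc$arcs$kind == "loop"))
  expect_error(assign_layers(bm, integer(0)), "nonempty")
  expect_error(assign_layers(bm, 99), "unknown source")
})

test_that("layers agree with an independent shortest-path oracle", {
  skip_if_not_installed("igraph")
  set.seed(42)
  for (rep in 1:40) {
    net <- random_network(sample(4:12, 1))
    sources <- sample(net$nodes, sample(1:2, 1))
    la <- assign_layers(net, sources)
    expect_equal(unname(la$layer), unname(oracle_layers(net, sources)))
  }
})

test_that("orientation points downhill, labels same-layer edges as loops, and is acyclic", {
  skip_if_not_installed("igraph")
  bm <- benchmark_network(1)
  la <- assign_layers(bm, 1)
  o <- orient_edges(bm, la)
  a <- o$arcs
  e_822 <- a[(a$from == 22 & a$to == 8), ]
  expect_equal(nrow(e_822), 1)           # edge {8,22} carries risk 22 -> 8
  expect_equal(e_822$kind, "downhill")
  expect_equal(a$kind[a$from == 13 & a$to == 14], "loop")
  expect_equal(a$kind[a$from == 42 & a$to == 43], "loop")
  expect_equal(a$kind[a$from == 48 & a$to == 49], "loop")
  # downhill arcs on random networks form a DAG
  set.seed(7)
  for (rep in 1:20) {
    net <- random_network(sample(4:12, 1))
    sources <- sample(net$nodes, sample(1:2, 1))
    o <- orient_edges(net, assign_layers(net, sources))
    down <- o$arcs[o$arcs$kind == "downhill", ]
    g <- igraph::graph_from_data_frame(
      down[, c("from", "to")], directed = TRUE,
      vertices = data.frame(name = net$nodes))
    expect_true(igraph::is_dag(g))
  }
})

test_that("degree and strength metrics match hand counts on the benchmark", {
  bm <- benchmark_network(1)
  m1 <- node_metrics(bm, 1)
  expect_equal(m1$degree, 4)
  expect_equal(m1$strength, 0.7117 + 0.3215 + 0.4431 + 0.6580)
  iso <- risk_network(data.frame(source = 1, target = 2, weight = 0.5),
                      nodes = 1:3)
  expect_equal(node_metrics(iso, 3)$degree, 0)
  expect_equal(node_metrics(iso, 3)$strength, 0)
  expect_error(node_metrics(bm, 99), "unknown node")
  # oriented from source 1: node 22 receives from 2, sends to 8, 9, 10
  o <- orient_edges(bm, assign_layers(bm, 1))
  m22 <- node_metrics(o, 22)
  expect_equal(m22$in_degree, 1)
  expect_equal(m22$out_degree, 3)
  expect_equal(m22$degree, m22$in_degree + m22$out_degree)
  expect_equal(m22$in_strength, 0.8179)
  expect_equal(m22$out_strength, 0.8328 + 0.7266 + 0.3939)
})
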