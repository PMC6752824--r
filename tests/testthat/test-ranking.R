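test_that("PageRank solves the 2-node stationary system exactly", {
  net <- directed_network(data.frame(from = "a", to = "b"))
  p <- pagerank(build_google_matrix(net, 0.85))$p
  # exact solution of G p = p for the 2x2 system
  expect_equal(unname(p), c(1 / 2.85, 1.85 / 2.85), tolerance = 1e-10)
})

test_that("PageRank is uniform on symmetric graphs", {
  ids <- paste0("k", 1:6)
  net <- directed_network(expand.grid(from = ids, to = ids,
                                      stringsAsFactors = FALSE))
  p <- pagerank(build_google_matrix(net))$p
  expect_equal(unname(p), rep(1 / 6, 6), tolerance = 1e-12)
  cyc <- directed_network(data.frame(from = ids, to = c(ids[-1], ids[1])))
  expect_equal(unname(cheirank(cyc)$p), rep(1 / 6, 6), tolerance = 1e-12)
})

google_matvec_for_test <- function(G, v) {
  as.numeric(as.matrix(G) %*% v)
}

test_that("PageRank matches dense eigensolver and igraph oracles", {
  for (s in 1:5) {
    net <- rand_net(sample(10:30, 1), seed = s)
    G <- build_google_matrix(net, 0.85)
    p <- pagerank(G, tol = 1e-14, max_iter = 1e5)$p
    expect_equal(p, dense_pagerank_oracle(dense_google_oracle(net, 0.85)),
                 tolerance = 1e-9)
    expect_lt(sum(abs(google_matvec_for_test(G, p) - p)), 1e-10)
  }
  # independent library oracle on a dangling-free net
  ids <- paste0("n", 1:12)
  set.seed(4)
  edges <- unique(data.frame(from = ids[sample(12, 40, TRUE)],
                             to = ids[sample(12, 40, TRUE)],
                             stringsAsFactors = FALSE))
  edges <- edges[edges$from != edges$to, ]
  edges <- rbind(edges, data.frame(from = ids, to = c(ids[-1], ids[1])))
  net <- directed_network(edges)
  p <- pagerank(build_google_matrix(net), tol = 1e-14, max_iter = 1e5)$p
  g <- igraph::graph_from_data_frame(net$edges)
  pi <- igraph::page_rank(g, damping = 0.85)$vector[names(p)]
  expect_equal(unname(p), unname(pi), tolerance = 1e-8)
})

test_that("non-convergence is reported with the residual", {
  net <- rand_net(20, seed = 2)
  expect_error(pagerank(build_google_matrix(net), tol = 1e-14, max_iter = 2L),
               "residual")
})

test_that("CheiRank is the PageRank of the inverted network", {
  net <- rand_net(25, seed = 11)
  expect_equal(cheirank(net)$p,
               pagerank(build_google_matrix(invert_network(net)))$p)
  # fan graph: pure emitter is top CheiRank, bottom PageRank
  fan <- directed_network(data.frame(from = "hub", to = paste0("x", 1:9)))
  kstar <- cheirank(fan)$rank
  k <- pagerank(build_google_matrix(fan))$rank
  expect_equal(unname(kstar["hub"]), 1L)
  expect_equal(unname(k["hub"]), 10L)
})

test_that("rank order is deterministic with index tie-breaking", {
  expect_equal(rank_order(c(0.2, 0.5, 0.3)), c(2L, 3L, 1L))
  expect_equal(rank_order(rep(0.25, 4)), 1:4)
  set.seed(8)
  for (i in 1:20) {
    p <- runif(15)
    ord <- rank_order(p)
    rk <- order(ord)
    expect_equal(ord[rk], seq_along(p))      # inverse consistency
    expect_true(all(diff(p[ord]) <= 0))
  }
})

test_that("local ranking restricts the global order", {
  net <- rand_net(30, seed = 21)
  rv <- pagerank(build_google_matrix(net))
  lr <- local_ranking(rv, net$node_ids)
  expect_equal(lr$global_K, seq_len(30))
  sub <- names(sort(rv$rank))[c(5, 2, 9)]
  lr2 <- local_ranking(rv, sub)
  expect_equal(lr2$id, names(sort(rv$rank))[c(2, 5, 9)])
  expect_equal(lr2$K_r, 1:3)
  expect_error(local_ranking(rv, "missing"), "not in ranking")
})

test_that("category sub-indices of the published ranking are sequential", {
  t3 <- attr(load_fixture("table3"), "table")
  expect_equal(t3$K_cat[t3$category == "cancer"], 1:37)
  expect_equal(t3$K_cat[t3$category == "drug"], 1:203)
  # local_ranking reproduces the same sub-indexing rule
  p <- stats::setNames(sort(runif(10), decreasing = TRUE), paste0("n", 1:10))
  rv <- regomax:::new_rank_vector(p, "pagerank", 0.85, 1e-12, 1L)
  cats <- stats::setNames(rep(c("a", "b"), 5), names(p))
  lr <- local_ranking(rv, names(p), cats)
  expect_equal(lr$K_cat[lr$category == "a"], 1:5)
})

test_that("PageRank is equivariant under node relabeling", {
  net <- rand_net(20, seed = 31)
  p1 <- pagerank(build_google_matrix(net), tol = 1e-13, max_iter = 1e4)$p
  set.seed(32)
  perm <- sample(net$node_ids)
  map <- stats::setNames(perm, net$node_ids)
  net2 <- directed_network(
    data.frame(from = unname(map[net$edges$from]),
               to = unname(map[net$edges$to]), stringsAsFactors = FALSE),
    nodes = unname(map[net$node_ids]))
  p2 <- pagerank(build_google_matrix(net2), tol = 1e-13, max_iter = 1e4)$p
  expect_equal(unname(p2[unname(map[names(p1)])]), unname(p1),
               tolerance = 1e-10)
})

test_that("the top node of a hub-dominated network is stable in alpha", {
  net <- generate_network(synthetic_config(n_background = 200L,
                                           hub_count = 1L, hub_bias = 0.9,
                                           seed = 17L))
  tops <- vapply(c(0.5, 0.65, 0.85, 0.95), function(a) {
    rv <- pagerank(build_google_matrix(net, a))
    names(rv$p)[rv$order[1]]
  }, character(1))
  expect_true(all(tops == "hub01"))
})

test_that("rank tables serialise with the documented schema", {
  net <- directed_network(data.frame(from = "a", to = "b"))
  rv <- pagerank(build_google_matrix(net))
  f <- tempfile()
  write_rank_table(rv, f, labels = c(a = "Node A"),
                   categories = c(a = "x", b = "y"))
  tab <- read.delim(f, stringsAsFactors = FALSE)
  expect_equal(names(tab), c("rank", "id", "label", "probability",
                             "category"))
  expect_equal(tab$id, c("b", "a"))
  expect_equal(tab$label[2], "Node A")
  expect_equal(sum(tab$probability), 1, tolerance = 1e-10)
})
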