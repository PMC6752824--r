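synthetic_rgm <- function(seed = 8, n_cancer = 6L, n_drug = 6L,
                          planted = list()) {
  cfg <- synthetic_config(
    n_background = 120L,
    groups = list(list(category = "cancer", size = n_cancer,
                       in_rate = 0.08, out_rate = 0.03),
                  list(category = "drug", size = n_drug, in_rate = 0.03,
                       out_rate = 0.03)),
    planted_paths = planted, seed = seed)
  net <- generate_network(cfg)
  sub <- names(net$categories)[net$categories %in% c("cancer", "drug")]
  list(net = net,
       rgm = regomax(build_google_matrix(net), sub),
       categories = net$categories)
}

test_that("friend scores are the sorted (G_rr + G_qrnd) column", {
  s <- synthetic_rgm(seed = 12)
  rgm <- s$rgm
  cands <- setdiff(rgm$subset, "cancer01")
  fs <- friend_scores(rgm, "cancer01", cands)
  M <- rgm$G_rr + rgm$G_qrnd
  brute <- sort(M[cands, "cancer01"], decreasing = TRUE)
  expect_equal(fs$score, unname(brute), tolerance = 1e-14)
  expect_equal(fs$candidate[1:2], names(brute)[1:2])
  # single candidate wins regardless of score
  one <- friend_scores(rgm, "cancer01", "drug03")
  expect_equal(one$candidate, "drug03")
  expect_equal(nrow(friend_scores(rgm, "cancer01", character())), 0L)
})

test_that("equal scores are broken by ascending local PageRank index", {
  s <- synthetic_rgm(seed = 13)
  rgm <- s$rgm
  M0 <- matrix(0.5, 4, 4, dimnames = list(rgm$subset[1:4], rgm$subset[1:4]))
  fake <- rgm
  fake$subset <- rgm$subset[1:4]
  fake$G_rr <- M0
  fake$G_qrnd <- 0 * M0
  fake$G_qr <- fake$G_qrd <- 0 * M0
  fake$K_r <- rgm$K_r[1:4]
  fs <- friend_scores(fake, fake$subset[1], fake$subset[2:4])
  expect_equal(fs$candidate,
               fake$subset[2:4][order(fake$K_r[2:4])])
})

test_that("the friend network reaches a fixpoint and respects categories", {
  s <- synthetic_rgm(seed = 21)
  seeds <- grep("^cancer", s$rgm$subset, value = TRUE)[1:2]
  fn <- build_friend_network(s$rgm, seeds, s$categories, "cancer",
                             attach_categories = "drug")
  # every non-seed primary node reachable from a seed via expansion edges
  prim <- fn$nodes$id[fn$nodes$role == "primary-group"]
  exp_edges <- fn$edges[fn$edges$to %in% prim, ]
  reach <- seeds
  repeat {
    nxt <- unique(c(reach, exp_edges$to[exp_edges$from %in% reach]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  expect_setequal(intersect(reach, prim), prim)
  expect_true(all(fn$nodes$category[fn$nodes$role == "attached-group"] ==
                    "drug"))
  # attached drugs are never expanded
  expect_true(!any(fn$edges$from %in%
                     fn$nodes$id[fn$nodes$role == "attached-group"]))
  # iterations contiguous from 1
  expect_equal(sort(unique(fn$edges$iteration[fn$edges$to %in% prim])),
               seq_len(max(fn$edges$iteration[fn$edges$to %in% prim])))
  # hidden edges have zero restricted adjacency
  A <- as.matrix(adjacency_matrix(s$net))[s$rgm$subset, s$rgm$subset]
  hid <- fn$edges[fn$edges$kind == "hidden", ]
  if (nrow(hid)) {
    expect_true(all(A[cbind(hid$to, hid$from)] == 0))
  }
})

test_that("n_friends = 0 yields seeds only and no expansion edges", {
  s <- synthetic_rgm(seed = 22)
  seeds <- grep("^cancer", s$rgm$subset, value = TRUE)[1:2]
  fn <- build_friend_network(s$rgm, seeds, s$categories, "cancer",
                             n_friends = 0L)
  expect_equal(fn$nodes$id, seeds)
  expect_equal(nrow(fn$edges), 0L)
  expect_error(build_friend_network(s$rgm, "nope", s$categories, "cancer"),
               "not in subset")
  expect_error(build_friend_network(s$rgm, seeds, s$categories["cancer01"],
                                    "cancer"),
               "category map missing")
})

test_that("a dominant planted node collapses the expansion to one step", {
  s <- synthetic_rgm(seed = 30)
  rgm <- s$rgm
  cancers <- grep("^cancer", rgm$subset, value = TRUE)
  # plant a column-dominant score toward cancer06 from every cancer
  fake <- rgm
  fake$G_qrnd[,] <- 0
  fake$G_qrnd["cancer06", setdiff(cancers, "cancer06")] <- 1
  fake$G_rr[,] <- 0
  fn <- build_friend_network(fake, cancers[1:3], s$categories, "cancer",
                             n_friends = 1L)
  expect_equal(fn$params$iterations, 2L)  # iteration 2 adds nothing new
  expect_setequal(fn$nodes$id, c(cancers[1:3], "cancer06"))
  expect_true(all(fn$edges$to == "cancer06"))
})

test_that("top partner tables equal the brute-force top-k", {
  s <- synthetic_rgm(seed = 35)
  rgm <- s$rgm
  cancers <- grep("^cancer", rgm$subset, value = TRUE)
  drugs <- grep("^drug", rgm$subset, value = TRUE)
  tp <- top_partners(rgm, cancers, drugs, k = 3)
  M <- rgm$G_rr + rgm$G_qrnd
  for (cr in cancers) {
    got <- tp$partner[tp$node == cr]
    brute <- names(sort(M[drugs, cr], decreasing = TRUE))[1:3]
    expect_equal(got, brute)
  }
  # k = |cols| returns the whole sorted column; k beyond is flagged short
  full <- top_partners(rgm, cancers[1], drugs, k = length(drugs))
  expect_equal(nrow(full), length(drugs))
  over <- top_partners(rgm, cancers[1], drugs, k = 50)
  expect_true(attr(over, "short"))
  expect_equal(nrow(over), length(drugs))
  expect_error(top_partners(rgm, cancers, c(drugs, cancers[1])), "disjoint")
  # both published score variants are available
  tp2 <- top_partners(rgm, cancers, drugs, k = 3, score = "rr_plus_qr")
  expect_equal(sort(unique(tp2$node)), sort(cancers))
})

test_that("a planted indirect partner ranks first and is flagged hidden", {
  s <- synthetic_rgm(seed = 44,
                     planted = list(list(source = "cancer02",
                                         relay_len = 1L,
                                         target = "drug04")))
  drugs <- grep("^drug", s$rgm$subset, value = TRUE)
  tp <- top_partners(s$rgm, "cancer02", drugs, k = 3)
  expect_equal(tp$partner[1], "drug04")
  expect_equal(tp$kind[1], "hidden")
})

test_that("exports round-trip and validate", {
  s <- synthetic_rgm(seed = 50)
  seeds <- grep("^cancer", s$rgm$subset, value = TRUE)[1:2]
  fn <- build_friend_network(s$rgm, seeds, s$categories, "cancer",
                             attach_categories = "drug")
  f <- tempfile(fileext = ".tsv")
  export_graph(fn, f, "edge-tsv")
  back <- read_friend_network(f)
  expect_identical(back$nodes, fn$nodes)
  expect_identical(back$edges, fn$edges)
  expect_identical(back$seeds, fn$seeds)
  # byte-identical on re-export (determinism)
  f2 <- tempfile()
  export_graph(fn, f2, "edge-tsv")
  expect_identical(readLines(f), readLines(f2))
  # GraphML is well-formed XML with the attributes declared
  skip_if_not_installed("xml2")
  g <- tempfile(fileext = ".graphml")
  export_graph(fn, g, "graphml")
  doc <- xml2::read_xml(g)
  expect_equal(xml2::xml_name(doc), "graphml")
  keys <- xml2::xml_attr(xml2::xml_find_all(doc, ".//d1:key",
                                            xml2::xml_ns(doc)), "attr.name")
  expect_true(all(c("category", "kind", "weight") %in% keys))
  d <- tempfile(fileext = ".dot")
  export_graph(fn, d, "dot")
  expect_match(readLines(d, n = 1), "digraph")
  expect_error(export_graph(fn, tempfile(), "svg"), "'arg'")
})

test_that("an empty network exports a valid header-only file", {
  s <- synthetic_rgm(seed = 51)
  seeds <- grep("^cancer", s$rgm$subset, value = TRUE)[1]
  fn <- build_friend_network(s$rgm, seeds, s$categories, "cancer",
                             n_friends = 0L)
  f <- tempfile()
  export_graph(fn, f, "edge-tsv")
  back <- read_friend_network(f)
  expect_equal(nrow(back$edges), 0L)
  expect_equal(back$nodes$id, seeds)
})
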