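# score matrix used for friend selection / partner tables
score_matrix <- function(rgm, score = c("rr_plus_qrnd", "rr_plus_qr")) {
  score <- match.arg(score)
  if (score == "rr_plus_qrnd") rgm$G_rr + rgm$G_qrnd else rgm$G_rr + rgm$G_qr
}

#' Strongest partners of a node in a reduced Google matrix
#'
#' Scores every candidate c by the (G_rr + G_qrnd) element in row c of the
#' column of `from_node` — the non-obvious strength of the link pointing
#' from `from_node` to c — and returns candidates sorted by decreasing
#' score, ties broken by ascending local PageRank index K_r.
#'
#' @param rgm a `regomax` object.
#' @param from_node node id in the subset.
#' @param candidates character vector of candidate ids (the node itself is
#'   excluded).
#' @param score `"rr_plus_qrnd"` (default) or `"rr_plus_qr"`.
#' @return data.frame with columns `candidate`, `score`, `kind` (`"direct"`,
#'   `"hidden"`, or `"none"` when neither applies) and `hidden` (logical).
#' @export
friend_scores <- function(rgm, from_node, candidates,
                          score = "rr_plus_qrnd") {
  stopifnot(inherits(rgm, "regomax"))
  M <- score_matrix(rgm, score)
  b <- resolve_index(from_node, colnames(M))
  candidates <- setdiff(candidates, rgm$subset[b])
  if (length(candidates) == 0L) {
    return(data.frame(candidate = character(), score = numeric(),
                      kind = character(), hidden = logical(),
                      stringsAsFactors = FALSE))
  }
  ci <- vapply(candidates, resolve_index, integer(1L), ids = rownames(M))
  sc <- M[ci, b]
  ord <- order(-sc, rgm$K_r[ci])
  direct <- direct_link_mask(rgm)[cbind(ci[ord], b)]
  hid <- hidden_link_mask(rgm)[cbind(ci[ord], b)]
  data.frame(candidate = candidates[ord], score = unname(sc[ord]),
             kind = ifelse(direct, "direct",
                           ifelse(hid, "hidden", "none")),
             hidden = hid, stringsAsFactors = FALSE)
}

#' Iterative friend-network construction
#'
#' Grows an interaction graph from seed nodes: at iteration 1 each seed is
#' connected to its `n_friends` strongest same-category partners by
#' (G_rr + G_qrnd) score (only strictly positive scores qualify: a
#' non-positive score means no interaction to follow); at every later iteration only the nodes newly
#' added in the previous one are expanded, until a fixpoint (no new node) or
#' `max_iter`.  Finally every primary-category node present receives its
#' `n_attach` strongest partners in each attach category; attached nodes are
#' never expanded.  Each edge records its iteration and whether it is a
#' direct link (present in the restricted adjacency) or a purely hidden link
#' (absent from the adjacency, positive G_qrnd).
#'
#' @param rgm a `regomax` object.
#' @param seeds seed node ids, all of `primary_category`.
#' @param categories named character vector id -> category covering the
#'   subset.
#' @param primary_category category that is iteratively expanded.
#' @param attach_categories categories attached as satellites (default
#'   none).
#' @param n_friends same-category partners added per expanded node.
#' @param n_attach partners per attach category.
#' @param max_iter safety valve; the finite node set guarantees a fixpoint.
#' @param score score matrix choice, see [friend_scores].
#' @return object of class `friend_network`: `nodes` data.frame (`id`,
#'   `category`, `role`, `iteration`), `edges` data.frame (`from`, `to`,
#'   `weight`, `iteration`, `kind`), `seeds`, `params`.
#' @export
build_friend_network <- function(rgm, seeds, categories, primary_category,
                                 attach_categories = character(),
                                 n_friends = 2L, n_attach = 2L,
                                 max_iter = 100L, score = "rr_plus_qrnd") {
  stopifnot(inherits(rgm, "regomax"))
  missing_cat <- setdiff(rgm$subset, names(categories))
  if (length(missing_cat)) {
    stop("category map missing for: ", paste(missing_cat, collapse = ", "))
  }
  bad <- setdiff(seeds, rgm$subset)
  if (length(bad)) stop("seed(s) not in subset: ", paste(bad, collapse = ", "))
  if (any(categories[seeds] != primary_category)) {
    stop("all seeds must be of the primary category")
  }
  primary_pool <- rgm$subset[categories[rgm$subset] == primary_category]
  nodes <- data.frame(id = seeds, category = primary_category,
                      role = "primary-group", iteration = 0L,
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = character(), to = character(),
                      weight = numeric(), iteration = integer(),
                      kind = character(), stringsAsFactors = FALSE)
  frontier <- seeds
  iter <- 0L
  while (length(frontier) > 0L && iter < max_iter && n_friends > 0L) {
    iter <- iter + 1L
    new_frontier <- character()
    for (nd in frontier) {
      fs <- friend_scores(rgm, nd, setdiff(primary_pool, nd), score = score)
      top <- utils::head(fs[fs$score > 0, , drop = FALSE], n_friends)
      if (nrow(top) == 0L) next
      edges <- rbind(edges, data.frame(
        from = nd, to = top$candidate, weight = top$score,
        iteration = iter,
        kind = top$kind,
        stringsAsFactors = FALSE))
      fresh <- setdiff(top$candidate, nodes$id)
      if (length(fresh)) {
        nodes <- rbind(nodes, data.frame(
          id = fresh, category = primary_category, role = "primary-group",
          iteration = iter, stringsAsFactors = FALSE))
        new_frontier <- c(new_frontier, fresh)
      }
    }
    frontier <- new_frontier
  }
  # satellite attachment: every primary node present, including seeds
  for (cat in attach_categories) {
    pool <- rgm$subset[categories[rgm$subset] == cat]
    for (nd in nodes$id[nodes$role == "primary-group"]) {
      fs <- friend_scores(rgm, nd, pool, score = score)
      top <- utils::head(fs[fs$score > 0, , drop = FALSE], n_attach)
      if (nrow(top) == 0L) next
      edges <- rbind(edges, data.frame(
        from = nd, to = top$candidate, weight = top$score,
        iteration = nodes$iteration[match(nd, nodes$id)] + 1L,
        kind = top$kind,
        stringsAsFactors = FALSE))
      fresh <- setdiff(top$candidate, nodes$id)
      if (length(fresh)) {
        nodes <- rbind(nodes, data.frame(
          id = fresh, category = cat, role = "attached-group",
          iteration = nodes$iteration[match(nd, nodes$id)] + 1L,
          stringsAsFactors = FALSE))
      }
    }
  }
  rownames(nodes) <- rownames(edges) <- NULL
  structure(
    list(nodes = nodes, edges = edges, seeds = seeds,
         params = list(primary_category = primary_category,
                       attach_categories = attach_categories,
                       n_friends = n_friends, n_attach = n_attach,
                       score = score, iterations = iter)),
    class = "friend_network")
}

#' @export
print.friend_network <- function(x, ...) {
  cat("Friend network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges (", sum(x$edges$kind == "hidden"), "hidden ), fixpoint after",
      x$params$iterations, "iteration(s)\n")
  invisible(x)
}

#' Top-k partner table
#'
#' For every row node, the k strongest column entries of the chosen score
#' matrix among `cols`, with each partner flagged direct or hidden.  Both
#' published score variants are supported: (G_rr + G_qrnd) and
#' (G_rr + G_qr).
#'
#' @param rgm a `regomax` object.
#' @param rows,cols disjoint id vectors within the subset.
#' @param k partners per row; if `k > length(cols)` all are returned and the
#'   table is flagged `short`.
#' @param score `"rr_plus_qrnd"` (default) or `"rr_plus_qr"`.
#' @return data.frame with columns `node`, `rank`, `partner`, `score`,
#'   `kind`; attribute `short` TRUE when k exceeded the candidate count.
#' @export
top_partners <- function(rgm, rows, cols, k = 3L,
                         score = "rr_plus_qrnd") {
  stopifnot(inherits(rgm, "regomax"))
  if (length(intersect(rows, cols))) stop("'rows' and 'cols' must be disjoint")
  short <- k > length(cols)
  out <- lapply(rows, function(nd) {
    fs <- friend_scores(rgm, nd, cols, score = score)
    top <- utils::head(fs, k)
    data.frame(node = nd, rank = seq_len(nrow(top)), partner = top$candidate,
               score = top$score,
               kind = top$kind,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "short") <- short
  res
}

#' Export a friend network
#'
#' `edge-tsv` is a lossless round-trip format (all node and edge fields);
#' `graphml` carries node category/iteration and edge kind/weight as
#' attributes; `dot` is Graphviz source.
#'
#' @param fn a `friend_network`.
#' @param path output file.
#' @param format `"edge-tsv"`, `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(fn, path, format = c("edge-tsv", "graphml", "dot")) {
  stopifnot(inherits(fn, "friend_network"))
  format <- match.arg(format)
  if (format == "edge-tsv") {
    hdr <- c("# friend-network v1",
             paste0("# seeds\t", paste(fn$seeds, collapse = ",")),
             "#node\tid\tcategory\trole\titeration")
    nl <- paste("N", fn$nodes$id, fn$nodes$category, fn$nodes$role,
                fn$nodes$iteration, sep = "\t")
    el <- if (nrow(fn$edges)) {
      paste("E", fn$edges$from, fn$edges$to,
            formatC(fn$edges$weight, format = "e", digits = 16),
            fn$edges$iteration, fn$edges$kind, sep = "\t")
    } else character()
    writeLines(c(hdr, nl, "#edge\tfrom\tto\tweight\titeration\tkind", el),
               path, useBytes = TRUE)
  } else if (format == "graphml") {
    g <- friend_igraph(fn)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    esc <- function(x) gsub("\"", "\\\"", x, fixed = TRUE)
    lines <- c("digraph friend_network {",
               paste0("  \"", esc(fn$nodes$id), "\" [category=\"",
                      esc(fn$nodes$category), "\"];"),
               if (nrow(fn$edges)) paste0(
                 "  \"", esc(fn$edges$from), "\" -> \"", esc(fn$edges$to),
                 "\" [kind=\"", fn$edges$kind, "\", weight=",
                 formatC(fn$edges$weight, format = "e", digits = 6), "];"),
               "}")
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

friend_igraph <- function(fn) {
  g <- igraph::graph_from_data_frame(
    if (nrow(fn$edges)) fn$edges else
      data.frame(from = character(), to = character()),
    directed = TRUE, vertices = fn$nodes)
  g
}

#' Read back an `edge-tsv` friend-network export
#'
#' @param path file written by [export_graph] with `format = "edge-tsv"`.
#' @return a `friend_network`.
#' @export
read_friend_network <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  seeds_line <- grep("^# seeds\t", lines, value = TRUE)
  seeds <- if (length(seeds_line) && nzchar(sub("^# seeds\t", "", seeds_line[1L]))) {
    strsplit(sub("^# seeds\t", "", seeds_line[1L]), ",", fixed = TRUE)[[1L]]
  } else character()
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  is_node <- vapply(parts, function(p) p[[1L]] == "N", logical(1L))
  np <- parts[is_node]
  ep <- parts[!is_node]
  nodes <- data.frame(
    id = vapply(np, `[[`, character(1L), 2L),
    category = vapply(np, `[[`, character(1L), 3L),
    role = vapply(np, `[[`, character(1L), 4L),
    iteration = as.integer(vapply(np, `[[`, character(1L), 5L)),
    stringsAsFactors = FALSE)
  edges <- if (length(ep)) data.frame(
    from = vapply(ep, `[[`, character(1L), 2L),
    to = vapply(ep, `[[`, character(1L), 3L),
    weight = as.numeric(vapply(ep, `[[`, character(1L), 4L)),
    iteration = as.integer(vapply(ep, `[[`, character(1L), 5L)),
    kind = vapply(ep, `[[`, character(1L), 6L),
    stringsAsFactors = FALSE)
  else data.frame(from = character(), to = character(), weight = numeric(),
                  iteration = integer(), kind = character(),
                  stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, seeds = seeds,
                 params = list()),
            class = "friend_network")
}
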