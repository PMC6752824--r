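#' Directed network
#'
#' A directed network of uniquely identified nodes connected by unweighted,
#' deduplicated directed links ("`from` cites `to`").  Self-loops are never
#' stored: the analyses here operate on citation networks without
#' self-citations, and a self-loop would distort the out-degree normalisation
#' of the Google matrix.
#'
#' @param edges two-column `data.frame` (or matrix) of character node ids,
#'   columns `from` and `to`.  Duplicate rows are collapsed, self-loops
#'   dropped (with a message giving the count).
#' @param nodes optional character vector of node ids; the node set is the
#'   union of `nodes` and all edge endpoints, ordered with `nodes` first.
#' @param labels optional named character vector mapping node id to a display
#'   name.
#' @param categories optional named character vector mapping node id to a
#'   category tag (e.g. `"cancer"`, `"drug"`, `"country"`).
#' @return an object of class `directed_network` with fields `node_ids`,
#'   `edges` (character `from`/`to` data.frame), `labels`, `categories`.
#' @export
directed_network <- function(edges = NULL, nodes = NULL, labels = NULL,
                             categories = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("'edges' needs two columns (from, to)")
  edges <- data.frame(from = as.character(edges[[1L]]),
                      to = as.character(edges[[2L]]),
                      stringsAsFactors = FALSE)
  endpoint_ids <- unique(c(edges$from, edges$to))
  loops <- edges$from == edges$to
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  edges <- unique(edges)
  rownames(edges) <- NULL
  node_ids <- unique(c(as.character(nodes), endpoint_ids,
                       names(labels), names(categories)))
  if (length(node_ids) == 0L) stop("network has no nodes")
  net <- structure(
    list(node_ids = node_ids, edges = edges,
         labels = labels, categories = categories),
    class = "directed_network")
  net
}

#' @export
print.directed_network <- function(x, ...) {
  cat("Directed network: N =", length(x$node_ids),
      "nodes, N_l =", nrow(x$edges), "links\n")
  if (!is.null(x$categories)) {
    tab <- table(x$categories)
    cat("Categories:", paste(names(tab), tab, sep = ":", collapse = ", "),
        "\n")
  }
  invisible(x)
}

n_nodes <- function(net) length(net$node_ids)
n_links <- function(net) nrow(net$edges)

node_index <- function(net, node) {
  idx <- match(node, net$node_ids)
  if (anyNA(idx)) {
    stop("unknown node(s): ", paste(node[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Read a directed network from an edge-list file
#'
#' The edge-list dialect is UTF-8 TSV, one `source<TAB>target` pair per line;
#' lines starting with `#` are comments.  An optional label table maps node id
#' to display name and category (`id<TAB>label<TAB>category`); ids appearing
#' only in the label table become isolated nodes.
#'
#' @param path edge-list file.
#' @param labels_path optional label-table file.
#' @return a [directed_network].
#' @export
load_edge_list <- function(path, labels_path = NULL) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  body <- lines[keep]
  lineno <- seq_along(lines)[keep]
  if (length(body) == 0L) stop("empty edge-list file: ", path)
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) != 2L || any(!nzchar(p)),
                logical(1L))
  if (any(bad)) {
    stop("malformed edge-list line ", lineno[which(bad)[1L]], " in ", path,
         ": expected 'source<TAB>target'")
  }
  edges <- data.frame(from = vapply(parts, `[[`, character(1L), 1L),
                      to = vapply(parts, `[[`, character(1L), 2L),
                      stringsAsFactors = FALSE)
  labels <- NULL
  categories <- NULL
  extra_nodes <- NULL
  if (!is.null(labels_path)) {
    lab <- read_label_table(labels_path)
    labels <- lab$labels
    categories <- lab$categories
    extra_nodes <- names(labels)
  }
  directed_network(edges, nodes = extra_nodes, labels = labels,
                   categories = categories)
}

read_label_table <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1L), 1L)
  labs <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else p[[1L]],
                 character(1L))
  cats <- vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else NA_character_,
                 character(1L))
  labels <- stats::setNames(labs, ids)
  categories <- if (all(is.na(cats))) NULL else stats::setNames(cats, ids)
  list(labels = labels, categories = categories)
}

#' Write a network as an edge-list file
#'
#' Emits the same TSV dialect [load_edge_list] reads, byte-stably: links
#' sorted by source id then target id.
#'
#' @param net a [directed_network].
#' @param path output edge-list file.
#' @param labels_path optional output path for the label table
#'   (`id<TAB>label<TAB>category`).
#' @export
save_edge_list <- function(net, path, labels_path = NULL) {
  e <- net$edges[order(net$edges$from, net$edges$to), , drop = FALSE]
  writeLines(paste(e$from, e$to, sep = "\t"), path, useBytes = TRUE)
  if (!is.null(labels_path)) {
    ids <- net$node_ids
    labs <- if (is.null(net$labels)) ids else {
      out <- net$labels[ids]
      out[is.na(out)] <- ids[is.na(out)]
      out
    }
    cats <- if (is.null(net$categories)) rep("", length(ids)) else {
      out <- net$categories[ids]
      out[is.na(out)] <- ""
      out
    }
    writeLines(paste(ids, labs, cats, sep = "\t"), labels_path,
               useBytes = TRUE)
  }
  invisible(path)
}

#' Out-degree of nodes
#'
#' Number of outgoing links of each node (the column normaliser
#' `k_out(j)` of the Google matrix).  Nodes with out-degree zero are the
#' dangling nodes.
#'
#' @param net a [directed_network].
#' @param node optional node id (or vector of ids); default all nodes.
#' @return named integer vector of out-degrees.
#' @export
out_degree <- function(net, node = NULL) {
  deg <- stats::setNames(integer(n_nodes(net)), net$node_ids)
  tab <- table(net$edges$from)
  deg[names(tab)] <- as.integer(tab)
  if (is.null(node)) deg else deg[net$node_ids[node_index(net, node)]]
}

#' In-degree of nodes
#'
#' @inheritParams out_degree
#' @return named integer vector of in-degrees.
#' @export
in_degree <- function(net, node = NULL) {
  deg <- stats::setNames(integer(n_nodes(net)), net$node_ids)
  tab <- table(net$edges$to)
  deg[names(tab)] <- as.integer(tab)
  if (is.null(node)) deg else deg[net$node_ids[node_index(net, node)]]
}

#' Invert the direction of every link
#'
#' Every link (s, t) becomes (t, s); node set, labels and categories are
#' unchanged.  The Google matrix of the inverted network underlies CheiRank.
#'
#' @param net a [directed_network].
#' @return the link-inverted [directed_network].
#' @export
invert_network <- function(net) {
  net$edges <- data.frame(from = net$edges$to, to = net$edges$from,
                          stringsAsFactors = FALSE)
  net
}

#' Adjacency matrix in the column-source convention
#'
#' Returns the sparse binary adjacency A with `A[i, j] = 1` when node j cites
#' node i, i.e. columns index link sources.  This transposed convention keeps
#' the Google matrix column-stochastic.
#'
#' @param net a [directed_network].
#' @return a sparse `Matrix::dgCMatrix` with node ids as dimnames.
#' @export
adjacency_matrix <- function(net) {
  n <- n_nodes(net)
  i <- match(net$edges$to, net$node_ids)
  j <- match(net$edges$from, net$node_ids)
  Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n),
                       dimnames = list(net$node_ids, net$node_ids))
}
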