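# power iteration on an abstract column-stochastic operator
power_iterate <- function(matvec, n, tol, max_iter) {
  p <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    p_new <- matvec(p)
    p_new <- p_new / sum(p_new)
    res <- sum(abs(p_new - p))
    p <- p_new
    if (res < tol) return(list(p = p, iterations = it, residual = res))
  }
  stop("PageRank power iteration did not converge in ", max_iter,
       " iterations (last L1 residual ", format(res), ")")
}

#' PageRank of a Google matrix
#'
#' Power iteration from the uniform vector until the L1 change per step drops
#' below `tol`; the result is the stationary probability vector P with
#' G P = P, normalised to sum 1.  The component P(j) is the probability to
#' find a random surfer on node j; sorting by decreasing P gives the rank
#' index K (K = 1 for the most influential node).
#'
#' @param G a `google_matrix` (see [build_google_matrix]).
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   last residual.
#' @return object of class `rank_vector`: fields `p` (named probabilities),
#'   `order` (node index at each rank position), `rank` (rank index K per
#'   node), `kind`, `alpha`, `tol`, `iterations`.
#' @export
pagerank <- function(G, tol = 1e-12, max_iter = 1000L) {
  stopifnot(inherits(G, "google_matrix"), tol > 0)
  res <- power_iterate(function(v) google_matvec(G, v), G$N, tol, max_iter)
  new_rank_vector(stats::setNames(res$p, G$node_ids), kind = "pagerank",
                  alpha = G$alpha, tol = tol, iterations = res$iterations)
}

new_rank_vector <- function(p, kind, alpha, tol, iterations) {
  ord <- rank_order(p)
  structure(
    list(p = p, order = ord,
         rank = stats::setNames(order(ord), names(p)),
         kind = kind, alpha = alpha, tol = tol, iterations = iterations),
    class = "rank_vector")
}

#' @export
print.rank_vector <- function(x, n = 10L, ...) {
  cat(x$kind, "over", length(x$p), "nodes (alpha =", x$alpha,
      ",", x$iterations, "iterations)\n")
  top <- x$order[seq_len(min(n, length(x$p)))]
  print(data.frame(K = seq_along(top), id = names(x$p)[top],
                   p = unname(x$p[top])))
  invisible(x)
}

#' CheiRank of a directed network
#'
#' PageRank of the link-inverted network: the stationary vector P* of the
#' Google matrix G* built after replacing every link (s, t) by (t, s).
#' CheiRank measures node "diffusivity" (outgoing communicativity), the
#' mirror of PageRank's influence.
#'
#' @param net a [directed_network].
#' @inheritParams build_google_matrix
#' @inheritParams pagerank
#' @return a `rank_vector` of kind `"cheirank"`.
#' @export
cheirank <- function(net, alpha = 0.85, tol = 1e-12, max_iter = 1000L) {
  rv <- pagerank(build_google_matrix(invert_network(net), alpha),
                 tol = tol, max_iter = max_iter)
  rv$kind <- "cheirank"
  rv
}

#' Rank order of a probability vector
#'
#' Deterministic permutation sorting probabilities non-increasingly, ties
#' broken by ascending node index, so `result[k]` is the node index at rank
#' position k.
#'
#' @param p numeric vector (or a `rank_vector`).
#' @return integer permutation of `seq_along(p)`.
#' @export
rank_order <- function(p) {
  if (inherits(p, "rank_vector")) p <- p$p
  order(-p, seq_along(p))
}

#' Local ranking of a node subset
#'
#' Restricts a global ranking to a subset: the local index K_r numbers the
#' subset nodes 1..N_r in the order induced by the global ranking.  When a
#' category map is given, per-category sub-indices (K_r restricted to each
#' category) are emitted as well.
#'
#' @param rv a `rank_vector` over the full network.
#' @param subset character vector of node ids (must exist in `rv`).
#' @param categories optional named character vector id -> category.
#' @return object of class `local_ranking`: data.frame with columns `K_r`,
#'   `id`, `p`, `global_K`, `category`, `K_cat`.
#' @export
local_ranking <- function(rv, subset, categories = NULL) {
  idx <- match(subset, names(rv$p))
  if (anyNA(idx)) {
    stop("node(s) not in ranking: ",
         paste(subset[is.na(idx)], collapse = ", "))
  }
  gk <- rv$rank[idx]
  ord <- order(gk)
  df <- data.frame(K_r = seq_along(subset),
                   id = subset[ord],
                   p = unname(rv$p[idx][ord]),
                   global_K = unname(gk[ord]),
                   stringsAsFactors = FALSE)
  if (!is.null(categories)) {
    df$category <- unname(categories[df$id])
    df$K_cat <- stats::ave(seq_len(nrow(df)), df$category,
                           FUN = seq_along)
  }
  class(df) <- c("local_ranking", "data.frame")
  df
}

#' Write a rank table as TSV
#'
#' Schema: `rank<TAB>id<TAB>label<TAB>probability<TAB>category`, identical
#' for PageRank and CheiRank.
#'
#' @param rv a `rank_vector`.
#' @param path output file.
#' @param labels,categories optional named character vectors keyed by id.
#' @export
write_rank_table <- function(rv, path, labels = NULL, categories = NULL) {
  ids <- names(rv$p)[rv$order]
  lab <- if (is.null(labels)) ids else {
    l <- labels[ids]; l[is.na(l)] <- ids[is.na(l)]; l
  }
  cat_col <- if (is.null(categories)) rep("", length(ids)) else {
    ca <- categories[ids]; ca[is.na(ca)] <- ""; ca
  }
  lines <- paste(seq_along(ids), ids, lab,
                 formatC(unname(rv$p[ids]), format = "e", digits = 12),
                 cat_col, sep = "\t")
  writeLines(c("rank\tid\tlabel\tprobability\tcategory", lines), path,
             useBytes = TRUE)
  invisible(path)
}
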