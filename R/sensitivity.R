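#' Perturb one element of a reduced Google matrix
#'
#' Multiplies the element (target, source) of G_R by (1 + delta) and
#' renormalises the source column to unit sum, leaving every other column
#' untouched.  This is the elementary link-boost operation underlying
#' PageRank sensitivity.
#'
#' @param rgm a `regomax` object (or a plain column-stochastic matrix).
#' @param target row node (id or index): the head of the boosted link.
#' @param source column node (id or index): the tail of the boosted link.
#' @param delta relative boost, `delta > -1`.
#' @return same type as `rgm`, with the perturbed `G_R` (components are left
#'   as computed for the unperturbed matrix).
#' @export
perturb_column <- function(rgm, target, source, delta) {
  is_rgm <- inherits(rgm, "regomax")
  M <- if (is_rgm) rgm$G_R else rgm
  a <- resolve_index(target, rownames(M))
  b <- resolve_index(source, colnames(M))
  if (delta <= -1) stop("'delta' must be > -1")
  if (M[a, b] <= 0) {
    stop("element (", target, ", ", source,
         ") is a structural zero; perturbing it is undefined")
  }
  M[a, b] <- M[a, b] * (1 + delta)
  M[, b] <- M[, b] / sum(M[, b])
  if (is_rgm) {
    rgm$G_R <- M
    rgm$perturbed <- c(target = a, source = b, delta = delta)
    rgm
  } else M
}

resolve_index <- function(node, ids) {
  if (is.character(node)) {
    i <- match(node, ids)
    if (is.na(i)) stop("unknown node: ", node)
    i
  } else as.integer(node)
}

#' PageRank sensitivity to a link perturbation
#'
#' The logarithmic derivative D = d ln P(observed) / d delta of the reduced
#' PageRank with respect to a relative boost (1 + delta) of the element
#' (target, source) of G_R (with column renormalisation).  D measures how
#' much the influence of the observed node rises or falls when the link
#' source -> target is strengthened.  Evaluated by finite differences on the
#' N_r-dimensional reduced matrix:
#' forward  D = (ln P_d(c) - ln P_0(c)) / delta;
#' central  D = (ln P_{+d}(c) - ln P_{-d}(c)) / (2 delta).
#'
#' @param rgm a `regomax` object.
#' @param source,target tail and head of the perturbed link (ids or
#'   indices); the element (target, source) of G_R must be positive.
#' @param observed node whose PageRank derivative is reported; defaults to
#'   `target`.
#' @param delta finite-difference step (default 1e-4).
#' @param scheme `"central"` (default, second-order) or `"forward"`.
#' @return the sensitivity D, a single number.
#' @export
pagerank_sensitivity <- function(rgm, source, target, observed = target,
                                 delta = 1e-4, scheme = c("central",
                                                          "forward")) {
  stopifnot(inherits(rgm, "regomax"), delta > 0)
  scheme <- match.arg(scheme)
  c_idx <- resolve_index(observed, rownames(rgm$G_R))
  p_at <- function(d) {
    M <- perturb_column(rgm$G_R, target, source, d)
    p <- stationary_vector(M)
    unname(p[c_idx])
  }
  if (scheme == "forward") {
    (log(p_at(delta)) - log(p_at(0))) / delta
  } else {
    (log(p_at(delta)) - log(p_at(-delta))) / (2 * delta)
  }
}

#' Sensitivity matrix over families of perturbed links
#'
#' Tabulates D over all source/target pairs.  In `"diagonal"` mode the
#' observed node is the perturbation's source (e.g. vary the cancer -> drug
#' link, observe that cancer); in `"observed"` mode a fixed `observed` node
#' is monitored for every perturbed link.  Pairs whose G_R element is not
#' positive are reported as `NA` ("no link" is not "insensitive").
#'
#' @param rgm a `regomax` object.
#' @param sources,targets node ids (or indices) in the subset; each matrix
#'   entry (source, target) perturbs the link source -> target.
#' @param mode `"diagonal"` or `"observed"`.
#' @param observed observed node for `mode = "observed"`.
#' @inheritParams pagerank_sensitivity
#' @return numeric matrix, rows = sources, columns = targets.
#' @export
sensitivity_matrix <- function(rgm, sources, targets,
                               mode = c("diagonal", "observed"),
                               observed = NULL, delta = 1e-4,
                               scheme = "central") {
  stopifnot(inherits(rgm, "regomax"))
  mode <- match.arg(mode)
  if (mode == "observed" && is.null(observed)) {
    stop("'observed' must be given for mode = \"observed\"")
  }
  ids <- rownames(rgm$G_R)
  si <- vapply(sources, resolve_index, integer(1L), ids = ids)
  ti <- vapply(targets, resolve_index, integer(1L), ids = ids)
  D <- matrix(NA_real_, length(si), length(ti),
              dimnames = list(ids[si], ids[ti]))
  for (x in seq_along(si)) {
    for (y in seq_along(ti)) {
      if (rgm$G_R[ti[y], si[x]] <= 0) next
      obs <- if (mode == "diagonal") si[x] else observed
      D[x, y] <- pagerank_sensitivity(rgm, source = si[x], target = ti[y],
                                      observed = obs, delta = delta,
                                      scheme = scheme)
    }
  }
  D
}

#' Write a sensitivity matrix as a TSV heat-table
#'
#' One `row label<TAB>column label<TAB>value` line per finite entry, ready
#' for any plotting tool; absent (NA) entries are written as `NA`.
#'
#' @param D matrix from [sensitivity_matrix].
#' @param path output file.
#' @export
write_sensitivity <- function(D, path) {
  idx <- expand.grid(row = seq_len(nrow(D)), col = seq_len(ncol(D)))
  lines <- paste(rownames(D)[idx$row], colnames(D)[idx$col],
                 ifelse(is.na(D[cbind(idx$row, idx$col)]), "NA",
                        formatC(D[cbind(idx$row, idx$col)], format = "e",
                                digits = 10)),
                 sep = "\t")
  writeLines(c("source\ttarget\tD", lines), path, useBytes = TRUE)
  invisible(path)
}
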