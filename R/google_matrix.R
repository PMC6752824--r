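#' Google matrix of a directed network
#'
#' Builds the column-stochastic Google matrix G = alpha * S + (1 - alpha)/N
#' where S[i, j] = A[i, j] / k_out(j) for non-dangling columns and
#' S[i, j] = 1/N for dangling columns (nodes without outgoing links).  The
#' damping factor alpha is the probability of following a link rather than
#' teleporting uniformly; the standard value 0.85 is the default and results
#' are insensitive to it over roughly 0.5-0.95.
#'
#' The rank-one teleportation part and the uniform dangling columns are held
#' implicitly: the object stores the sparse link part of S plus the dangling
#' index set, and all operations (matrix-vector products, dense realisation,
#' block extraction) behave as if the dense G existed.
#'
#' @param net a [directed_network].
#' @param alpha damping factor in (0, 1).
#' @return an object of class `google_matrix` with fields `S` (sparse link
#'   part, dangling columns zero), `dangling` (integer indices), `alpha`,
#'   `N`, `node_ids`.
#' @export
build_google_matrix <- function(net, alpha = 0.85) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be a single number in (0, 1)")
  }
  n <- n_nodes(net)
  kout <- out_degree(net)
  A <- adjacency_matrix(net)
  j <- match(net$edges$from, net$node_ids)
  i <- match(net$edges$to, net$node_ids)
  S <- Matrix::sparseMatrix(i = i, j = j, x = 1 / kout[j], dims = c(n, n),
                            dimnames = list(net$node_ids, net$node_ids))
  structure(
    list(S = S, dangling = which(kout == 0L), alpha = alpha, N = n,
         node_ids = net$node_ids),
    class = "google_matrix")
}

#' @export
print.google_matrix <- function(x, ...) {
  cat("Google matrix: N =", x$N, ", alpha =", x$alpha, ",",
      length(x$dangling), "dangling node(s)\n")
  invisible(x)
}

#' @export
dim.google_matrix <- function(x) c(x$N, x$N)

#' Dense realisation of a Google matrix
#'
#' @param x a `google_matrix`.
#' @param ... unused.
#' @return dense N x N matrix with node ids as dimnames.
#' @export
as.matrix.google_matrix <- function(x, ...) {
  G <- x$alpha * as.matrix(x$S)
  if (length(x$dangling)) G[, x$dangling] <- G[, x$dangling] + x$alpha / x$N
  G <- G + (1 - x$alpha) / x$N
  dimnames(G) <- list(x$node_ids, x$node_ids)
  G
}

# y = G %*% v without materialising the dense matrix
google_matvec <- function(gm, v) {
  y <- as.numeric(gm$alpha * (gm$S %*% v))
  y + (gm$alpha * sum(v[gm$dangling]) + (1 - gm$alpha) * sum(v)) / gm$N
}

# dense block G[rows, cols] (integer indices), honouring the implicit parts
google_block <- function(gm, rows, cols) {
  B <- gm$alpha * as.matrix(gm$S[rows, cols, drop = FALSE])
  dang <- cols %in% gm$dangling
  if (any(dang)) B[, dang] <- B[, dang] + gm$alpha / gm$N
  B + (1 - gm$alpha) / gm$N
}
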