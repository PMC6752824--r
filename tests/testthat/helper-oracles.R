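# brute-force dense Google matrix straight from the definitions:
# A[i,j] = 1 iff j cites i; S normalises columns, uniform on dangling;
# G = alpha*S + (1-alpha)/N.  Independent of the package's sparse path.
dense_google_oracle <- function(net, alpha = 0.85) {
  ids <- net$node_ids
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (k in seq_len(nrow(net$edges))) {
    A[net$edges$to[k], net$edges$from[k]] <- 1
  }
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  for (j in seq_len(n)) {
    kout <- sum(A[, j])
    S[, j] <- if (kout == 0) 1 / n else A[, j] / kout
  }
  alpha * S + (1 - alpha) / n
}

# Schur-complement reduced matrix from the dense oracle G
dense_regomax_oracle <- function(Gd, r) {
  s <- setdiff(seq_len(nrow(Gd)), r)
  Gd[r, r, drop = FALSE] +
    Gd[r, s, drop = FALSE] %*%
    solve(diag(length(s)) - Gd[s, s, drop = FALSE], Gd[s, r, drop = FALSE])
}

# dominant eigenvector of a dense stochastic matrix via base eigen()
dense_pagerank_oracle <- function(Gd) {
  e <- eigen(Gd)
  k <- which.max(Mod(e$values))
  v <- Re(e$vectors[, k])
  stats::setNames(v / sum(v), rownames(Gd))
}

# simple random directed network, independent of the package generator
rand_net <- function(n, p = 2.5 / n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(stats::runif(n * n) < p, n, n)
  diag(A) <- FALSE
  ids <- sprintf("v%03d", seq_len(n))
  idx <- which(A, arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 2]], to = ids[idx[, 1]],
                      stringsAsFactors = FALSE)
  directed_network(edges, nodes = ids)
}

write_tmp_edges <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
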