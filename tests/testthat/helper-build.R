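# Small in-code builders shared across test files.

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

tiny_universe <- function(n = 5L, synonyms = TRUE) {
  ids <- paste0("G", seq_len(n))
  syn <- if (synonyms) lapply(seq_len(n), function(i) paste0("alt", i)) else NULL
  gene_universe(ids, syn, organism_name = "test")
}

# Symmetric network from an explicit (i, j, w) edge table.
edge_net <- function(i, j, w, n, name = "net", group = "test-group",
                     publication = "", ...) {
  upper <- Matrix::sparseMatrix(i = pmin(i, j), j = pmax(i, j), x = w,
                                dims = c(n, n))
  sparse_network(upper + Matrix::t(upper),
                 network_meta(name, group, publication = publication, ...))
}

# Dense oracle for symmetric degree normalization.
dense_normalize <- function(w) {
  d <- rowSums(w)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  diag(dinv) %*% w %*% diag(dinv)
}

# Dense direct-solve oracle for the propagation system (I + lambda L) f = y.
dense_propagate <- function(w, y, lambda = 1) {
  w <- as.matrix(w)
  l <- diag(rowSums(w)) - w
  solve(diag(nrow(w)) + lambda * l, y)
}

# Evaluate expr under a temporary seed, restoring the RNG state afterwards.
run_with_seed_local <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Random symmetric non-negative weighted graph as a dense matrix.
random_graph <- function(n, p = 0.3) {
  w <- matrix(0, n, n)
  up <- which(upper.tri(w))
  on <- up[stats::runif(length(up)) < p]
  w[on] <- stats::runif(length(on), 0.1, 1)
  w + t(w)
}
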