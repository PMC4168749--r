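#' Build a 0/1 label vector for a query
#'
#' Query genes are assigned label 1 and every other gene 0. Duplicate query
#' indices are deduplicated.
#'
#' @param query_indices Universe indices of query genes (non-empty).
#' @param n Universe size.
#' @return Numeric vector of length `n` with exactly
#'   `length(unique(query_indices))` ones.
#' @export
build_labels <- function(query_indices, n) {
  query_indices <- unique(as.integer(query_indices))
  if (length(query_indices) == 0L) stop("query is empty")
  if (any(query_indices < 1L | query_indices > n)) {
    stop("query index outside the universe")
  }
  y <- numeric(n)
  y[query_indices] <- 1
  y
}

#' Score genes by Gaussian-field label propagation
#'
#' Solves the smoothness-regularized linear system
#' \deqn{(I + \lambda L) f = y}
#' where `L = D - W` is the graph Laplacian of the composite network
#' (`D` = diagonal of composite row sums) and `y` is the 0/1 label vector.
#' The solution diffuses the query labels over the network: a gene's score
#' grows with its connectivity to query genes, and all scores lie in
#' `[0, 1]` (the system matrix is a symmetric diagonally dominant M-matrix,
#' so the maximum principle applies to 0/1 input). `lambda` controls
#' smoothing strength: at `lambda = 0` the scores equal the labels; larger
#' values spread mass further over the graph.
#'
#' The SPD system is solved by conjugate gradients to a relative residual
#' tolerance; isolated genes decouple from the system and receive their
#' label value exactly.
#'
#' @param composite A [combine] result (or any object with a symmetric
#'   non-negative sparse `adjacency`).
#' @param y Label vector from [build_labels].
#' @param lambda Non-negative smoothing strength (default 1).
#' @param tol Relative residual tolerance (default 1e-10).
#' @param max_iter Iteration cap; default `10 * n`.
#' @return An object of class `score_vector`: `f` (scores), `lambda`,
#'   `iterations`, `residual` (relative), `query_indices`.
#' @export
propagate <- function(composite, y, lambda = 1, tol = 1e-10, max_iter = NULL) {
  w <- if (inherits(composite, "composite_network")) composite$adjacency else composite
  n <- nrow(w)
  stopifnot(length(y) == n, lambda >= 0)
  if (is.null(max_iter)) max_iter <- 10L * n
  query_indices <- which(y == 1)
  if (lambda == 0) {
    return(structure(
      list(f = y, lambda = lambda, iterations = 0L, residual = 0,
           query_indices = query_indices),
      class = "score_vector"
    ))
  }
  d <- Matrix::rowSums(w)
  # A x = x + lambda * (d * x - W x); SPD, spectrum within [1, 1 + 2*lambda*max(d)]
  amul <- function(x) {
    x + lambda * (d * x - as.vector(w %*% x))
  }
  ynorm <- sqrt(sum(y^2))
  x <- y                      # warm start: exact already on isolated genes
  r <- y - amul(x)
  p <- r
  rs <- sum(r^2)
  iter <- 0L
  while (sqrt(rs) > tol * ynorm && iter < max_iter) {
    ap <- amul(p)
    alpha <- rs / sum(p * ap)
    x <- x + alpha * p
    r <- r - alpha * ap
    rs_new <- sum(r^2)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
    iter <- iter + 1L
  }
  res <- sqrt(sum((y - amul(x))^2)) / ynorm
  if (res > tol) {
    stop(sprintf(
      "label propagation did not converge in %d iterations (relative residual %.3g)",
      iter, res
    ))
  }
  isolated <- d == 0
  x[isolated] <- y[isolated]
  # exact solution lies in [0, 1] (maximum principle); clip rounding spill
  x <- pmin(pmax(x, 0), 1)
  structure(
    list(f = as.numeric(x), lambda = lambda, iterations = iter, residual = res,
         query_indices = query_indices),
    class = "score_vector"
  )
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf(
    "Propagation scores: n = %d, lambda = %g, %d CG iterations, residual %.2g\n",
    length(x$f), x$lambda, x$iterations, x$residual
  ))
  invisible(x)
}

#' Rank non-query genes by propagation score
#'
#' Non-query genes with positive score, sorted by score descending with ties
#' broken by universe index ascending (deterministic output), truncated to
#' `n_top`. `n_top = 0` requests no related genes, e.g. to visualize only how
#' the query genes interconnect.
#'
#' @param scores A [propagate] result or bare numeric vector.
#' @param query_indices Indices to exclude from the ranking.
#' @param n_top Maximum number of genes returned (may exceed availability).
#' @return Data frame with columns `index` and `score`.
#' @export
rank_related <- function(scores, query_indices, n_top = 20L) {
  f <- if (inherits(scores, "score_vector")) scores$f else as.numeric(scores)
  stopifnot(n_top >= 0L)
  cand <- setdiff(which(f > 0), as.integer(query_indices))
  cand <- cand[order(-f[cand], cand)]
  cand <- utils::head(cand, n_top)
  data.frame(index = as.integer(cand), score = f[cand])
}

#' Rank attributes by score-weighted incidence
#'
#' An attribute (e.g. a protein domain) is scored by the sum of propagation
#' scores of the result-set genes that carry it, so an attribute shared by
#' many high-scoring genes outranks one carried by a single gene. Attributes
#' with zero score are excluded; ties are broken by attribute name
#' (C collation).
#'
#' @param attribute_incidence Sparse binary genes-by-attributes matrix with
#'   named columns.
#' @param scores A [propagate] result or numeric vector.
#' @param result_gene_set Universe indices of the displayed genes.
#' @param n_top Maximum number of attributes returned.
#' @return Data frame with columns `attribute` and `score`.
#' @export
score_attributes <- function(attribute_incidence, scores, result_gene_set,
                             n_top = 20L) {
  stopifnot(n_top >= 0L)
  f <- if (inherits(scores, "score_vector")) scores$f else as.numeric(scores)
  if (is.null(attribute_incidence) || n_top == 0L) {
    return(data.frame(attribute = character(0), score = numeric(0)))
  }
  g <- unique(as.integer(result_gene_set))
  if (length(g) == 0L) {
    return(data.frame(attribute = character(0), score = numeric(0)))
  }
  inc <- attribute_incidence[g, , drop = FALSE]
  s <- as.vector(Matrix::crossprod(inc, f[g]))
  names(s) <- colnames(attribute_incidence)
  s <- s[s > 0]
  if (length(s) == 0L) {
    return(data.frame(attribute = character(0), score = numeric(0)))
  }
  ord <- order(-s, names(s), method = "radix")
  s <- utils::head(s[ord], n_top)
  data.frame(attribute = names(s), score = unname(s), stringsAsFactors = FALSE)
}
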