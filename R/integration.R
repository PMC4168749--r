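#' Network weighting
#'
#' Before composition, each selected source network receives a non-negative
#' weight. Three methods are provided: `equal` (every network 1/m), `group`
#' (each evidence group receives 1/(number of groups), split equally within
#' the group, so a group contributing many redundant networks is not
#' over-counted), and `adaptive` (query-specific weights fitted by
#' non-negative least squares, see [weight_query_adaptive]).
#'
#' @name network-weights
NULL

new_network_weights <- function(weights, method) {
  stopifnot(is.numeric(weights), !is.null(names(weights)))
  if (any(weights < 0)) stop("network weights must be non-negative")
  if (!any(weights > 0)) stop("at least one network weight must be positive")
  structure(list(weights = weights, method = method),
            class = "network_weights")
}

#' @export
print.network_weights <- function(x, ...) {
  cat(sprintf("Network weights (%s):\n", x$method))
  for (nm in names(x$weights)) {
    cat(sprintf("  %-40s %.4f\n", nm, x$weights[[nm]]))
  }
  invisible(x)
}

#' @rdname network-weights
#' @param networks Non-empty list of [sparse_network]s.
#' @return A `network_weights` object: named weight vector plus the method.
#' @export
weight_equal <- function(networks) {
  if (length(networks) == 0L) stop("no networks to weight")
  nm <- vapply(networks, function(x) x$meta$name, character(1))
  new_network_weights(stats::setNames(rep(1 / length(networks), length(networks)), nm),
                      "equal")
}

#' @rdname network-weights
#' @export
weight_by_group <- function(networks) {
  if (length(networks) == 0L) stop("no networks to weight")
  nm <- vapply(networks, function(x) x$meta$name, character(1))
  grp <- vapply(networks, function(x) x$meta$group, character(1))
  n_groups <- length(unique(grp))
  per_group <- table(grp)
  w <- 1 / (n_groups * as.vector(per_group[grp]))
  new_network_weights(stats::setNames(w, nm), "group")
}

# Lawson-Hanson style active-set non-negative least squares.
# Columns flagged in `free` (e.g. an intercept) are unconstrained and stay in
# the passive set throughout. Returns the coefficient vector.
nnls_solve <- function(X, y, free = rep(FALSE, ncol(X)), max_iter = 30L * ncol(X)) {
  p <- ncol(X)
  beta <- numeric(p)
  passive <- free
  if (any(passive)) {
    beta[passive] <- qr.coef(qr(X[, passive, drop = FALSE]), y)
    beta[is.na(beta)] <- 0
  }
  for (outer in seq_len(max_iter)) {
    grad <- crossprod(X, y - X %*% beta)[, 1L]
    cand <- which(!passive & grad > sqrt(.Machine$double.eps) * max(1, max(abs(grad))))
    if (length(cand) == 0L) break
    passive[cand[which.max(grad[cand])]] <- TRUE
    repeat {
      s <- numeric(p)
      s[passive] <- qr.coef(qr(X[, passive, drop = FALSE]), y)
      s[is.na(s)] <- 0
      viol <- passive & !free & s <= 0
      if (!any(viol)) {
        beta <- s
        break
      }
      ratio <- beta[viol] / (beta[viol] - s[viol])
      alpha <- min(ratio)
      beta <- beta + alpha * (s - beta)
      drop_set <- passive & !free & beta <= sqrt(.Machine$double.eps)
      beta[drop_set] <- 0
      passive[drop_set] <- FALSE
    }
  }
  beta
}

#' Query-adaptive network weighting
#'
#' Fits per-network weights by regressing a query co-membership target over
#' gene pairs: pairs with both endpoints in the query have target 1, pairs
#' with exactly one query endpoint have target 0 (pairs touching no query
#' gene carry no information about the query and are excluded). The
#' predictors are the normalized edge weights of each candidate network on
#' those pairs. Coefficients are found by non-negative least squares with an
#' unpenalized intercept and a small ridge penalty on the network
#' coefficients to stabilize collinear (near-duplicate) networks. Networks
#' whose edges align with query co-membership are up-weighted; irrelevant
#' networks are driven to zero. If every coefficient is zero the method
#' falls back to equal weights with a warning. Weights are rescaled to sum
#' to one.
#'
#' @param networks List of normalized [sparse_network]s (see
#'   [normalize_symmetric]).
#' @param query_indices Universe indices of the query genes (at least 2).
#' @param ridge Non-negative ridge penalty on network coefficients
#'   (default 1e-3).
#' @return A `network_weights` object with method `"adaptive"` (or
#'   `"equal"` after fallback).
#' @export
weight_query_adaptive <- function(networks, query_indices, ridge = 1e-3) {
  if (length(networks) == 0L) stop("no networks to weight")
  query_indices <- unique(as.integer(query_indices))
  if (length(query_indices) < 2L) {
    stop("query-adaptive weighting needs at least 2 query genes; use weight_equal()")
  }
  stopifnot(ridge >= 0)
  n <- nrow(networks[[1L]]$adjacency)
  m <- length(networks)
  nm <- vapply(networks, function(x) x$meta$name, character(1))
  q <- query_indices
  nq <- setdiff(seq_len(n), q)
  # pair design: query-query pairs (target 1) then query-other pairs (target 0)
  qq <- utils::combn(q, 2L)
  pi_ <- c(qq[1L, ], rep(q, each = length(nq)))
  pj_ <- c(qq[2L, ], rep(nq, times = length(q)))
  t_ <- c(rep(1, ncol(qq)), rep(0, length(q) * length(nq)))
  X <- matrix(0, length(t_), m)
  for (k in seq_len(m)) {
    X[, k] <- networks[[k]]$adjacency[cbind(pi_, pj_)]
  }
  X <- cbind(1, X)                               # unpenalized intercept
  if (ridge > 0) {
    X <- rbind(X, cbind(0, diag(sqrt(ridge), m)))
    t_ <- c(t_, numeric(m))
  }
  beta <- nnls_solve(X, t_, free = c(TRUE, rep(FALSE, m)))
  w <- pmax(beta[-1L], 0)
  if (!any(w > 0)) {
    warning("all adaptive network weights were zero; falling back to equal weights")
    return(weight_equal(networks))
  }
  new_network_weights(stats::setNames(w / sum(w), nm), "adaptive")
}

#' Combine weighted networks into a composite
#'
#' The composite adjacency is the weighted sum of the (normalized) source
#' adjacencies: each edge weight is multiplied by its network's weight, the
#' union of all edges is taken, and multiple edges between the same pair are
#' collapsed into one whose weight is the sum of the individual weighted
#' edge weights. Per-pair provenance is kept for every contributing network
#' so the collapse can later be undone for display; networks with weight 0
#' contribute nothing and appear in no provenance record.
#'
#' @param networks List of normalized [sparse_network]s.
#' @param weights A `network_weights` covering every network by name.
#' @return An object of class `composite_network` with `adjacency` (sparse
#'   symmetric), `provenance` (data frame with one row per contributing
#'   network per pair: `i`, `j` with i < j, `network`, `group`,
#'   `publication`, `raw_weight`, `norm_weight`, `alpha`, `contribution`),
#'   and the `weights` used.
#' @export
combine <- function(networks, weights) {
  stopifnot(inherits(weights, "network_weights"))
  if (length(networks) == 0L) stop("no networks to combine")
  nm <- vapply(networks, function(x) x$meta$name, character(1))
  missing_w <- setdiff(nm, names(weights$weights))
  if (length(missing_w)) {
    stop(sprintf("weights missing for network(s): %s",
                 paste(missing_w, collapse = ", ")))
  }
  n <- nrow(networks[[1L]]$adjacency)
  total <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n))
  prov <- vector("list", length(networks))
  for (k in seq_along(networks)) {
    net <- networks[[k]]
    if (nrow(net$adjacency) != n) {
      stop(sprintf("network '%s' dimension mismatch", net$meta$name))
    }
    a <- weights$weights[[net$meta$name]]
    if (a == 0) next
    total <- total + a * net$adjacency
    e <- upper_edges(net$adjacency)
    if (length(e$i) == 0L) next
    raw <- if (!is.null(net$raw)) net$raw[cbind(e$i, e$j)] else e$x
    prov[[k]] <- data.frame(
      i = e$i, j = e$j,
      network = net$meta$name, group = net$meta$group,
      publication = net$meta$publication,
      raw_weight = raw, norm_weight = e$x,
      alpha = a, contribution = a * e$x,
      stringsAsFactors = FALSE
    )
  }
  prov <- do.call(rbind, prov[!vapply(prov, is.null, logical(1))])
  if (is.null(prov)) {
    prov <- data.frame(i = integer(0), j = integer(0), network = character(0),
                       group = character(0), publication = character(0),
                       raw_weight = numeric(0), norm_weight = numeric(0),
                       alpha = numeric(0), contribution = numeric(0))
  }
  structure(
    list(adjacency = Matrix::drop0(total), provenance = prov, weights = weights),
    class = "composite_network"
  )
}

#' @export
print.composite_network <- function(x, ...) {
  cat(sprintf("Composite network: %d genes, %d edges, %d source networks (%s weighting)\n",
              nrow(x$adjacency), length(x$adjacency@x) %/% 2L,
              length(x$weights$weights), x$weights$method))
  invisible(x)
}

#' Collapse a composite into per-group display edges
#'
#' For display, a gene pair shows at most one edge per evidence group that
#' contributed to it: the display edge's weight is the sum of the
#' weight-scaled contributions of the group's networks on that pair, and its
#' `sources` record every contributing network with its original (raw) edge
#' weight and publication text. Summed over groups, display-edge weights
#' reconstruct the composite entry exactly.
#'
#' @param composite A [combine] result.
#' @param gene_subset Universe indices; only pairs with both endpoints in
#'   the subset are displayed.
#' @return A data frame of class `display_edges`: `gene_a`, `gene_b`
#'   (indices, a < b), `group`, `weight`, and a list-column `sources` of
#'   data frames (`network`, `raw_weight`, `publication`).
#' @export
collapse_for_display <- function(composite, gene_subset) {
  stopifnot(inherits(composite, "composite_network"))
  gene_subset <- unique(as.integer(gene_subset))
  p <- composite$provenance
  p <- p[p$i %in% gene_subset & p$j %in% gene_subset, , drop = FALSE]
  if (nrow(p) == 0L) {
    out <- data.frame(gene_a = integer(0), gene_b = integer(0),
                      group = character(0), weight = numeric(0))
    out$sources <- list()
    class(out) <- c("display_edges", "data.frame")
    return(out)
  }
  key <- paste(p$i, p$j, p$group, sep = "\r")
  ord <- order(p$i, p$j, p$group, p$network, method = "radix")
  p <- p[ord, ]
  key <- key[ord]
  first <- !duplicated(key)
  weight <- as.vector(rowsum(p$contribution, key, reorder = FALSE)[, 1L])
  sources <- split(
    data.frame(network = p$network, raw_weight = p$raw_weight,
               publication = p$publication, stringsAsFactors = FALSE),
    factor(key, levels = unique(key))
  )
  out <- data.frame(
    gene_a = p$i[first], gene_b = p$j[first], group = p$group[first],
    weight = weight, stringsAsFactors = FALSE
  )
  out$sources <- unname(sources)
  rownames(out) <- NULL
  class(out) <- c("display_edges", "data.frame")
  out
}
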