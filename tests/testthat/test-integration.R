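# Brute-force NNLS oracle: minimize ||X b - y||^2 with b >= 0 on constrained
# columns by enumerating active sets and keeping the feasible minimum.
nnls_oracle <- function(X, y, free) {
  p <- ncol(X)
  constrained <- which(!free)
  best <- NULL; best_rss <- Inf
  for (bits in 0:(2^length(constrained) - 1)) {
    on <- constrained[bitwAnd(bits, 2^(seq_along(constrained) - 1)) > 0]
    cols <- sort(c(which(free), on))
    b <- numeric(p)
    if (length(cols)) {
      fit <- qr.coef(qr(X[, cols, drop = FALSE]), y)
      fit[is.na(fit)] <- 0
      b[cols] <- fit
    }
    if (any(b[constrained] < -1e-12)) next
    rss <- sum((y - X %*% b)^2)
    if (rss < best_rss - 1e-12) { best_rss <- rss; best <- b }
  }
  best
}

test_that("equal and group weighting split mass as documented", {
  nets <- lapply(1:4, function(k) edge_net(1L, 2L, 1, 4L, name = paste0("n", k)))
  expect_equal(unname(weight_equal(nets)$weights), rep(0.25, 4))
  expect_equal(unname(weight_equal(nets[1])$weights), 1.0)
  expect_error(weight_equal(list()), "no networks")

  grouped <- list(
    edge_net(1L, 2L, 1, 4L, name = "c1", group = "coexp"),
    edge_net(1L, 2L, 1, 4L, name = "c2", group = "coexp"),
    edge_net(1L, 3L, 1, 4L, name = "p1", group = "ppi")
  )
  w <- weight_by_group(grouped)$weights
  expect_equal(unname(w[c("c1", "c2", "p1")]), c(0.25, 0.25, 0.5))

  single_group <- weight_by_group(grouped[1:2])$weights
  expect_equal(unname(single_group), rep(0.5, 2))
  w3 <- weight_by_group(list(
    edge_net(1L, 2L, 1, 4L, name = "a", group = "g1"),
    edge_net(1L, 2L, 1, 4L, name = "b", group = "g2"),
    edge_net(1L, 2L, 1, 4L, name = "c", group = "g3")
  ))$weights
  expect_equal(unname(w3), rep(1 / 3, 3))
})

test_that("query-adaptive weighting matches the enumerated NNLS oracle", {
  n <- 8L
  q <- c(1L, 2L, 3L)
  # first network: exactly the query-query clique; second: disjoint pairs
  relevant <- normalize_symmetric(
    edge_net(c(1L, 1L, 2L), c(2L, 3L, 3L), rep(1, 3), n, name = "rel"))
  irrelevant <- normalize_symmetric(
    edge_net(c(5L, 6L), c(6L, 7L), rep(1, 2), n, name = "irr"))
  nets <- list(relevant, irrelevant)
  w <- weight_query_adaptive(nets, q, ridge = 1e-3)
  expect_gt(w$weights[["rel"]], w$weights[["irr"]])
  expect_equal(sum(w$weights), 1.0)

  # oracle on the explicitly enumerated pair design
  nq <- setdiff(seq_len(n), q)
  qq <- utils::combn(q, 2L)
  pi_ <- c(qq[1, ], rep(q, each = length(nq)))
  pj_ <- c(qq[2, ], rep(nq, times = length(q)))
  t_ <- c(rep(1, ncol(qq)), rep(0, length(q) * length(nq)))
  X <- cbind(1,
             relevant$adjacency[cbind(pi_, pj_)],
             irrelevant$adjacency[cbind(pi_, pj_)])
  ridge <- 1e-3
  Xa <- rbind(X, cbind(0, diag(sqrt(ridge), 2)))
  ya <- c(t_, 0, 0)
  b <- nnls_oracle(Xa, ya, free = c(TRUE, FALSE, FALSE))
  expect_equal(unname(w$weights), pmax(b[-1], 0) / sum(pmax(b[-1], 0)),
               tolerance = 1e-8)
})

test_that("adaptive weighting falls back to equal weights when uninformative", {
  n <- 8L
  nets <- lapply(1:2, function(k) {
    normalize_symmetric(edge_net(5L, 6L, 1, n, name = paste0("n", k)))
  })
  expect_warning(w <- weight_query_adaptive(nets, c(1L, 2L)), "equal weights")
  expect_equal(w$method, "equal")
  expect_equal(unname(w$weights), c(0.5, 0.5))
  expect_error(weight_query_adaptive(nets, 1L), "at least 2 query genes")
})

test_that("duplicated networks share the single-copy weight between them", {
  n <- 10L
  q <- c(1L, 2L, 3L, 4L)
  base <- edge_net(c(1L, 2L, 3L, 1L), c(2L, 3L, 4L, 4L), rep(1, 4), n,
                   name = "a")
  dup <- base; dup$meta$name <- "b"
  noise <- edge_net(c(6L, 7L), c(7L, 8L), rep(1, 2), n, name = "z")
  solo <- weight_query_adaptive(
    list(normalize_symmetric(base), normalize_symmetric(noise)), q)
  pair <- weight_query_adaptive(
    list(normalize_symmetric(base), normalize_symmetric(dup),
         normalize_symmetric(noise)), q)
  # the two copies together carry what the single copy carried (weights are
  # normalized to sum 1, so compare relative to the noise network)
  ratio_solo <- solo$weights[["a"]] / max(solo$weights[["z"]], 1e-12)
  ratio_pair <- (pair$weights[["a"]] + pair$weights[["b"]]) /
    max(pair$weights[["z"]], 1e-12)
  expect_equal(ratio_pair, ratio_solo, tolerance = 1e-4)
})

test_that("adaptive weights are invariant to network list order", {
  fx <- generate_fixture(fixture_spec(n_genes = 60, n_modules = 2,
                                      module_size = 12, seed = 5))
  nets <- lapply(fx$db$networks, normalize_symmetric)
  q <- 1:5
  w1 <- weight_query_adaptive(nets, q)$weights
  w2 <- weight_query_adaptive(rev(nets), q)$weights
  expect_equal(w1[sort(names(w1))], w2[sort(names(w2))], tolerance = 1e-8)
})

test_that("composite combination is the weighted edge sum with provenance", {
  n <- 5L
  n1 <- edge_net(1L, 2L, 0.3, n, name = "a", group = "coexp")
  n2 <- edge_net(1L, 2L, 0.5, n, name = "b", group = "ppi")
  w_unit <- structure(list(weights = c(a = 1, b = 1), method = "equal"),
                      class = "network_weights")
  comp <- combine(list(n1, n2), w_unit)
  expect_equal(comp$adjacency[1, 2], 0.8)
  expect_equal(nrow(comp$provenance), 2L)

  # zero-weight network contributes nothing and leaves no provenance
  w01 <- structure(list(weights = c(a = 0, b = 1), method = "equal"),
                   class = "network_weights")
  comp01 <- combine(list(n1, n2), w01)
  expect_equal(as.matrix(comp01$adjacency), as.matrix(n2$adjacency))
  expect_equal(unique(comp01$provenance$network), "b")

  # disjoint edge sets: composite edge count is the sum
  d1 <- edge_net(1L, 2L, 1, n, name = "a")
  d2 <- edge_net(3L, 4L, 1, n, name = "b")
  compd <- combine(list(d1, d2), w_unit)
  expect_equal(length(compd$adjacency@x) %/% 2L, 2L)

  expect_error(combine(list(n1, edge_net(1L, 2L, 1, 7L, name = "b")), w_unit),
               "dimension")
  expect_error(combine(list(n1, n2),
                       structure(list(weights = c(a = 1), method = "equal"),
                                 class = "network_weights")),
               "missing")
})

test_that("combine is linear in the weight vector", {
  set.seed(31)
  n <- 12L
  nets <- lapply(1:3, function(k) {
    w <- random_graph(n, 0.3)
    sparse_network(w, network_meta(paste0("n", k), "test-group"))
  })
  mk_w <- function(v) structure(list(weights = stats::setNames(v, c("n1", "n2", "n3")),
                                     method = "equal"), class = "network_weights")
  a <- c(0.2, 0.5, 0.1); b <- c(0.3, 0.1, 0.6)
  lhs <- combine(nets, mk_w(a + b))$adjacency
  rhs <- combine(nets, mk_w(a))$adjacency + combine(nets, mk_w(b))$adjacency
  expect_equal(as.matrix(lhs), as.matrix(rhs), tolerance = 1e-12)
})

test_that("display collapse yields one edge per group whose weights conserve the composite", {
  n <- 6L
  nets <- c(
    lapply(1:5, function(k) edge_net(1L, 2L, 0.1 * k, n,
                                     name = paste0("co", k),
                                     group = "co-expression",
                                     publication = paste("pub", k))),
    lapply(1:2, function(k) edge_net(1L, 2L, 0.2 * k, n,
                                     name = paste0("pi", k),
                                     group = "physical-interaction"))
  )
  normalized <- lapply(nets, normalize_symmetric)
  w <- weight_equal(normalized)
  comp <- combine(normalized, w)
  edges <- collapse_for_display(comp, 1:2)

  # one display edge per contributing group for the shared pair
  expect_equal(nrow(edges), 2L)
  expect_setequal(edges$group, c("co-expression", "physical-interaction"))
  co <- edges[edges$group == "co-expression", ]
  expect_equal(nrow(co$sources[[1]]), 5L)
  expect_equal(co$sources[[1]]$publication[1], "pub 1")
  # raw (pre-normalization) weights surface in the sources
  expect_setequal(co$sources[[1]]$raw_weight, 0.1 * (1:5))

  # conservation: per-pair display weights sum to the composite entry
  total <- sum(edges$weight)
  expect_equal(total, comp$adjacency[1, 2], tolerance = 1e-9)

  # pairs outside the subset are not displayed
  expect_equal(nrow(collapse_for_display(comp, 3:4)), 0L)

  # single network: display weight is alpha * normalized weight
  one <- combine(normalized[1], structure(
    list(weights = c(co1 = 0.4), method = "equal"), class = "network_weights"))
  e1 <- collapse_for_display(one, 1:2)
  expect_equal(e1$weight, 0.4 * normalized[[1]]$adjacency[1, 2])
})

test_that("conservation holds pairwise on random multi-group fixtures", {
  set.seed(37)
  for (rep in 1:3) {
    n <- 15L
    nets <- lapply(1:4, function(k) {
      sparse_network(random_graph(n, 0.25),
                     network_meta(paste0("n", k),
                                  c("g1", "g2")[1 + k %% 2]))
    })
    normalized <- lapply(nets, normalize_symmetric)
    comp <- combine(normalized, weight_by_group(normalized))
    edges <- collapse_for_display(comp, seq_len(n))
    key <- paste(edges$gene_a, edges$gene_b)
    per_pair <- tapply(edges$weight, key, sum)
    for (k in names(per_pair)) {
      ij <- as.integer(strsplit(k, " ")[[1]])
      expect_equal(unname(per_pair[[k]]), comp$adjacency[ij[1], ij[2]],
                   tolerance = 1e-9)
    }
    # every nonzero composite pair has at least one provenance record
    e <- as.matrix(comp$adjacency)
    nz <- which(e > 0 & upper.tri(e), arr.ind = TRUE)
    expect_equal(nrow(unique(comp$provenance[, c("i", "j")])), nrow(nz))
  }
})
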