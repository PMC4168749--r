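test_that("edge-list import symmetrizes, sums duplicates and drops self-edges", {
  u <- tiny_universe(4)
  meta <- network_meta("n1", "test-group")
  net <- read_edge_list(write_tsv_lines("G1\tG2\t0.5"), u, meta)
  expect_equal(net$adjacency[1, 2], 0.5)
  expect_equal(net$adjacency[2, 1], 0.5)
  expect_equal(network_edge_count(net), 1L)

  dup <- read_edge_list(write_tsv_lines(c("G1\tG2\t0.3", "G2\tG1\t0.5")), u, meta)
  expect_equal(dup$adjacency[1, 2], 0.8)
  expect_equal(network_edge_count(dup), 1L)

  # missing weight defaults to 1; synonym resolution applies
  syn <- read_edge_list(write_tsv_lines("alt1\tG3"), u, meta)
  expect_equal(syn$adjacency[1, 3], 1.0)

  mixed <- read_edge_list(
    write_tsv_lines(c("G1\tG1\t1.0", "G1\tnope\t1", "G1\tG2\t2")), u, meta)
  rep <- attr(mixed, "import_report")
  expect_equal(rep$dropped_self_edges, 1L)
  expect_equal(rep$skipped_unresolved, 1L)
  expect_equal(rep$used, 1L)

  expect_error(read_edge_list(write_tsv_lines("G1\tG1\t1.0"), u, meta),
               "no resolvable edges")
})

test_that("malformed edge rows raise errors naming the line", {
  u <- tiny_universe(3)
  meta <- network_meta("n1", "test-group")
  expect_error(read_edge_list(write_tsv_lines(c("G1\tG2\t1", "G1\tG3\tbad")),
                              u, meta), "line 2")
  expect_error(read_edge_list(write_tsv_lines("G1\tG2\t-0.5"), u, meta),
               "line 1.*negative|negative.*line 1")
  expect_error(network_meta("n", ""), "non-empty")
})

test_that("edge-list import is invariant to row order", {
  u <- tiny_universe(6)
  meta <- network_meta("n1", "test-group")
  rows <- c("G1\tG2\t0.4", "G2\tG3\t0.7", "G1\tG5\t0.1", "G4\tG6\t0.9",
            "G1\tG2\t0.2")
  a <- read_edge_list(write_tsv_lines(rows), u, meta)
  b <- read_edge_list(write_tsv_lines(rev(rows)), u, meta)
  expect_equal(as.matrix(a$adjacency), as.matrix(b$adjacency))
})

test_that("symmetric normalization matches the dense oracle and bounds the spectrum", {
  u <- tiny_universe(2)
  # single edge of any weight normalizes to exactly 1
  for (w in c(0.01, 1, 42)) {
    net <- edge_net(1L, 2L, w, 2L)
    expect_equal(normalize_symmetric(net)$adjacency[1, 2], 1.0)
  }

  # path A-B-C with unit weights: off-diagonal entries 1/sqrt(2)
  path3 <- edge_net(c(1L, 2L), c(2L, 3L), c(1, 1), 3L)
  norm <- normalize_symmetric(path3)
  expect_equal(norm$adjacency[1, 2], 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(norm$adjacency[2, 3], 1 / sqrt(2), tolerance = 1e-12)

  set.seed(7)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    w <- random_graph(n)
    w[, n] <- 0; w[n, ] <- 0       # keep one isolated gene
    net <- sparse_network(w, network_meta("r", "test-group"))
    got <- as.matrix(normalize_symmetric(net)$adjacency)
    expect_equal(got, dense_normalize(w), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(all(got[n, ] == 0))               # isolated row stays zero
    expect_lte(max(abs(got)), 1 + 1e-12)          # entries bounded by 1
    expect_lte(max(abs(eigen(got, symmetric = TRUE,
                             only.values = TRUE)$values)), 1 + 1e-10)
  }
})

test_that("binary network files round-trip bit-exactly and reject corruption", {
  u <- tiny_universe(10)
  set.seed(11)
  w <- random_graph(10)
  net <- sparse_network(w, network_meta(
    "bin-net", "physical-interaction", source_description = "desc",
    publication = "pub text", open_license = FALSE, default_selected = TRUE
  ))
  path <- withr::local_tempfile(fileext = ".gmnw")
  write_binary(net, path)
  back <- read_binary(path, u)
  expect_identical(as.matrix(back$adjacency), as.matrix(net$adjacency))
  expect_identical(unclass(back$meta), unclass(net$meta))

  # empty network: n preserved, zero edges
  empty <- sparse_network(Matrix::sparseMatrix(
    i = integer(0), j = integer(0), x = numeric(0), dims = c(10, 10)
  ), network_meta("empty", "test-group"))
  write_binary(empty, path)
  back_empty <- read_binary(path, u)
  expect_equal(nrow(back_empty$adjacency), 10L)
  expect_equal(network_edge_count(back_empty), 0L)

  # truncation must error, not yield a partial network
  write_binary(net, path)
  full <- readBin(path, "raw", file.size(path))
  writeBin(full[seq_len(length(full) - 25L)], path)
  expect_error(read_binary(path, u), "truncated")

  writeBin(charToRaw("NOPE"), path)
  expect_error(read_binary(path, u), "GMNW")

  write_binary(net, path)
  expect_error(read_binary(path, tiny_universe(4)), "does not match universe")
})

test_that("database subset filtering honours core and open-license flags", {
  u <- tiny_universe(4)
  mk <- function(name, core, open) {
    edge_net(1L, 2L, 1, 4L, name = name, default_selected = core,
             open_license = open)
  }
  db <- network_db(u, list(mk("a", TRUE, TRUE), mk("b", FALSE, TRUE),
                           mk("c", FALSE, FALSE)))
  expect_equal(length(filter_database(db, core_only = TRUE)$networks), 1L)
  expect_equal(length(filter_database(db, open_license_only = TRUE)$networks), 2L)
  expect_equal(length(filter_database(db)$networks), 3L)
  expect_error(filter_database(db, core_only = TRUE, open_license_only = FALSE)$networks[[2]],
               "subscript")
  db_open <- network_db(u, list(mk("a", TRUE, TRUE), mk("b", FALSE, TRUE)))
  expect_equal(length(filter_database(db_open, open_license_only = TRUE)$networks), 2L)
  expect_error(filter_database(network_db(u, list(mk("a", FALSE, FALSE))),
                               core_only = TRUE, open_license_only = TRUE),
               "no networks")
})

test_that("sparse_network constructor enforces its invariants", {
  m <- network_meta("n", "test-group")
  asym <- matrix(c(0, 1, 0.5, 0), 2, 2)
  expect_error(sparse_network(asym, m), "symmetric")
  withdiag <- matrix(c(1, 0.5, 0.5, 0), 2, 2)
  expect_error(sparse_network(withdiag, m), "diagonal")
  neg <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(sparse_network(neg, m), "non-negative")
})
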