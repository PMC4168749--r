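#' Network metadata
#'
#' Descriptive metadata attached to every source network: the evidence group
#' it belongs to (e.g. "co-expression", "physical-interaction",
#' "shared-protein-domains"), free-text provenance, and the two boolean flags
#' used for database subsetting (`default_selected` marks membership of the
#' core subset; `open_license` marks data with no restrictions on use).
#'
#' @param name Network name, unique within a database.
#' @param group Evidence group (non-empty).
#' @param source_description Free text on how the data was collected.
#' @param publication Free-text citation.
#' @param open_license Logical; data carries no use restrictions.
#' @param default_selected Logical; network belongs to the core subset.
#' @return A list of class `network_meta`.
#' @export
network_meta <- function(name, group,
                         source_description = "", publication = "",
                         open_license = TRUE, default_selected = TRUE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.character(group) || length(group) != 1L || !nzchar(group)) {
    stop("network group must be a non-empty string")
  }
  structure(
    list(
      name = name, group = group,
      source_description = as.character(source_description),
      publication = as.character(publication),
      open_license = isTRUE(open_license),
      default_selected = isTRUE(default_selected)
    ),
    class = "network_meta"
  )
}

#' Sparse symmetric gene network
#'
#' Wraps a symmetric, non-negative, zero-diagonal sparse adjacency matrix
#' over a gene universe together with its [network_meta]. All stored weights
#' are strictly positive; explicit zeros are dropped.
#'
#' @param adjacency An n-by-n sparse (or dense) symmetric matrix.
#' @param meta A [network_meta].
#' @return An object of class `sparse_network` with elements `adjacency`
#'   (a `dgCMatrix`) and `meta`.
#' @export
sparse_network <- function(adjacency, meta) {
  stopifnot(inherits(meta, "network_meta"))
  adjacency <- methods::as(methods::as(adjacency, "CsparseMatrix"), "generalMatrix")
  if (nrow(adjacency) != ncol(adjacency)) stop("adjacency must be square")
  sym_err <- max(abs(adjacency - Matrix::t(adjacency)))
  if (sym_err > 1e-12) {
    stop(sprintf("adjacency not symmetric (max asymmetry %.3g)", sym_err))
  }
  if (any(Matrix::diag(adjacency) != 0)) stop("adjacency must have zero diagonal")
  if (length(adjacency@x) && any(adjacency@x < 0)) {
    stop("network weights must be non-negative")
  }
  adjacency <- Matrix::drop0(adjacency)
  structure(list(adjacency = adjacency, meta = meta), class = "sparse_network")
}

#' @export
print.sparse_network <- function(x, ...) {
  cat(sprintf(
    "Sparse network '%s' [%s]: %d genes, %d edges\n",
    x$meta$name, x$meta$group, nrow(x$adjacency), network_edge_count(x)
  ))
  invisible(x)
}

#' Number of undirected edges in a network
#' @param net A `sparse_network`.
#' @return Integer edge count (each unordered pair counted once).
#' @export
network_edge_count <- function(net) {
  length(net$adjacency@x) %/% 2L
}

# Internal: edge table (i < j) of a symmetric sparse adjacency.
upper_edges <- function(adjacency) {
  tm <- methods::as(methods::as(adjacency, "TsparseMatrix"), "generalMatrix")
  i <- tm@i + 1L
  j <- tm@j + 1L
  keep <- i < j
  list(i = i[keep], j = j[keep], x = tm@x[keep])
}

#' Import a tab-delimited edge list as a network
#'
#' Rows are `geneA<TAB>geneB[<TAB>weight]`; a missing weight defaults to 1.
#' Gene names are resolved case-insensitively against the universe; rows
#' with unresolvable names are skipped and counted. Self-edges are dropped
#' (propagation handles the diagonal through the identity term) and duplicate
#' pairs are summed, consistent with the collapse-by-sum rule used when
#' composing networks. The import is invariant to the row order of the file.
#'
#' @param path Edge-list TSV path.
#' @param universe A [gene_universe].
#' @param meta A [network_meta].
#' @return A [sparse_network] with an `import_report` attribute: a list with
#'   counts of parsed rows, skipped unresolvable rows, dropped self-edges and
#'   dropped zero-weight rows.
#' @export
read_edge_list <- function(path, universe, meta) {
  stopifnot(inherits(universe, "gene_universe"))
  if (!file.exists(path)) stop(sprintf("edge list not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop(sprintf("edge list is empty: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop(sprintf("line %d: expected at least two tab-separated columns",
                 lineno[which(nf < 2L)[1L]]))
  }
  a <- vapply(fields, `[`, character(1), 1L)
  b <- vapply(fields, `[`, character(1), 2L)
  w <- rep(1.0, length(fields))
  has_w <- nf >= 3L
  if (any(has_w)) {
    raw_w <- vapply(fields[has_w], `[`, character(1), 3L)
    parsed <- suppressWarnings(as.numeric(raw_w))
    if (anyNA(parsed)) {
      bad <- which(has_w)[which(is.na(parsed))[1L]]
      stop(sprintf("line %d: non-numeric weight '%s'",
                   lineno[bad], raw_w[which(is.na(parsed))[1L]]))
    }
    if (any(parsed < 0)) {
      bad <- which(has_w)[which(parsed < 0)[1L]]
      stop(sprintf("line %d: negative weight %s", lineno[bad],
                   format(parsed[which(parsed < 0)[1L]])))
    }
    w[has_w] <- parsed
  }
  ia <- resolve(trimws(a), universe)
  ib <- resolve(trimws(b), universe)
  unresolved <- is.na(ia) | is.na(ib)
  self <- !unresolved & ia == ib
  zero <- !unresolved & !self & w == 0
  ok <- !unresolved & !self & !zero
  report <- list(
    rows = length(lines),
    used = sum(ok),
    skipped_unresolved = sum(unresolved),
    dropped_self_edges = sum(self),
    dropped_zero_weight = sum(zero)
  )
  if (report$used == 0L) {
    stop(sprintf(
      "no resolvable edges in %s (%d unresolved, %d self-edges)",
      path, report$skipped_unresolved, report$dropped_self_edges
    ))
  }
  n <- length(universe)
  i <- pmin(ia[ok], ib[ok])
  j <- pmax(ia[ok], ib[ok])
  # sparseMatrix sums duplicated (i, j) entries, giving the duplicate-sum rule
  upper <- Matrix::sparseMatrix(i = i, j = j, x = w[ok], dims = c(n, n))
  net <- sparse_network(upper + Matrix::t(upper), meta)
  attr(net, "import_report") <- report
  net
}

#' Symmetric degree normalization
#'
#' Replaces the adjacency W by `D^(-1/2) W D^(-1/2)` where D is the diagonal
#' of row sums. This bounds the spectral radius of the result by 1 and stops
#' dense, heavily weighted networks from dominating the composite. Rows of
#' isolated genes stay zero. The original adjacency is retained in the
#' `raw` element so per-edge provenance can report the original weights.
#'
#' @param net A [sparse_network].
#' @return A [sparse_network] whose `adjacency` is normalized and which
#'   carries the pre-normalization matrix as `raw`.
#' @export
normalize_symmetric <- function(net) {
  stopifnot(inherits(net, "sparse_network"))
  w <- net$adjacency
  d <- Matrix::rowSums(w)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  norm <- Matrix::Diagonal(x = dinv) %*% w %*% Matrix::Diagonal(x = dinv)
  out <- sparse_network(norm, net$meta)
  out$raw <- if (is.null(net$raw)) net$adjacency else net$raw
  out
}

#' Network database
#'
#' Bundles a universe, a list of source networks sharing that universe, and
#' an optional gene-by-attribute incidence matrix (attributes are non-gene
#' nodes such as protein domains, attached to the genes carrying them).
#'
#' @param universe A [gene_universe].
#' @param networks List of [sparse_network]s over `universe`.
#' @param attributes Optional sparse binary n-by-p incidence matrix with
#'   unique column names (attribute names).
#' @return An object of class `network_db`.
#' @export
network_db <- function(universe, networks, attributes = NULL) {
  stopifnot(inherits(universe, "gene_universe"))
  n <- length(universe)
  for (net in networks) {
    stopifnot(inherits(net, "sparse_network"))
    if (nrow(net$adjacency) != n) {
      stop(sprintf("network '%s' dimension %d does not match universe size %d",
                   net$meta$name, nrow(net$adjacency), n))
    }
  }
  nm <- vapply(networks, function(x) x$meta$name, character(1))
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate network name: '%s'", nm[duplicated(nm)][1L]))
  }
  if (!is.null(attributes)) {
    attributes <- methods::as(attributes, "CsparseMatrix")
    if (nrow(attributes) != n) stop("attribute incidence rows must match universe")
    if (is.null(colnames(attributes)) || anyDuplicated(colnames(attributes))) {
      stop("attribute columns must carry unique names")
    }
  }
  structure(
    list(universe = universe, networks = networks, attributes = attributes),
    class = "network_db"
  )
}

#' @export
print.network_db <- function(x, ...) {
  groups <- table(vapply(x$networks, function(nw) nw$meta$group, character(1)))
  cat(sprintf("Network database: %d genes, %d networks (%s)%s\n",
              length(x$universe), length(x$networks),
              paste(sprintf("%s: %d", names(groups), groups), collapse = ", "),
              if (is.null(x$attributes)) ""
              else sprintf(", %d attributes", ncol(x$attributes))))
  invisible(x)
}

#' Filter a database to its core / open-license subsets
#'
#' The core subset keeps only networks selected by default; the open-license
#' subset keeps only networks whose data carries no use restrictions. Flags
#' combine conjunctively. The universe and attributes are unchanged.
#'
#' @param db A [network_db].
#' @param core_only Keep only `default_selected` networks.
#' @param open_license_only Keep only `open_license` networks.
#' @return A filtered [network_db]; errors if nothing survives.
#' @export
filter_database <- function(db, core_only = FALSE, open_license_only = FALSE) {
  stopifnot(inherits(db, "network_db"))
  keep <- vapply(db$networks, function(net) {
    (!core_only || net$meta$default_selected) &&
      (!open_license_only || net$meta$open_license)
  }, logical(1))
  if (!any(keep)) stop("no networks satisfy the requested subset flags")
  network_db(db$universe, db$networks[keep], db$attributes)
}
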