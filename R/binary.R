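#' Compact binary network files
#'
#' Networks are persisted as compact binary sparse matrices so a database can
#' be loaded and used directly without re-parsing text. The format (magic
#' `GMNW`, little-endian) stores only the upper triangle in CSR layout,
#' halving disk size; the symmetric adjacency is reconstructed on load.
#' Weights are 8-byte IEEE doubles, so round trips are bit-exact.
#'
#' Layout, all little-endian:
#' \preformatted{
#'   bytes 0-3   magic "GMNW"
#'   int32       format version (1)
#'   int32       n (universe size)
#'   int32       nnz (stored upper-triangle entries)
#'   int32[n+1]  CSR row pointers (0-based)
#'   int32[nnz]  0-based column indices
#'   double[nnz] weights
#'   int32       metadata byte length
#'   bytes       UTF-8 JSON metadata block
#' }
#'
#' @param net A [sparse_network].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_binary <- function(net, path) {
  stopifnot(inherits(net, "sparse_network"))
  e <- upper_edges(net$adjacency)
  n <- nrow(net$adjacency)
  ord <- order(e$i, e$j)
  i <- e$i[ord]; j <- e$j[ord]; x <- e$x[ord]
  row_ptr <- c(0L, cumsum(tabulate(i, nbins = n)))
  meta_json <- jsonlite::toJSON(unclass(net$meta), auto_unbox = TRUE)
  meta_raw <- charToRaw(as.character(meta_json))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("GMNW"), con)
  writeBin(c(1L, n, length(x)), con, size = 4L, endian = "little")
  writeBin(as.integer(row_ptr), con, size = 4L, endian = "little")
  writeBin(as.integer(j - 1L), con, size = 4L, endian = "little")
  writeBin(as.double(x), con, size = 8L, endian = "little")
  writeBin(length(meta_raw), con, size = 4L, endian = "little")
  writeBin(meta_raw, con)
  invisible(path)
}

read_exact <- function(con, what, n, size) {
  out <- readBin(con, what, n = n, size = size, endian = "little")
  if (length(out) != n) stop("binary network file is truncated")
  out
}

#' @rdname write_binary
#' @param universe The [gene_universe] the network is indexed against; its
#'   size must match the stored dimension.
#' @return `read_binary` returns the reconstructed [sparse_network].
#' @export
read_binary <- function(path, universe) {
  stopifnot(inherits(universe, "gene_universe"))
  if (!file.exists(path)) stop(sprintf("network file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4L)
  if (length(magic) != 4L || !identical(rawToChar(magic), "GMNW")) {
    stop(sprintf("not a GMNW network file: %s", path))
  }
  hdr <- read_exact(con, "integer", 3L, 4L)
  version <- hdr[1L]; n <- hdr[2L]; nnz <- hdr[3L]
  if (version != 1L) stop(sprintf("unsupported GMNW version %d", version))
  if (n != length(universe)) {
    stop(sprintf("network dimension %d does not match universe size %d",
                 n, length(universe)))
  }
  row_ptr <- read_exact(con, "integer", n + 1L, 4L)
  cols <- read_exact(con, "integer", nnz, 4L)
  vals <- read_exact(con, "double", nnz, 8L)
  meta_len <- read_exact(con, "integer", 1L, 4L)
  meta_raw <- readBin(con, "raw", n = meta_len)
  if (length(meta_raw) != meta_len) stop("binary network file is truncated")
  meta_list <- jsonlite::fromJSON(rawToChar(meta_raw))
  meta <- network_meta(
    name = meta_list$name, group = meta_list$group,
    source_description = meta_list$source_description %||% "",
    publication = meta_list$publication %||% "",
    open_license = isTRUE(meta_list$open_license),
    default_selected = isTRUE(meta_list$default_selected)
  )
  i <- rep.int(seq_len(n), diff(row_ptr))
  upper <- Matrix::sparseMatrix(i = i, j = cols + 1L, x = vals, dims = c(n, n))
  sparse_network(upper + Matrix::t(upper), meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
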