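#' Read a tab-delimited expression profile
#'
#' Expects a header row of sample names, gene names in column 1, and numeric
#' expression values in the remaining columns. Gene names are resolved
#' against the universe; unresolvable rows are skipped and counted, and
#' duplicate rows for the same gene are averaged. Missing or non-numeric
#' cells are errors (no imputation is attempted), as is a profile with fewer
#' than two samples.
#'
#' @param path Profile TSV path.
#' @param universe A [gene_universe].
#' @return An object of class `expression_profile` with `gene_indices`
#'   (universe indices, unique), `values` (genes-by-samples numeric matrix),
#'   `sample_names`, and an `import_report` attribute.
#' @export
read_profile <- function(path, universe) {
  stopifnot(inherits(universe, "gene_universe"))
  if (!file.exists(path)) stop(sprintf("profile file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) < 2L) stop(sprintf("profile has no data rows: %s", path))
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  sample_names <- header[-1L]
  if (length(sample_names) < 2L) {
    stop("expression profile needs at least 2 samples")
  }
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nf <- lengths(rows)
  expected <- length(sample_names) + 1L
  if (any(nf != expected)) {
    stop(sprintf("profile row %d has %d columns, expected %d",
                 which(nf != expected)[1L] + 1L, nf[nf != expected][1L], expected))
  }
  genes <- vapply(rows, `[`, character(1), 1L)
  vals <- matrix(NA_real_, nrow = length(rows), ncol = length(sample_names))
  for (r in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[r]][-1L]))
    if (anyNA(v)) {
      stop(sprintf("non-numeric value at profile row %d, sample '%s'",
                   r + 1L, sample_names[which(is.na(v))[1L]]))
    }
    vals[r, ] <- v
  }
  idx <- resolve(trimws(genes), universe)
  skipped <- sum(is.na(idx))
  vals <- vals[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) stop("no profile genes resolved against the universe")
  n_dup <- sum(duplicated(idx))
  if (n_dup > 0L) {
    u <- sort(unique(idx))
    counts <- as.vector(table(factor(idx, levels = u)))
    vals <- rowsum(vals, group = idx) / counts   # rowsum orders rows by sorted group
    idx <- u
  }
  structure(
    list(
      gene_indices = as.integer(idx),
      values = unname(vals),
      sample_names = sample_names
    ),
    class = "expression_profile",
    import_report = list(
      rows = length(rows), used = length(idx),
      skipped_unresolved = skipped, duplicates_averaged = n_dup
    )
  )
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("Expression profile: %d genes x %d samples\n",
              length(x$gene_indices), length(x$sample_names)))
  invisible(x)
}

#' Convert an expression profile to a co-expression network
#'
#' Computes pairwise Pearson correlation between gene expression rows, drops
#' non-positive correlations, and sparsifies by keeping each gene's `k`
#' most-correlated neighbours; a pair survives if either endpoint selects it
#' (union symmetrization), so increasing `k` never removes an edge. Edge
#' weight is the correlation itself, hence all weights lie in (0, 1]. Genes
#' with zero variance carry no information about co-expression and are
#' excluded (they get no incident edges).
#'
#' @param profile An [read_profile] result.
#' @param k Neighbours kept per gene (default 50, a common sparsification
#'   for co-expression graphs).
#' @param meta A [network_meta]; its group is conventionally
#'   `"co-expression"`.
#' @param universe_size Number of genes in the universe the adjacency is
#'   indexed against.
#' @return A [sparse_network] over the universe.
#' @export
profile_to_network <- function(profile, k = 50L, meta, universe_size) {
  stopifnot(inherits(profile, "expression_profile"), k >= 1L)
  v <- profile$values
  usable <- apply(v, 1L, stats::sd) > 0
  if (sum(usable) < 2L) {
    stop("fewer than 2 genes with non-zero variance; cannot build network")
  }
  v <- v[usable, , drop = FALSE]
  idx <- profile$gene_indices[usable]
  r <- stats::cor(t(v))
  diag(r) <- 0
  r[r <= 0] <- 0
  # clamp tiny numerical overshoot so weights stay within (0, 1]
  r[r > 1] <- 1
  m <- nrow(r)
  keep <- matrix(FALSE, m, m)
  for (g in seq_len(m)) {
    pos <- which(r[g, ] > 0)
    if (length(pos) == 0L) next
    top <- pos[order(r[g, pos], pos, decreasing = c(TRUE, FALSE), method = "radix")]
    top <- utils::head(top, k)
    keep[g, top] <- TRUE
  }
  keep <- keep | t(keep)   # union symmetrization
  sel <- which(keep & upper.tri(keep), arr.ind = TRUE)
  n <- universe_size
  upper <- Matrix::sparseMatrix(
    i = idx[sel[, 1L]], j = idx[sel[, 2L]],
    x = r[sel], dims = c(n, n)
  )
  sparse_network(upper + Matrix::t(upper), meta)
}
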