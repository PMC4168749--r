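#' On-disk network databases
#'
#' A local database is a directory holding `genome.tsv` (the organism's
#' genome table), `manifest.tsv` (one row per network: file, name, group,
#' flags, provenance text), the networks themselves as compact binary files
#' under `networks/`, and optionally `attributes.tsv` (long
#' `gene<TAB>attribute` format). [load_database] reads the whole directory
#' back into a [network_db].
#'
#' @name database-files
NULL

manifest_path <- function(db_dir) file.path(db_dir, "manifest.tsv")

manifest_columns <- c("file", "name", "group", "default_selected",
                      "open_license", "source_description", "publication")

read_manifest <- function(db_dir) {
  path <- manifest_path(db_dir)
  if (!file.exists(path)) {
    stop(sprintf("no database manifest at %s; run import-organism first", db_dir))
  }
  m <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character", quote = "")
  if (!identical(colnames(m), manifest_columns)) {
    stop(sprintf("malformed manifest at %s", path))
  }
  m
}

write_manifest <- function(db_dir, manifest) {
  utils::write.table(manifest, manifest_path(db_dir), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
}

#' @rdname database-files
#' @param db_dir Database directory.
#' @return `load_database` returns a [network_db].
#' @export
load_database <- function(db_dir) {
  if (!dir.exists(db_dir)) stop(sprintf("database directory not found: %s", db_dir))
  universe <- read_genome_table(file.path(db_dir, "genome.tsv"))
  manifest <- read_manifest(db_dir)
  networks <- lapply(seq_len(nrow(manifest)), function(r) {
    read_binary(file.path(db_dir, "networks", manifest$file[r]), universe)
  })
  attributes <- NULL
  attr_path <- file.path(db_dir, "attributes.tsv")
  if (file.exists(attr_path)) {
    attributes <- read_attribute_table(attr_path, universe)
  }
  network_db(universe, networks, attributes)
}

#' Read a gene-attribute incidence table
#'
#' Long format `gene<TAB>attribute`, one pair per row; unresolvable genes
#' are dropped.
#'
#' @param path TSV path.
#' @param universe A [gene_universe].
#' @return Sparse binary genes-by-attributes incidence matrix.
#' @export
read_attribute_table <- function(path, universe) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 2L
  g <- vapply(fields[ok], `[`, character(1), 1L)
  a <- vapply(fields[ok], `[`, character(1), 2L)
  idx <- resolve(trimws(g), universe)
  keep <- !is.na(idx)
  if (!any(keep)) stop(sprintf("no attribute rows resolved in %s", path))
  a <- trimws(a[keep]); idx <- idx[keep]
  lev <- sort(unique(a), method = "radix")
  pair_key <- paste(idx, a, sep = "\r")
  first <- !duplicated(pair_key)
  Matrix::sparseMatrix(
    i = idx[first], j = match(a[first], lev), x = 1,
    dims = c(length(universe), length(lev)), dimnames = list(NULL, lev)
  )
}
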