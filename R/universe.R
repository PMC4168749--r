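#' Gene universe: an organism's gene set with synonym resolution
#'
#' A `gene_universe` holds the ordered set of primary gene identifiers for an
#' organism together with a case-insensitive map from every known name
#' (primary IDs and synonyms) to the gene's index. All network and profile
#' matrices in a database are indexed against this universe, so it is built
#' once per organism and never reordered.
#'
#' @param primary_ids Character vector of unique primary identifiers, one per
#'   gene, in universe order.
#' @param synonyms List (same length as `primary_ids`) of character vectors of
#'   alternate identifiers for each gene. May be `NULL` for no synonyms.
#' @param organism_name Free-text organism label.
#'
#' @return An object of class `gene_universe` with elements `primary_ids`,
#'   `all_names` (every registered name, original case), `name_index`
#'   (integer vector mapping `tolower(all_names)` to universe indices) and
#'   `organism_name`. Indices are 1-based and dense (`1..n`).
#' @export
gene_universe <- function(primary_ids, synonyms = NULL, organism_name = "") {
  primary_ids <- as.character(primary_ids)
  if (length(primary_ids) == 0L) {
    stop("a gene universe needs at least one gene")
  }
  if (anyNA(primary_ids) || any(!nzchar(primary_ids))) {
    stop("primary IDs must be non-empty strings")
  }
  low <- tolower(primary_ids)
  if (anyDuplicated(low)) {
    dup <- primary_ids[duplicated(low)][1L]
    stop(sprintf("duplicate primary ID (case-insensitive): '%s'", dup))
  }
  n <- length(primary_ids)
  if (is.null(synonyms)) synonyms <- rep(list(character(0)), n)
  stopifnot(length(synonyms) == n)

  all_names <- primary_ids
  name_index <- seq_len(n)
  for (i in seq_len(n)) {
    syn <- unique(as.character(synonyms[[i]]))
    syn <- syn[nzchar(syn)]
    # a gene's own aliases may repeat its primary ID; drop those quietly
    syn <- syn[!tolower(syn) %in% tolower(c(primary_ids[i]))]
    syn <- syn[!duplicated(tolower(syn))]
    all_names <- c(all_names, syn)
    name_index <- c(name_index, rep(i, length(syn)))
  }
  low_all <- tolower(all_names)
  if (anyDuplicated(low_all)) {
    d <- low_all[duplicated(low_all)][1L]
    hits <- unique(name_index[low_all == d])
    stop(sprintf(
      "synonym '%s' maps to more than one gene: %s",
      all_names[match(d, low_all)],
      paste(primary_ids[hits], collapse = ", ")
    ))
  }
  structure(
    list(
      primary_ids = primary_ids,
      all_names = all_names,
      name_index = stats::setNames(name_index, low_all),
      organism_name = organism_name
    ),
    class = "gene_universe"
  )
}

#' Number of genes in a universe
#' @param x A `gene_universe`.
#' @param ... Ignored.
#' @export
length.gene_universe <- function(x) length(x$primary_ids)

#' @export
print.gene_universe <- function(x, ...) {
  cat(sprintf(
    "Gene universe%s: %d genes, %d registered names\n",
    if (nzchar(x$organism_name)) paste0(" (", x$organism_name, ")") else "",
    length(x$primary_ids), length(x$all_names)
  ))
  invisible(x)
}

#' Read an organism genome table
#'
#' Parses a tab-delimited genome file: one gene per row, first column the
#' primary identifier, remaining columns alternate identifiers and synonyms.
#' No header row is expected (pass `header = TRUE` if the file has one).
#' Blank lines and lines starting with `#` are skipped.
#'
#' Duplicate primary IDs, and synonyms shared between two different genes,
#' are hard errors naming the offending identifiers: silently reassigning a
#' name would corrupt every matrix built on the universe. Repetitions within
#' a single gene's own row are deduplicated without complaint.
#'
#' @param path Path to the genome TSV.
#' @param organism_name Optional organism label stored on the universe.
#' @param header If `TRUE`, discard the first non-comment row.
#' @return A [gene_universe].
#' @export
read_genome_table <- function(path, organism_name = "", header = FALSE) {
  if (!file.exists(path)) stop(sprintf("genome file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (header && length(lines) > 0L) lines <- lines[-1L]
  if (length(lines) == 0L) stop(sprintf("genome file has no data rows: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  primary <- vapply(fields, function(f) trimws(f[1L]), character(1))
  if (any(!nzchar(primary))) {
    stop(sprintf(
      "genome file row %d has an empty primary ID",
      which(!nzchar(primary))[1L]
    ))
  }
  syn <- lapply(fields, function(f) {
    s <- trimws(f[-1L])
    s[nzchar(s)]
  })
  gene_universe(primary, syn, organism_name = organism_name)
}

#' Resolve a gene name to its universe index
#'
#' Case-insensitive exact match against primary IDs and synonyms. Not-found
#' is a value (`NA`), not an error, so callers can report unresolved names.
#'
#' @param name Character vector of names to resolve.
#' @param universe A [gene_universe].
#' @return Integer vector of universe indices, `NA` where unmatched.
#' @export
resolve <- function(name, universe) {
  stopifnot(inherits(universe, "gene_universe"))
  idx <- universe$name_index[tolower(as.character(name))]
  names(idx) <- NULL
  as.integer(idx)
}

#' Autocomplete gene names by prefix
#'
#' Case-insensitive prefix match over all registered names (primary IDs and
#' synonyms), sorted lexicographically (C collation, so results are
#' locale-independent) and truncated to `limit`. The empty prefix matches
#' everything, yielding the first `limit` names.
#'
#' @param prefix Prefix string (may be empty).
#' @param universe A [gene_universe].
#' @param limit Maximum number of names to return (>= 1).
#' @return Character vector of matching names in their original case.
#' @export
autocomplete <- function(prefix, universe, limit = 10L) {
  stopifnot(inherits(universe, "gene_universe"), limit >= 1L)
  hits <- universe$all_names[startsWith(
    tolower(universe$all_names), tolower(prefix)
  )]
  hits <- sort(unique(hits), method = "radix")
  utils::head(hits, limit)
}

#' Resolve a list of gene names, reporting failures
#'
#' Resolves each name case-insensitively, deduplicates indices keeping
#' first-seen order (two names for the same gene count once), and reports
#' unresolved names rather than dropping them silently.
#'
#' @param names Character vector of gene names.
#' @param universe A [gene_universe].
#' @return A list with `indices` (integer, deduplicated, first-seen order)
#'   and `unresolved` (character). Errors if nothing resolves.
#' @export
resolve_gene_list <- function(names, universe) {
  names <- as.character(names)
  idx <- resolve(names, universe)
  unresolved <- names[is.na(idx)]
  idx <- idx[!is.na(idx)]
  idx <- idx[!duplicated(idx)]
  if (length(idx) == 0L) {
    stop("no query genes resolved against the universe")
  }
  list(indices = idx, unresolved = unresolved)
}
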