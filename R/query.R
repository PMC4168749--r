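#' Find the genes most related to a query list
#'
#' The central entry point: given a network database and a query gene list,
#' builds the weighted composite functional network and scores every gene's
#' relatedness to the query by label propagation. The pipeline is: resolve
#' the query names against the universe, optionally restrict the database to
#' its core / open-license subsets, symmetric-normalize each source network,
#' fit per-network weights, sum the weighted networks into the composite,
#' propagate the 0/1 query labels, rank the non-query genes, collapse the
#' composite into per-group display edges over the result genes, score
#' attributes, and (when annotation sets are supplied) annotate the result
#' set by hypergeometric enrichment.
#'
#' Unresolved query names are reported on the result, not fatal, unless no
#' name resolves. With fewer than two resolved query genes the adaptive
#' weighting falls back to equal weights (the co-membership regression needs
#' at least one query-query pair).
#'
#' @param db A [network_db].
#' @param query Character vector of gene names (or an integer vector of
#'   universe indices).
#' @param weighting `"adaptive"` (default), `"equal"` or `"group"`.
#' @param lambda Propagation smoothing strength (default 1).
#' @param n_related Maximum related genes to return (default 20; 0 shows
#'   only how the query genes interconnect).
#' @param n_attributes Maximum related attributes (default 20).
#' @param core_only,open_license_only Database subset flags.
#' @param ridge Ridge penalty for adaptive weighting.
#' @param annotations Optional named list of annotation member-index
#'   vectors; when given, an enrichment table over the result genes is
#'   attached.
#' @param tol,max_iter Conjugate-gradient controls passed to [propagate].
#' @return An object of class `netprop_result` with elements
#'   `query_genes` (resolved names), `query_indices`, `unresolved`,
#'   `related` (data frame `gene`, `index`, `score`), `attributes`,
#'   `display_edges` (with `gene_a_name`/`gene_b_name`), `weights`,
#'   `scores` (the full [propagate] result), `enrichment` (or `NULL`) and
#'   `config`.
#' @examples
#' fx <- generate_fixture(fixture_spec(n_genes = 60, n_modules = 2,
#'                                     module_size = 10, seed = 7))
#' res <- netprop_query(fx$db, fx$universe$primary_ids[1:4])
#' res
#' coef(res)
#' @export
netprop_query <- function(db, query,
                          weighting = c("adaptive", "equal", "group"),
                          lambda = 1, n_related = 20L, n_attributes = 20L,
                          core_only = FALSE, open_license_only = FALSE,
                          ridge = 1e-3, annotations = NULL,
                          tol = 1e-10, max_iter = NULL) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(db, "network_db"), lambda >= 0, n_related >= 0L,
            n_attributes >= 0L)
  n <- length(db$universe)
  if (is.numeric(query)) {
    qi <- unique(as.integer(query))
    if (any(qi < 1L | qi > n)) stop("query index outside the universe")
    resolved <- list(indices = qi, unresolved = character(0))
  } else {
    resolved <- resolve_gene_list(query, db$universe)
  }
  db_used <- filter_database(db, core_only = core_only,
                             open_license_only = open_license_only)
  normalized <- lapply(db_used$networks, normalize_symmetric)
  w <- fit_weights(normalized, resolved$indices, weighting, ridge)
  composite <- combine(normalized, w)
  y <- build_labels(resolved$indices, n)
  scores <- propagate(composite, y, lambda = lambda, tol = tol,
                      max_iter = max_iter)
  related <- rank_related(scores, resolved$indices, n_top = n_related)
  result_set <- c(resolved$indices, related$index)
  edges <- collapse_for_display(composite, result_set)
  edges$gene_a_name <- db$universe$primary_ids[edges$gene_a]
  edges$gene_b_name <- db$universe$primary_ids[edges$gene_b]
  attrs <- score_attributes(db_used$attributes, scores, result_set,
                            n_top = n_attributes)
  enrich <- if (!is.null(annotations)) {
    hypergeom_enrich(result_set, annotations, n)
  }
  structure(
    list(
      query_genes = db$universe$primary_ids[resolved$indices],
      query_indices = resolved$indices,
      unresolved = resolved$unresolved,
      related = data.frame(
        gene = db$universe$primary_ids[related$index],
        index = related$index, score = related$score,
        stringsAsFactors = FALSE
      ),
      attributes = attrs,
      display_edges = edges,
      weights = w,
      scores = scores,
      enrichment = enrich,
      config = list(
        weighting = weighting, lambda = lambda, n_related = n_related,
        n_attributes = n_attributes, core_only = core_only,
        open_license_only = open_license_only, ridge = ridge,
        version = as.character(utils::packageVersion("netprop"))
      )
    ),
    class = "netprop_result"
  )
}

#' @export
print.netprop_result <- function(x, ...) {
  cat(sprintf("Query of %d gene(s): %s\n", length(x$query_genes),
              paste(utils::head(x$query_genes, 8L), collapse = ", ")))
  if (length(x$unresolved)) {
    cat(sprintf("  unresolved: %s\n", paste(x$unresolved, collapse = ", ")))
  }
  cat(sprintf("  weighting: %s; lambda = %g\n",
              x$weights$method, x$scores$lambda))
  cat(sprintf("  %d related gene(s), %d display edge(s), %d attribute(s)\n",
              nrow(x$related), nrow(x$display_edges), nrow(x$attributes)))
  if (nrow(x$related)) {
    top <- utils::head(x$related, 5L)
    cat("  top related:\n")
    for (r in seq_len(nrow(top))) {
      cat(sprintf("    %-12s %.5f\n", top$gene[r], top$score[r]))
    }
  }
  invisible(x)
}

#' @export
summary.netprop_result <- function(object, ...) {
  x <- object
  cat(sprintf("Query genes (%d): %s\n", length(x$query_genes),
              paste(x$query_genes, collapse = ", ")))
  if (length(x$unresolved)) {
    cat(sprintf("Unresolved (%d): %s\n", length(x$unresolved),
                paste(x$unresolved, collapse = ", ")))
  }
  print(x$weights)
  cat(sprintf("Propagation: lambda = %g, %d CG iterations, residual %.2g\n",
              x$scores$lambda, x$scores$iterations, x$scores$residual))
  if (nrow(x$related)) {
    cat("Related genes:\n")
    print(x$related[, c("gene", "score")], row.names = FALSE)
  }
  if (nrow(x$attributes)) {
    cat("Related attributes:\n")
    print(x$attributes, row.names = FALSE)
  }
  if (!is.null(x$enrichment)) {
    cat("Enrichment (top 10):\n")
    print(utils::head(x$enrichment, 10L), row.names = FALSE)
  }
  invisible(x)
}

#' Network weights used by a query
#'
#' The fitted per-network weights are the "coefficients" of a query result:
#' they say how much each source network contributed to the composite.
#'
#' @param object A `netprop_result`.
#' @param ... Ignored.
#' @return Named numeric vector of network weights.
#' @export
coef.netprop_result <- function(object, ...) {
  object$weights$weights
}

#' Plot the score profile of a query result
#'
#' Horizontal barplot of the propagation scores of the related genes
#' (highest on top), a compact text substitute for a network view.
#'
#' @param x A `netprop_result`.
#' @param max_bars Maximum number of genes drawn.
#' @param ... Passed to [graphics::barplot].
#' @export
plot.netprop_result <- function(x, max_bars = 20L, ...) {
  rel <- utils::head(x$related, max_bars)
  if (nrow(rel) == 0L) {
    stop("no related genes to plot")
  }
  graphics::barplot(rev(rel$score), names.arg = rev(rel$gene), horiz = TRUE,
                    las = 1, xlab = "propagation score",
                    main = sprintf("Genes related to %s",
                                   paste(utils::head(x$query_genes, 3L),
                                         collapse = ", ")), ...)
  invisible(x)
}
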