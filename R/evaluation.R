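#' Area under the ROC curve by rank statistic
#'
#' Mann-Whitney formulation with midranks, so tied scores contribute 1/2 and
#' a constant score vector yields 0.5. Invariant under any strictly
#' increasing transform of the scores.
#'
#' @param pos Scores of positive examples.
#' @param neg Scores of negative examples.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(pos, neg) {
  np <- length(pos); nn <- length(neg)
  if (np == 0L || nn == 0L) stop("auroc needs both positive and negative scores")
  r <- rank(c(pos, neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

run_with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' K-fold cross-validated function prediction
#'
#' Benchmarks guilt-by-association recovery of an annotation term. The
#' term's member genes are split into `folds` parts by a seeded shuffle; in
#' each fold the retained members form the query, the network weights are
#' fitted, labels propagated, and the held-out members are scored against
#' all non-member genes. Evaluation is transductive: held-out genes leave
#' the query but stay in the network. AUROC uses midranks (ties count 1/2);
#' precision@k uses k = number of genes held out in the fold.
#'
#' @param db A [network_db].
#' @param term Either an integer vector of member indices or a list with
#'   `name` and `members`.
#' @param folds Number of folds (>= 2, <= number of members).
#' @param weighting One of `"adaptive"`, `"equal"`, `"group"`.
#' @param seed Integer seed fixing the fold assignment.
#' @param lambda Propagation smoothing strength.
#' @param ridge Ridge penalty for adaptive weighting.
#' @return An object of class `cv_report`: per-fold data frame (`fold`,
#'   `n_heldout`, `auroc`, `precision_at_k`), means, standard deviations,
#'   and the seed.
#' @export
kfold_crossval <- function(db, term, folds = 5L,
                           weighting = c("adaptive", "equal", "group"),
                           seed = 1L, lambda = 1, ridge = 1e-3) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(db, "network_db"))
  if (is.list(term)) {
    term_name <- term$name %||% "term"
    members <- unique(as.integer(term$members))
  } else {
    term_name <- "term"
    members <- unique(as.integer(term))
  }
  n <- length(db$universe)
  if (folds < 2L) stop("need at least 2 folds")
  if (length(members) < folds) {
    stop(sprintf("term '%s' has %d members, fewer than %d folds",
                 term_name, length(members), folds))
  }
  assignment <- run_with_seed(seed, {
    shuffled <- sample(members)
    stats::setNames(rep_len(seq_len(folds), length(shuffled)), shuffled)
  })
  negatives <- setdiff(seq_len(n), members)
  normalized <- lapply(db$networks, normalize_symmetric)
  rows <- vector("list", folds)
  for (fold in seq_len(folds)) {
    held <- as.integer(names(assignment)[assignment == fold])
    query <- setdiff(members, held)
    w <- fit_weights(normalized, query, weighting, ridge)
    composite <- combine(normalized, w)
    sc <- propagate(composite, build_labels(query, n), lambda = lambda)
    a <- auroc(sc$f[held], sc$f[negatives])
    k <- length(held)
    top <- rank_related(sc, query, n_top = k)
    prec <- if (k > 0L) sum(top$index %in% held) / k else NA_real_
    rows[[fold]] <- data.frame(fold = fold, n_heldout = k,
                               auroc = a, precision_at_k = prec)
  }
  per_fold <- do.call(rbind, rows)
  structure(
    list(
      term = term_name, folds = folds, seed = seed,
      per_fold = per_fold,
      mean_auroc = mean(per_fold$auroc),
      sd_auroc = stats::sd(per_fold$auroc),
      mean_precision = mean(per_fold$precision_at_k),
      sd_precision = stats::sd(per_fold$precision_at_k)
    ),
    class = "cv_report"
  )
}

# silence-free weighting dispatch shared by CV and the query pipeline; falls
# back to equal weights when the query is too small for the regression
fit_weights <- function(normalized, query, weighting, ridge) {
  switch(weighting,
    equal = weight_equal(normalized),
    group = weight_by_group(normalized),
    adaptive = if (length(query) >= 2L) {
      suppressWarnings(weight_query_adaptive(normalized, query, ridge = ridge))
    } else {
      weight_equal(normalized)
    }
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation of '%s' (seed %d)\n",
              x$folds, x$term, x$seed))
  cat(sprintf("  AUROC        %.4f (sd %.4f)\n", x$mean_auroc, x$sd_auroc))
  cat(sprintf("  precision@k  %.4f (sd %.4f)\n", x$mean_precision, x$sd_precision))
  invisible(x)
}

#' Hypergeometric enrichment of a result gene set
#'
#' For each annotation term, computes the one-sided upper-tail
#' hypergeometric p-value of the overlap between the result genes and the
#' term's members within the universe (the probability of at least the
#' observed overlap when drawing the result set uniformly at random), and
#' Benjamini-Hochberg q-values across the tested terms.
#'
#' @param result_genes Universe indices of the result set (non-empty).
#' @param annotation_sets Named list of integer vectors (term members), or a
#'   list of lists with `name` and `members`.
#' @param universe_size Number of genes in the universe.
#' @return Data frame sorted by p ascending: `term`, `term_size`, `overlap`,
#'   `p`, `q`.
#' @export
hypergeom_enrich <- function(result_genes, annotation_sets, universe_size) {
  result_genes <- unique(as.integer(result_genes))
  if (length(result_genes) == 0L) stop("result gene set is empty")
  terms <- lapply(annotation_sets, function(s) {
    if (is.list(s)) unique(as.integer(s$members)) else unique(as.integer(s))
  })
  nms <- names(annotation_sets)
  if (is.null(nms)) {
    nms <- vapply(annotation_sets, function(s) {
      if (is.list(s) && !is.null(s$name)) s$name else NA_character_
    }, character(1))
  }
  if (anyNA(nms)) stop("annotation sets must be named")
  ndraw <- length(result_genes)
  out <- data.frame(
    term = nms,
    term_size = vapply(terms, length, integer(1)),
    overlap = vapply(terms, function(m) sum(result_genes %in% m), integer(1)),
    stringsAsFactors = FALSE
  )
  out$p <- stats::phyper(out$overlap - 1L, out$term_size,
                         universe_size - out$term_size, ndraw,
                         lower.tail = FALSE)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read annotation sets from a tab-delimited file
#'
#' Accepts either long format (`term<TAB>gene`, one pair per row) or
#' GMT-style rows (`term<TAB>description<TAB>gene1<TAB>gene2...`); rows with
#' three or more columns are treated as GMT. Gene names are resolved against
#' the universe; unresolvable names are dropped, and terms left without
#' members are omitted.
#'
#' @param path Annotation TSV path.
#' @param universe A [gene_universe].
#' @param gmt Force GMT interpretation regardless of column count.
#' @return Named list of integer vectors of member indices.
#' @export
read_annotations <- function(path, universe, gmt = FALSE) {
  stopifnot(inherits(universe, "gene_universe"))
  if (!file.exists(path)) stop(sprintf("annotation file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop(sprintf("annotation file is empty: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- list()
  for (f in fields) {
    if (length(f) < 2L) next
    term <- trimws(f[1L])
    genes <- if (gmt || length(f) >= 3L) trimws(f[-(1:2)]) else trimws(f[2L])
    if (gmt && length(f) == 2L) genes <- character(0)
    idx <- resolve(genes, universe)
    idx <- idx[!is.na(idx)]
    sets[[term]] <- unique(c(sets[[term]], idx))
  }
  sets[lengths(sets) >= 1L]
}
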