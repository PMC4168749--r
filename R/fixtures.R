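#' Specification for a synthetic planted-partition organism
#'
#' Describes a deterministic synthetic test organism: a universe of genes of
#' which the first `n_modules * module_size` are partitioned into functional
#' modules, planted-partition source networks in one or more evidence
#' groups, an expression profile whose module genes share a latent factor,
#' and one annotation set per module. Every stochastic choice flows from one
#' seeded pseudo-random stream, so a spec reproduces its fixture exactly.
#'
#' Within-module gene pairs receive an edge with probability
#' `within_module_edge_prob` and weight Uniform(0.5, 1); all other pairs
#' with probability `background_edge_prob` and weight Uniform(0, 0.3). In
#' the profile, each module has a latent factor per sample; a module gene's
#' expression is `effect_size * factor + Normal(0, noise_sd)`, so module
#' genes are positively correlated while background genes are pure noise.
#'
#' @param n_genes Universe size.
#' @param n_modules Number of planted modules.
#' @param module_size Genes per module (`n_modules * module_size` must not
#'   exceed `n_genes`).
#' @param within_module_edge_prob Edge probability inside modules.
#' @param background_edge_prob Edge probability elsewhere (must be smaller).
#' @param networks_per_group Source networks generated per group.
#' @param groups Character vector of evidence group names.
#' @param n_samples Samples in the expression profile.
#' @param effect_size Module-factor loading in the profile.
#' @param noise_sd Gaussian noise standard deviation in the profile.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 200L, n_modules = 4L, module_size = 25L,
                         within_module_edge_prob = 0.4,
                         background_edge_prob = 0.02,
                         networks_per_group = 1L,
                         groups = c("co-expression", "physical-interaction",
                                    "shared-protein-domains"),
                         n_samples = 20L, effect_size = 1, noise_sd = 0.5,
                         seed = 1L) {
  stopifnot(
    within_module_edge_prob >= 0, within_module_edge_prob <= 1,
    background_edge_prob >= 0, background_edge_prob <= 1,
    networks_per_group >= 1L, length(groups) >= 1L, n_samples >= 2L
  )
  if (within_module_edge_prob <= background_edge_prob) {
    stop("within-module edge probability must exceed the background probability")
  }
  if (n_modules * module_size > n_genes) {
    stop(sprintf("%d modules of %d genes exceed universe size %d",
                 n_modules, module_size, n_genes))
  }
  structure(
    list(
      n_genes = as.integer(n_genes), n_modules = as.integer(n_modules),
      module_size = as.integer(module_size),
      within_module_edge_prob = within_module_edge_prob,
      background_edge_prob = background_edge_prob,
      networks_per_group = as.integer(networks_per_group),
      groups = as.character(groups),
      n_samples = as.integer(n_samples),
      effect_size = effect_size, noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

#' Generate a synthetic organism fixture
#'
#' Materializes a [fixture_spec] into a gene universe (IDs `G0001`... with
#' one synonym each), a [network_db] of planted-partition networks plus a
#' per-module attribute incidence (`DOM1`...), one annotation set per
#' module, and an expression profile. Identical specs produce identical
#' fixtures.
#'
#' @param spec A [fixture_spec].
#' @return A list of class `fixture` with `universe`, `db`, `annotations`
#'   (named list of member-index vectors), `profile`, `modules` (integer
#'   module id per gene, 0 = background), and `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  run_with_seed(spec$seed, {
    n <- spec$n_genes
    ids <- sprintf("G%04d", seq_len(n))
    universe <- gene_universe(ids, lapply(seq_len(n), function(i) {
      sprintf("syn%04d", i)
    }), organism_name = sprintf("synthetic-organism-seed%d", spec$seed))

    modules <- integer(n)
    for (m in seq_len(spec$n_modules)) {
      modules[((m - 1L) * spec$module_size + 1L):(m * spec$module_size)] <- m
    }

    pairs <- utils::combn(n, 2L)
    pi_ <- pairs[1L, ]; pj_ <- pairs[2L, ]
    within <- modules[pi_] > 0L & modules[pi_] == modules[pj_]

    networks <- list()
    for (g in spec$groups) {
      for (r in seq_len(spec$networks_per_group)) {
        u <- stats::runif(length(pi_))
        keep <- ifelse(within, u < spec$within_module_edge_prob,
                       u < spec$background_edge_prob)
        w <- ifelse(within, stats::runif(length(pi_), 0.5, 1),
                    stats::runif(length(pi_), 0, 0.3))
        upper <- Matrix::sparseMatrix(
          i = pi_[keep], j = pj_[keep], x = w[keep], dims = c(n, n)
        )
        meta <- network_meta(
          name = if (spec$networks_per_group > 1L) sprintf("%s-%d", g, r) else g,
          group = g,
          source_description = "planted-partition synthetic network",
          publication = sprintf("synthetic fixture seed %d", spec$seed),
          open_license = TRUE, default_selected = TRUE
        )
        networks[[length(networks) + 1L]] <-
          sparse_network(upper + Matrix::t(upper), meta)
      }
    }

    attr_inc <- Matrix::sparseMatrix(
      i = which(modules > 0L), j = modules[modules > 0L],
      x = 1, dims = c(n, spec$n_modules),
      dimnames = list(NULL, sprintf("DOM%d", seq_len(spec$n_modules)))
    )
    db <- network_db(universe, networks, attributes = attr_inc)

    annotations <- lapply(seq_len(spec$n_modules), function(m) which(modules == m))
    names(annotations) <- sprintf("module_%d", seq_len(spec$n_modules))

    factors <- matrix(stats::rnorm(spec$n_modules * spec$n_samples),
                      spec$n_modules, spec$n_samples)
    vals <- matrix(stats::rnorm(n * spec$n_samples, sd = spec$noise_sd),
                   n, spec$n_samples)
    in_mod <- modules > 0L
    vals[in_mod, ] <- vals[in_mod, ] +
      spec$effect_size * factors[modules[in_mod], , drop = FALSE]
    profile <- structure(
      list(
        gene_indices = seq_len(n),
        values = vals,
        sample_names = sprintf("S%02d", seq_len(spec$n_samples))
      ),
      class = "expression_profile"
    )

    structure(
      list(universe = universe, db = db, annotations = annotations,
           profile = profile, modules = modules, spec = spec),
      class = "fixture"
    )
  })
}

#' Write a fixture to plain-text files
#'
#' Produces the tab-delimited inputs the importers consume: `genome.tsv`
#' (primary ID + synonym), one edge list per network, `profile.tsv`,
#' `annotations.tsv` (long `term<TAB>gene` format) and a `manifest.tsv`
#' listing networks with their groups and flags. Useful for exercising the
#' whole import pipeline and for the command-line `make-fixture` command.
#'
#' @param fixture A [generate_fixture] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture_files <- function(fixture, dir) {
  stopifnot(inherits(fixture, "fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  u <- fixture$universe
  n <- length(u)
  syn <- vapply(seq_len(n), function(i) {
    s <- u$all_names[u$name_index == i]
    paste(s[-1L], collapse = "\t")
  }, character(1))
  writeLines(paste0(u$primary_ids, ifelse(nzchar(syn), "\t", ""), syn),
             file.path(dir, "genome.tsv"))

  manifest <- character(0)
  for (net in fixture$db$networks) {
    e <- upper_edges(net$adjacency)
    fname <- paste0(gsub("[^A-Za-z0-9._-]", "_", net$meta$name), ".txt")
    writeLines(sprintf("%s\t%s\t%.17g",
                       u$primary_ids[e$i], u$primary_ids[e$j], e$x),
               file.path(dir, fname))
    manifest <- c(manifest, paste(fname, net$meta$name, net$meta$group,
                                  as.integer(net$meta$default_selected),
                                  as.integer(net$meta$open_license),
                                  sep = "\t"))
  }
  writeLines(c("#file\tname\tgroup\tdefault_selected\topen_license", manifest),
             file.path(dir, "manifest.tsv"))

  p <- fixture$profile
  rows <- c(
    paste(c("gene", p$sample_names), collapse = "\t"),
    vapply(seq_along(p$gene_indices), function(r) {
      paste(c(u$primary_ids[p$gene_indices[r]],
              sprintf("%.10g", p$values[r, ])), collapse = "\t")
    }, character(1))
  )
  writeLines(rows, file.path(dir, "profile.tsv"))

  ann <- unlist(lapply(names(fixture$annotations), function(term) {
    sprintf("%s\t%s", term, u$primary_ids[fixture$annotations[[term]]])
  }))
  writeLines(ann, file.path(dir, "annotations.tsv"))
  invisible(dir)
}
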