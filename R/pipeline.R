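write_tsv_ <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_ <- function(path) {
  as_tibble(read.table(path, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE, check.names = FALSE))
}

#' Pipeline configuration
#'
#' Validates and assembles the settings [run_pipeline()] needs: either a
#' simulation spec or paths to real inputs, the theme definitions, QC and
#' threshold parameters, an output directory and a master seed.
#'
#' @param themes List of [theme_config()] objects (priority order; the first
#'   theme claims accessions that end up in several collections when a single
#'   DAPC label is needed).
#' @param simulation A [sim_spec()], or `NULL` when real inputs are given.
#' @param genotypes_vcf,phenotypes_tsv,qualitative_tsv Paths to real inputs
#'   (used when `simulation` is `NULL`).
#' @param class_probs Qualitative class distributions for the simulation
#'   (named list trait -> probability vector).
#' @param maf_min,max_missing SNP QC parameters (see [qc_filter()]).
#' @param ibs_threshold Duplicate-calling IBS threshold (default 0.95).
#' @param shannon_bins Quantitative binning class count (default 6).
#' @param dapc_variance PCA variance fraction retained for DAPC (default 0.80).
#' @param backfill Re-truncate from the ranked list to restore `n_target`
#'   after duplicate pruning (default `FALSE`; the source procedure does not
#'   backfill).
#' @param out_dir Output directory (`NULL` for in-memory only).
#' @param seed Master seed; stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(themes,
                            simulation = NULL,
                            genotypes_vcf = NULL,
                            phenotypes_tsv = NULL,
                            qualitative_tsv = NULL,
                            class_probs = NULL,
                            maf_min = 0.05,
                            max_missing = 0.20,
                            ibs_threshold = 0.95,
                            shannon_bins = 6,
                            dapc_variance = 0.80,
                            backfill = FALSE,
                            out_dir = NULL,
                            seed = 1L) {
  if (is.null(simulation) && is.null(genotypes_vcf) && is.null(phenotypes_tsv)) {
    abort("Provide either a simulation spec or real input paths.")
  }
  stopifnot(length(themes) >= 1, all(vapply(themes, inherits, logical(1), "theme")))
  structure(
    list(
      themes = themes, simulation = simulation,
      genotypes_vcf = genotypes_vcf, phenotypes_tsv = phenotypes_tsv,
      qualitative_tsv = qualitative_tsv, class_probs = class_probs,
      maf_min = maf_min, max_missing = max_missing,
      ibs_threshold = ibs_threshold, shannon_bins = shannon_bins,
      dapc_variance = dapc_variance, backfill = backfill,
      out_dir = out_dir, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Selection bookkeeping summary
#'
#' The conservation identity of the selection stage: per collection,
#' initial size minus duplicate removals equals the final size, and final
#' sizes are expressed as rounded percentage shares of the phenotyped
#' universe.
#'
#' @param initial Named integer vector of pre-dedup collection sizes.
#' @param removed Named integer vector (or scalar total) of accessions removed
#'   per collection by duplicate pruning.
#' @param final Named integer vector of post-dedup sizes; defaults to
#'   `initial - removed`.
#' @param universe Size of the phenotyped accession universe (for shares), or
#'   `NULL`.
#' @param genotyped Optional named integer vector of genotyped members per
#'   collection.
#' @return Tibble with one row per collection plus a `total` row; columns
#'   `collection`, `initial`, `removed`, `final`, and when available
#'   `share_pct` (final / universe * 100, rounded to 1 decimal) and
#'   `genotyped`.
#' @export
collection_bookkeeping <- function(initial, removed, final = NULL,
                                   universe = NULL, genotyped = NULL) {
  if (length(removed) == 1 && is.null(names(removed)) && is.null(final)) {
    abort("With a scalar `removed`, per-collection `final` sizes are required.")
  }
  if (is.null(final)) final <- initial - removed
  if (length(removed) == 1 && length(initial) > 1) {
    removed_per <- initial - final
    if (sum(removed_per) != removed) {
      abort("Totals disagree: sum(initial - final) != removed.")
    }
    removed <- removed_per
  }
  stopifnot(all(final == initial - removed))
  out <- tibble(
    collection = c(names(initial) %||% paste0("CC", seq_along(initial)), "total"),
    initial = unname(c(initial, sum(initial))),
    removed = unname(c(removed, sum(removed))),
    final = unname(c(final, sum(final)))
  )
  if (!is.null(universe)) {
    out$share_pct <- round(100 * out$final / universe, 1)
  }
  if (!is.null(genotyped)) {
    out$genotyped <- unname(c(genotyped, sum(genotyped)))
  }
  out
}

build_collection <- function(theme, blup_tidy, trait_table, km_full, genotyped,
                             ibs_threshold, backfill) {
  ranked <- rank_candidates(blup_tidy, theme)
  eligible <- apply_eligibility(ranked, theme$filters, trait_table)
  coll <- truncate_collection(eligible, theme$n_target, name = theme$name)
  dedup_pass <- function(coll) {
    ids <- intersect(coll$accession, genotyped)
    if (length(ids) < 2) return(coll)
    sub <- km_full$ibs[ids, ids, drop = FALSE]
    km <- structure(
      list(ibs = sub, n_loci = km_full$n_loci[ids, ids, drop = FALSE]),
      class = "ibs_matrix"
    )
    pairs <- find_duplicate_pairs(km, ibs_threshold)
    prune_duplicates(coll, pairs)
  }
  pruned <- dedup_pass(coll)
  if (backfill) {
    # refill from the ranked list, re-checking new members for duplicates
    repeat {
      shortfall <- theme$n_target - nrow(pruned)
      used <- c(pruned$accession, attr(pruned, "removed")$accession)
      pool <- eligible |> filter(!(.data$accession %in% used))
      if (shortfall <= 0 || !nrow(pool)) break
      extra <- head(pool, shortfall) |>
        mutate(collection = theme$name, status = "kept") |>
        select("collection", "accession", "composite_score", "rank", "status")
      refilled <- bind_rows(as_tibble(pruned), extra) |>
        arrange(.data$composite_score, .data$accession)
      coll2 <- structure(
        refilled,
        provenance = "post-dedup", removed = attr(pruned, "removed"),
        class = class(pruned)
      )
      pruned <- dedup_pass(coll2)
      if (nrow(pruned) == nrow(coll2)) break
    }
  }
  list(initial = coll, final = pruned, excluded = attr(ranked, "excluded"),
       ineligible = attr(eligible, "removed"))
}

#' Run the full thematic core-collection pipeline
#'
#' Executes every stage end to end: input loading or simulation, SNP QC,
#' data-mode aggregation of qualitative scores, per-trait EM-REML/BLUP,
#' per-theme ranking + eligibility + truncation, IBS duplicate pruning,
#' the diversity report (Shannon-Weaver, Ho/Hs/Fis, allele retention, Kappa),
#' and PCA/DAPC validation. When `config$out_dir` is set, all artifacts are
#' written as TSV/JSON alongside a JSON manifest recording the configuration,
#' seeds, versions, input hashes and per-stage counts.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `genotypes`, `records`, `fit`, `collections`
#'   (per theme: `initial`, `final`), `bookkeeping`, `diversity`,
#'   `pca_molecular`, `pca_phenotypic`, `dapc`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  # --- stage: inputs -------------------------------------------------------
  hashes <- list()
  if (!is.null(config$simulation)) {
    spec <- config$simulation
    spec$seed <- config$seed
    gm <- simulate_genotypes(spec)
    trials <- simulate_trials(gm, spec)
    records <- trials$records
    qual <- NULL
    if (!is.null(config$class_probs)) {
      qual <- simulate_qualitative(spec, config$class_probs)$scores
    }
    hashes$simulation_seed <- spec$seed
  } else {
    gm <- if (!is.null(config$genotypes_vcf)) read_genotypes_vcf(config$genotypes_vcf)
    records <- read_tsv_(config$phenotypes_tsv)
    qual <- if (!is.null(config$qualitative_tsv)) read_tsv_(config$qualitative_tsv)
    for (p in c(config$genotypes_vcf, config$phenotypes_tsv, config$qualitative_tsv)) {
      hashes[[basename(p)]] <- unname(tools::md5sum(p))
    }
  }

  # --- stage: QC + mode aggregation ---------------------------------------
  if (!is.null(gm)) gm <- qc_filter(gm, config$maf_min, config$max_missing)
  modal <- if (!is.null(qual)) aggregate_mode(qual)

  # --- stage: REML/BLUP ----------------------------------------------------
  quant_traits <- intersect(
    unique(unlist(map(config$themes, ~names(.x$directions)))),
    unique(records$trait)
  )
  if (!length(quant_traits)) abort("No theme trait has trial records.")
  fit <- fit_blup(records, traits = quant_traits)
  blup_tidy <- tidy(fit)

  # predicted values on the trait scale (for eligibility and diversity)
  quant_table <- blup_tidy |>
    mutate(value = .data$g_hat + unname(fit$mu[.data$trait])) |>
    select("accession", "trait", "value")
  # eligibility table: quantitative predictions plus modal qualitative classes
  trait_table <- quant_table |> mutate(value = as.character(.data$value))
  if (!is.null(modal)) {
    trait_table <- bind_rows(
      trait_table,
      modal |> mutate(class = as.character(.data$class)) |> rename(value = "class")
    )
  }

  # --- stage: selection + dedup -------------------------------------------
  genotyped <- if (!is.null(gm)) accessions(gm) else character()
  km_full <- if (!is.null(gm)) ibs_matrix(gm)
  collections <- map(config$themes, build_collection,
    blup_tidy = blup_tidy, trait_table = trait_table, km_full = km_full,
    genotyped = genotyped, ibs_threshold = config$ibs_threshold,
    backfill = config$backfill
  )
  names(collections) <- map_chr(config$themes, "name")

  initial_sizes <- map_dbl(collections, ~nrow(.x$initial))
  final_sizes <- map_dbl(collections, ~nrow(.x$final))
  removed_sizes <- initial_sizes - final_sizes
  genotyped_sizes <- map_dbl(collections, ~length(intersect(.x$final$accession, genotyped)))
  bookkeeping <- collection_bookkeeping(
    initial = initial_sizes, removed = removed_sizes,
    universe = length(unique(records$accession)),
    genotyped = genotyped_sizes
  )

  # --- stage: diversity ----------------------------------------------------
  members <- map(collections, ~.x$final$accession)
  diversity <- diversity_report(
    gm, members,
    quantitative = quant_table,
    qualitative = modal,
    shannon_bins = config$shannon_bins,
    kappa_universe = unique(records$accession)
  )

  # --- stage: ordination validation ---------------------------------------
  pca_mol <- pca_pheno <- dapc <- NULL
  blup_wide <- blup_tidy |>
    tidyr::pivot_wider(names_from = "trait", values_from = "g_hat")
  pheno_mat <- as.matrix(blup_wide[, -1, drop = FALSE])
  rownames(pheno_mat) <- blup_wide$accession
  pheno_mat <- pheno_mat[complete.cases(pheno_mat), , drop = FALSE]
  if (nrow(pheno_mat) >= 2 && ncol(pheno_mat) >= 2) {
    pca_pheno <- pca_ordination(pheno_mat, scale = TRUE)
  }
  if (!is.null(gm)) {
    pca_mol <- pca_ordination(impute_mean(gm)$dosages)
  }
  # single label per accession, themes in priority order
  label <- list()
  for (cn in rev(names(members))) for (a in members[[cn]]) label[[a]] <- cn
  dapc_ids <- intersect(names(label), rownames(pheno_mat))
  grp <- factor(unlist(label[dapc_ids]))
  if (length(dapc_ids) >= 6 && nlevels(grp) >= 2 && all(table(grp) >= 2)) {
    dapc <- dapc_fit(pheno_mat[dapc_ids, , drop = FALSE], grp,
                     variance_fraction = config$dapc_variance)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("coretheme")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    input_hashes = hashes,
    parameters = list(
      maf_min = config$maf_min, max_missing = config$max_missing,
      ibs_threshold = config$ibs_threshold,
      shannon_bins = config$shannon_bins,
      dapc_variance = config$dapc_variance, backfill = config$backfill
    ),
    themes = map(config$themes, function(th) list(
      name = th$name, traits = names(th$directions),
      directions = unname(th$directions), n_target = th$n_target,
      n_filters = length(th$filters)
    )),
    counts = as.data.frame(bookkeeping)
  )

  result <- list(
    genotypes = gm, records = records, modal = modal, fit = fit,
    collections = collections, bookkeeping = bookkeeping,
    diversity = diversity, pca_molecular = pca_mol,
    pca_phenotypic = pca_pheno, dapc = dapc, manifest = manifest
  )
  if (!is.null(config$out_dir)) write_pipeline_artifacts(result, config)
  invisible(result)
}

write_pipeline_artifacts <- function(result, config) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_tsv_(tidy(result$fit), file.path(out, "blups.tsv"))
  write_tsv_(glance(result$fit), file.path(out, "variance_components.tsv"))
  membership <- bind_rows(map(result$collections, function(cc) {
    bind_rows(
      as_tibble(cc$final),
      attr(cc$final, "removed") |>
        mutate(
          collection = cc$final$collection[1] %||% NA_character_,
          status = "removed_duplicate",
          composite_score = NA_real_, rank = NA_integer_
        ) |>
        select("collection", "accession", "composite_score", "rank", "status")
    )
  }))
  write_tsv_(membership, file.path(out, "membership.tsv"))
  write_tsv_(result$diversity$shannon, file.path(out, "shannon.tsv"))
  if (!is.null(result$diversity$molecular)) {
    write_tsv_(result$diversity$molecular, file.path(out, "molecular_diversity.tsv"))
  }
  kap <- as.data.frame(result$diversity$kappa)
  kap <- cbind(collection = rownames(kap), kap)
  write_tsv_(kap, file.path(out, "kappa.tsv"))
  if (!is.null(result$dapc)) {
    write_tsv_(tidy(result$dapc), file.path(out, "dapc_assignment.tsv"))
  }
  jsonlite::write_json(
    result$manifest, file.path(out, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out)
}
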