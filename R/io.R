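#' Read a biallelic SNP VCF into a genotype matrix
#'
#' Parses GT fields into alt-allele dosages (0/0 -> 0, 0/1 -> 1, 1/1 -> 2,
#' `./.` -> missing). Only biallelic SNP records are accepted; multiallelic
#' records abort with the offending locus named.
#'
#' @param path Path to an (uncompressed or gzipped) VCF file.
#' @return A [geno_matrix()].
#' @export
read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  check_vcf_structure(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    abort(paste0(
      "Multiallelic records not supported: ",
      paste(head(paste0(fix$CHROM[multi], ":", fix$POS[multi]), 5), collapse = ", ")
    ))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  if (anyDuplicated(samples)) abort("Duplicated sample identifiers in VCF.")
  core <- gsub("\\|", "/", gt)
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  dos <- t(matrix(map[core], nrow = nrow(gt), ncol = ncol(gt)))
  bad <- !is.na(core) & core != "./." & !(core %in% names(map))
  if (any(bad)) {
    abort(paste0("Unrecognised GT value(s): ", paste(unique(core[bad])[1:3], collapse = ", ")))
  }
  rownames(dos) <- samples
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_", fix$POS)[is.na(ids) | ids == "."]
  loci <- tibble(
    locus = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT
  )
  colnames(dos) <- loci$locus
  geno_matrix(dos, loci)
}

# Light structural scan so malformed files fail with a line number instead of
# an opaque parser error.
check_vcf_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1], "##fileformat=VCF")) {
    abort("Malformed VCF: missing ##fileformat header (line 1).")
  }
  hdr <- which(startsWith(lines, "#CHROM"))
  if (!length(hdr)) abort("Malformed VCF: missing #CHROM header line.")
  n_fields <- length(strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]])
  body <- seq(hdr[1] + 1, length(lines))
  if (hdr[1] == length(lines)) return(invisible(TRUE))
  for (i in body) {
    if (!nzchar(lines[i])) next
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf != n_fields) {
      abort(paste0("Malformed VCF at line ", i, ": expected ", n_fields,
                   " fields, found ", nf, "."))
    }
  }
  invisible(TRUE)
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Emits a minimal VCFv4.2 file with GT-only genotype columns; inverse of
#' [read_genotypes_vcf()] for raw (non-imputed) matrices.
#'
#' @param gm A [geno_matrix()] with raw integer dosages.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (gm$imputed) abort("Refusing to write an imputed (real-valued) matrix as VCF.")
  gt_code <- c("0" = "0/0", "1" = "0/1", "2" = "1/1")
  dos <- gm$dosages
  gt <- matrix(gt_code[as.character(dos)], nrow(dos), ncol(dos))
  gt[is.na(dos)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=coretheme",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dos)), collapse = "\t")
  )
  body <- paste(
    gm$loci$chrom, gm$loci$pos, gm$loci$locus, gm$loci$ref, gm$loci$alt,
    ".", ".", ".", "GT",
    apply(gt, 2, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' SNP quality-control filter
#'
#' Drops loci whose minor-allele frequency (computed on non-missing calls)
#' falls below `maf_min`, or whose missing fraction exceeds `max_missing`.
#'
#' @param gm A [geno_matrix()].
#' @param maf_min Minimum minor-allele frequency, in `[0, 0.5)`.
#' @param max_missing Maximum tolerated missing-call fraction, in `[0, 1]`.
#' @return The filtered `geno_matrix`, with attribute `qc_log`: a tibble of
#'   loci kept/dropped counts per rule.
#' @export
qc_filter <- function(gm, maf_min = 0.05, max_missing = 0.20) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (maf_min < 0 || maf_min >= 0.5) abort("`maf_min` must lie in [0, 0.5).")
  if (max_missing < 0 || max_missing > 1) abort("`max_missing` must lie in [0, 1].")
  dos <- gm$dosages
  n_miss <- colSums(is.na(dos))
  n_called <- nrow(dos) - n_miss
  p_alt <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  maf[n_called == 0] <- 0
  miss_frac <- n_miss / nrow(dos)
  fail_maf <- maf < maf_min
  fail_miss <- miss_frac > max_missing
  keep <- !fail_maf & !fail_miss
  if (!any(keep)) warn("QC removed every locus.")
  out <- geno_matrix(dos[, keep, drop = FALSE],
                     gm$loci[keep, , drop = FALSE], imputed = gm$imputed)
  attr(out, "qc_log") <- tibble(
    rule = c("maf", "missing", "kept"),
    n = c(sum(fail_maf), sum(fail_miss & !fail_maf), sum(keep))
  )
  out
}

#' Mean-dosage imputation of missing calls
#'
#' Replaces each missing call with its locus mean dosage (a real value).
#' The result is flagged `imputed` and is accepted by ordination but refused
#' by the diversity statistics, which must not see fabricated heterozygotes.
#'
#' @param gm A [geno_matrix()] with at least one non-missing call per locus.
#' @return An imputed `geno_matrix`.
#' @export
impute_mean <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  dos <- gm$dosages
  all_missing <- colSums(!is.na(dos)) == 0
  if (any(all_missing)) {
    abort(paste0(
      "Cannot impute all-missing locus: ",
      paste(head(colnames(dos)[all_missing], 5), collapse = ", ")
    ))
  }
  if (anyNA(dos)) {
    mode(dos) <- "double"
    mu <- colMeans(dos, na.rm = TRUE)
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- mu[idx[, 2]]
  }
  geno_matrix(dos, gm$loci, imputed = TRUE)
}

#' Aggregate repeated qualitative scores to their mode
#'
#' Collapses yearly ordinal/categorical observations to one modal class per
#' accession and trait. Ties are broken by the most recent year among the tied
#' classes, then by the lowest class code.
#'
#' @param qual_scores Tibble with columns `accession`, `year`, `trait`,
#'   `class`.
#' @return Tibble with one row per (accession, trait): `accession`, `trait`,
#'   `class`.
#' @export
aggregate_mode <- function(qual_scores) {
  stopifnot(all(c("accession", "year", "trait", "class") %in% names(qual_scores)))
  qual_scores |>
    group_by(.data$accession, .data$trait, .data$class) |>
    summarise(n_obs = n(), last_year = max(.data$year), .groups = "drop_last") |>
    arrange(
      dplyr::desc(.data$n_obs), dplyr::desc(.data$last_year), .data$class,
      .by_group = TRUE
    ) |>
    summarise(class = first(.data$class), .groups = "drop") |>
    arrange(.data$accession, .data$trait)
}

#' Theme configuration
#'
#' Describes one thematic collection: which traits drive the ranking and in
#' which direction, hard eligibility filters, and the target size.
#'
#' @param name Collection name.
#' @param directions Named character vector mapping trait to `"higher"` or
#'   `"lower"` (which BLUP tail is favourable). Optional named `weights`
#'   (default equal) weight the per-trait ranks.
#' @param n_target Number of accessions to retain at truncation.
#' @param filters List of hard filters; each is
#'   `list(trait =, op =, value =)` with `op` one of `"<", "<=", ">", ">=",
#'   "in"` (`"in"` takes a vector of allowed classes).
#' @param weights Optional named numeric vector of per-trait rank weights.
#' @return A `theme` list.
#' @export
theme_config <- function(name, directions, n_target,
                         filters = list(), weights = NULL) {
  if (!length(directions) || is.null(names(directions))) {
    abort("`directions` must be a named trait -> direction vector.")
  }
  if (!all(directions %in% c("higher", "lower"))) {
    abort("Directions must be 'higher' or 'lower'.")
  }
  if (n_target < 1) abort("`n_target` must be >= 1.")
  ops <- c("<", "<=", ">", ">=", "in")
  for (f in filters) {
    if (!all(c("trait", "op", "value") %in% names(f)) || !(f$op %in% ops)) {
      abort("Each filter needs trait/op/value with op in <, <=, >, >=, in.")
    }
  }
  if (is.null(weights)) {
    weights <- setNames(rep(1, length(directions)), names(directions))
  }
  structure(
    list(name = name, directions = directions, weights = weights,
         n_target = as.integer(n_target), filters = filters),
    class = "theme"
  )
}

#' Read themes and pipeline settings from a YAML/JSON config file
#'
#' The file holds a `themes` list (each with `name`, `directions`, `n_target`,
#' optional `filters` and `weights`) plus optional globals `ibs_threshold`
#' (default 0.95), `shannon_bins` (default 6) and `dapc_variance` (default
#' 0.80).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with `themes` (list of [theme_config()] objects) and the
#'   global settings.
#' @export
read_theme_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config not found: ", path))
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$themes)) abort("Config must contain a `themes` list.")
  known <- c("themes", "ibs_threshold", "shannon_bins", "dapc_variance")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    abort(paste0("Unknown config key(s): ", paste(extra, collapse = ", ")))
  }
  themes <- map(raw$themes, function(th) {
    filters <- map(th$filters %||% list(), function(f) {
      list(trait = f$trait, op = f$op, value = unlist(f$value))
    })
    theme_config(
      name = th$name,
      directions = unlist(th$directions),
      n_target = th$n_target,
      filters = filters,
      weights = if (!is.null(th$weights)) unlist(th$weights)
    )
  })
  list(
    themes = themes,
    ibs_threshold = raw$ibs_threshold %||% 0.95,
    shannon_bins = raw$shannon_bins %||% 6L,
    dapc_variance = raw$dapc_variance %||% 0.80
  )
}
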