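#' Class-binning scheme for a quantitative trait
#'
#' Builds the six-class (by default) binning used by the Shannon-Weaver index
#' for quantitative traits: the entire collection's range `[min, max]` is cut
#' into `k` equal-width classes; class j covers
#' `(min + (j-1) * Amp / k, min + j * Amp / k]`, with class 1 additionally
#' closed at `min`. The scheme must always be built on the ENTIRE collection's
#' values, even when a sub-collection is subsequently binned against it.
#'
#' @param entire_values Numeric trait values of the entire collection.
#' @param k Number of classes (default 6).
#' @param trait Optional trait name carried in the result.
#' @return A `binning_scheme`: list with `trait`, `k`, `min`, `max`, `breaks`,
#'   and `monomorphic` (`TRUE` when the range is zero).
#' @export
binning_scheme <- function(entire_values, k = 6, trait = NULL) {
  v <- entire_values[is.finite(entire_values)]
  if (!length(v)) abort("No finite values to build a binning scheme from.")
  lo <- min(v)
  hi <- max(v)
  structure(
    list(
      trait = trait, k = as.integer(k), min = lo, max = hi,
      breaks = lo + (hi - lo) * seq(0, 1, length.out = k + 1),
      monomorphic = hi == lo
    ),
    class = "binning_scheme"
  )
}

#' Assign quantitative values to phenotype classes
#'
#' @param values Numeric vector; must lie within the scheme's `[min, max]`
#'   (always true for subsets of the collection the scheme was built on).
#' @param scheme A [binning_scheme()].
#' @return Integer class labels in `1..k`.
#' @export
bin_quantitative <- function(values, scheme) {
  stopifnot(inherits(scheme, "binning_scheme"))
  v <- values[!is.na(values)]
  if (any(v < scheme$min | v > scheme$max)) {
    abort("Values outside the entire-collection range cannot be binned.")
  }
  if (scheme$monomorphic) {
    out <- rep(1L, length(values))
    out[is.na(values)] <- NA_integer_
    return(out)
  }
  as.integer(cut(values, breaks = scheme$breaks, include.lowest = TRUE, right = TRUE))
}

#' Normalized Shannon-Weaver diversity index
#'
#' H' = -sum p_i ln(p_i) over the observed class frequencies, normalized by
#' its maximum ln(k) so the index runs from 0 (monomorphic) to 1 (uniform over
#' all defined classes). `k` is the number of DEFINED classes — 6 for binned
#' quantitative traits, the descriptor's class count for qualitative traits —
#' so a sub-collection missing classes is penalized.
#'
#' @param class_labels Vector of class labels (`NA` dropped).
#' @param k_classes Number of defined classes (>= 1).
#' @return Normalized H' in `[0, 1]`; `NA` for zero observations.
#' @export
shannon_weaver <- function(class_labels, k_classes) {
  stopifnot(k_classes >= 1)
  x <- class_labels[!is.na(class_labels)]
  if (!length(x)) return(NA_real_)
  p <- as.vector(table(x)) / length(x)
  h <- -sum(p * log(p))
  if (k_classes == 1) return(0)
  h / log(k_classes)
}

#' Per-locus Ho, Hs and Fis
#'
#' Single-population gene-diversity statistics on raw SNP calls. Per locus
#' with n-tilde non-missing individuals: Ho is the observed heterozygote
#' fraction; Hs is Nei's within-population gene diversity with the
#' Nei-Chesser small-sample correction,
#' `Hs = (n/(n-1)) * (1 - sum p_i^2 - Ho/(2n))` over sample allele
#' frequencies p_i; Fis = 1 - Ho/Hs wherever Hs > 0. Loci with fewer than two
#' called individuals are excluded from Hs/Fis. Means are reported over loci
#' with defined values; `mean_fis_ratio = 1 - mean(Ho)/mean(Hs)` is also
#' reported since both conventions appear in practice.
#'
#' @param gm A raw [geno_matrix()].
#' @param subset Optional accession ids to restrict to.
#' @return List with `per_locus` (tibble: `locus`, `n`, `ho`, `hs`, `fis`) and
#'   `summary` (tibble: `mean_ho`, `mean_hs`, `mean_fis`, `mean_fis_ratio`,
#'   `n_loci`).
#' @export
molecular_diversity <- function(gm, subset = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (gm$imputed) abort("Diversity statistics require raw (non-imputed) calls.")
  if (!is.null(subset)) gm <- subset_accessions(gm, subset)
  dos <- gm$dosages
  n_called <- colSums(!is.na(dos))
  ho <- colMeans(dos == 1, na.rm = TRUE)
  p <- colMeans(dos, na.rm = TRUE) / 2
  hs <- rep(NA_real_, ncol(dos))
  ok <- n_called >= 2
  nn <- n_called[ok]
  hs[ok] <- (nn / (nn - 1)) * (1 - p[ok]^2 - (1 - p[ok])^2 - ho[ok] / (2 * nn))
  hs[ok] <- pmax(hs[ok], 0) # guard tiny negative from finite-sample correction
  fis <- ifelse(!is.na(hs) & hs > 0, 1 - ho / hs, NA_real_)
  ho[n_called == 0] <- NA_real_
  per_locus <- tibble(
    locus = colnames(dos), n = unname(n_called),
    ho = unname(ho), hs = unname(hs), fis = unname(fis)
  )
  summary <- tibble(
    mean_ho = mean(ho, na.rm = TRUE),
    mean_hs = mean(hs, na.rm = TRUE),
    mean_fis = mean(fis, na.rm = TRUE),
    mean_fis_ratio = 1 - mean(ho, na.rm = TRUE) / mean(hs, na.rm = TRUE),
    n_loci = sum(!is.na(hs))
  )
  list(per_locus = per_locus, summary = summary)
}

#' Allele counts and retention of a sub-collection
#'
#' Counts the distinct alleles observed across loci (the alt allele counts if
#' any dosage > 0 among non-missing calls, the ref allele if any dosage < 2)
#' in the subset and in the reference set, and reports the percentage
#' retained.
#'
#' @param gm A raw [geno_matrix()].
#' @param subset Accession ids of the sub-collection.
#' @param reference Accession ids of the reference (default: all accessions);
#'   `subset` must be contained in it.
#' @return Tibble (`n_alleles_subset`, `n_alleles_reference`, `retention_pct`).
#' @export
allele_retention <- function(gm, subset, reference = accessions(gm)) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (!all(subset %in% reference)) abort("`subset` must be contained in `reference`.")
  count_alleles <- function(ids) {
    d <- gm$dosages[ids, , drop = FALSE]
    alt_seen <- colSums(d > 0, na.rm = TRUE) > 0
    ref_seen <- colSums(d < 2, na.rm = TRUE) > 0
    sum(alt_seen) + sum(ref_seen)
  }
  n_sub <- count_alleles(subset)
  n_ref <- count_alleles(reference)
  tibble(
    n_alleles_subset = n_sub,
    n_alleles_reference = n_ref,
    retention_pct = retention_percent(n_sub, n_ref)
  )
}

#' Retention percentage from allele counts
#'
#' @param n_subset,n_reference Allele counts of the sub-collection and the
#'   reference collection.
#' @return `100 * n_subset / n_reference`, rounded to 2 decimals.
#' @export
retention_percent <- function(n_subset, n_reference) {
  stopifnot(n_reference > 0)
  round(100 * n_subset / n_reference, 2)
}

#' Cohen's Kappa coincidence between collections
#'
#' Each collection is a binary selected/unselected vector over a common
#' accession universe; pairwise agreement beyond chance is
#' Kappa = (p_o - p_e) / (1 - p_e) from the 2x2 table. Degenerate vectors
#' (all selected or all unselected) yield `NA` for their pairs.
#'
#' @param membership Named list of accession-id vectors (one per collection),
#'   or a logical matrix/data frame with the universe in rows and collections
#'   in columns.
#' @param universe Accession ids forming the comparison universe; defaults to
#'   the union of the membership vectors (for a list input).
#' @return Symmetric Kappa matrix with unit diagonal.
#' @export
kappa_coincidence <- function(membership, universe = NULL) {
  if (is.list(membership) && !is.data.frame(membership)) {
    universe <- universe %||% sort(unique(unlist(membership)))
    m <- vapply(membership, function(ids) universe %in% ids, logical(length(universe)))
  } else {
    m <- as.matrix(membership) > 0
    if (!is.null(universe)) m <- m[universe, , drop = FALSE]
  }
  k <- ncol(m)
  n <- nrow(m)
  out <- diag(1, k)
  dimnames(out) <- list(colnames(m), colnames(m))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      x <- m[, i]
      y <- m[, j]
      if (all(x) || !any(x) || all(y) || !any(y)) {
        out[i, j] <- out[j, i] <- NA_real_
        next
      }
      po <- mean(x == y)
      pe <- mean(x) * mean(y) + mean(!x) * mean(!y)
      out[i, j] <- out[j, i] <- (po - pe) / (1 - pe)
    }
  }
  out
}

#' Phenotypic and molecular diversity report for thematic collections
#'
#' Convenience wrapper building the full comparison of collections against
#' the entire set: per-trait normalized Shannon-Weaver indices (quantitative
#' traits binned on the entire collection's range, qualitative traits on their
#' class sets), per-collection molecular summaries (mean Ho/Hs/Fis, allele
#' counts and retention), and the pairwise Kappa matrix.
#'
#' @param gm A raw [geno_matrix()] (or `NULL` to skip molecular statistics).
#' @param collections Named list of accession-id vectors (the collections).
#' @param quantitative Optional tibble (`accession`, `trait`, `value`) of
#'   quantitative trait values (typically BLUPs) over the entire collection.
#' @param qualitative Optional tibble (`accession`, `trait`, `class`) of modal
#'   qualitative classes over the entire collection.
#' @param shannon_bins Class count for quantitative binning (default 6).
#' @param kappa_universe Universe for the Kappa comparison (default: all
#'   accessions present in the phenotype tables, else the genotype matrix).
#' @return A `diversity_report`: list with `shannon` (tibble: `collection`,
#'   `trait`, `kind`, `h_prime`), `molecular` (tibble per collection),
#'   `kappa` (matrix).
#' @export
diversity_report <- function(gm, collections, quantitative = NULL,
                             qualitative = NULL, shannon_bins = 6,
                             kappa_universe = NULL) {
  stopifnot(is.list(collections), !is.null(names(collections)))
  all_sets <- c(list(entire = NULL), collections)

  shannon <- list()
  if (!is.null(quantitative)) {
    for (tr in unique(quantitative$trait)) {
      tt <- quantitative[quantitative$trait == tr, ]
      scheme <- binning_scheme(tt$value, k = shannon_bins, trait = tr)
      for (cn in names(all_sets)) {
        ids <- all_sets[[cn]] %||% tt$accession
        vals <- tt$value[tt$accession %in% ids]
        shannon[[length(shannon) + 1L]] <- tibble(
          collection = cn, trait = tr, kind = "quantitative",
          h_prime = shannon_weaver(bin_quantitative(vals, scheme), shannon_bins)
        )
      }
    }
  }
  if (!is.null(qualitative)) {
    for (tr in unique(qualitative$trait)) {
      tt <- qualitative[qualitative$trait == tr, ]
      k <- length(unique(tt$class))
      for (cn in names(all_sets)) {
        ids <- all_sets[[cn]] %||% tt$accession
        cls <- tt$class[tt$accession %in% ids]
        shannon[[length(shannon) + 1L]] <- tibble(
          collection = cn, trait = tr, kind = "qualitative",
          h_prime = shannon_weaver(cls, k)
        )
      }
    }
  }

  molecular <- NULL
  if (!is.null(gm)) {
    genotyped <- accessions(gm)
    molecular <- bind_rows(imap(all_sets, function(ids, cn) {
      ids <- intersect(ids %||% genotyped, genotyped)
      if (length(ids) < 2) {
        return(tibble(collection = cn, n_genotyped = length(ids)))
      }
      md <- molecular_diversity(gm, ids)$summary
      ret <- allele_retention(gm, ids, genotyped)
      bind_cols(tibble(collection = cn, n_genotyped = length(ids)), md, ret)
    }))
  }

  kap <- kappa_coincidence(collections, universe = kappa_universe)

  structure(
    list(shannon = bind_rows(shannon), molecular = molecular, kappa = kap),
    class = "diversity_report"
  )
}

#' @export
print.diversity_report <- function(x, ...) {
  cat("<diversity_report>\n")
  if (nrow(x$shannon)) {
    cat("Shannon-Weaver (normalized), mean by collection:\n")
    print(
      x$shannon |>
        group_by(.data$collection) |>
        summarise(mean_h = mean(.data$h_prime, na.rm = TRUE), .groups = "drop")
    )
  }
  if (!is.null(x$molecular)) {
    cat("Molecular summaries:\n")
    print(x$molecular)
  }
  cat("Kappa matrix:\n")
  print(round(x$kappa, 3))
  invisible(x)
}
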