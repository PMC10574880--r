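#' Identity-by-state kinship matrix
#'
#' Pairwise IBS similarity on alt-allele dosages: for accessions a and b,
#' IBS(a, b) = mean over loci non-missing in both of (1 - |d_a - d_b| / 2).
#' This is the average proportion of alleles shared. Computed with indicator-
#' matrix cross-products, so large panels do not require a per-pair loop.
#'
#' @param gm A raw (non-imputed) [geno_matrix()].
#' @param subset Optional accession ids to restrict to.
#' @return An object of class `ibs_matrix`: list with `ibs` (symmetric matrix,
#'   unit diagonal, `NA` where a pair shares no called locus) and `n_loci`
#'   (matrix of per-pair compared-locus counts).
#' @export
ibs_matrix <- function(gm, subset = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (gm$imputed) abort("IBS requires raw (non-imputed) dosages.")
  if (!is.null(subset)) gm <- subset_accessions(gm, subset)
  dos <- gm$dosages
  if (!nrow(dos)) abort("Empty accession subset.")
  I0 <- (!is.na(dos) & dos == 0) * 1
  I1 <- (!is.na(dos) & dos == 1) * 1
  I2 <- (!is.na(dos) & dos == 2) * 1
  M <- (!is.na(dos)) * 1
  n_loci <- M %*% t(M)
  # sum over loci of |d_a - d_b|
  absdiff <- I0 %*% t(I1) + I1 %*% t(I0) +
    I1 %*% t(I2) + I2 %*% t(I1) +
    2 * (I0 %*% t(I2) + I2 %*% t(I0))
  ibs <- 1 - absdiff / (2 * n_loci)
  none <- n_loci == 0
  if (any(none[upper.tri(none)])) {
    warn("Some accession pairs share no called locus; IBS set to NA.")
    ibs[none] <- NA_real_
  }
  diag(ibs) <- 1
  structure(list(ibs = ibs, n_loci = n_loci), class = "ibs_matrix")
}

#' @export
print.ibs_matrix <- function(x, ...) {
  off <- x$ibs[upper.tri(x$ibs)]
  cat("<ibs_matrix>", nrow(x$ibs), "accessions; off-diagonal IBS range:",
      sprintf("%.4f-%.4f", min(off, na.rm = TRUE), max(off, na.rm = TRUE)), "\n")
  invisible(x)
}

#' Pairwise IBS as a tibble
#' @param x An `ibs_matrix`.
#' @param ... Unused.
#' @return Tibble (`id1`, `id2`, `ibs`, `n_loci`), one row per unordered pair.
#' @method tidy ibs_matrix
#' @export
tidy.ibs_matrix <- function(x, ...) {
  ids <- rownames(x$ibs)
  ut <- which(upper.tri(x$ibs), arr.ind = TRUE)
  tibble(
    id1 = ids[ut[, 1]], id2 = ids[ut[, 2]],
    ibs = x$ibs[ut], n_loci = x$n_loci[ut]
  )
}

#' Find near-duplicate accession pairs
#'
#' All unordered pairs whose IBS exceeds `threshold`, sorted by descending
#' IBS then lexicographic ids.
#'
#' @param km An [ibs_matrix()].
#' @param threshold Similarity threshold in `(0, 1]` (default 0.95, the usual
#'   clone-detection cut-off).
#' @return Tibble (`id1`, `id2`, `ibs`, `n_loci`).
#' @export
find_duplicate_pairs <- function(km, threshold = 0.95) {
  stopifnot(inherits(km, "ibs_matrix"))
  if (threshold <= 0 || threshold > 1) abort("`threshold` must lie in (0, 1].")
  tidy(km) |>
    filter(!is.na(.data$ibs), .data$ibs > threshold) |>
    arrange(dplyr::desc(.data$ibs), .data$id1, .data$id2)
}

#' Prune near-duplicates from a thematic collection
#'
#' Greedy pass over the duplicate pairs in sorted order: from each pair whose
#' members are both still in the collection, the worse-ranked member is
#' removed (tie: the higher accession id), preserving the selection intent.
#' After the pass no surviving within-collection pair exceeds the threshold.
#'
#' @param collection A `thematic_collection` (see [truncate_collection()]).
#' @param pairs Duplicate pairs from [find_duplicate_pairs()]; pairs involving
#'   non-members are ignored.
#' @return The pruned `thematic_collection` (provenance `"post-dedup"`), with
#'   removals and their partner/IBS recorded in attribute `removed`.
#' @export
prune_duplicates <- function(collection, pairs) {
  stopifnot(inherits(collection, "thematic_collection"))
  present <- collection$accession
  rank_of <- setNames(collection$rank, collection$accession)
  removed <- attr(collection, "removed")
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      a <- pairs$id1[i]
      b <- pairs$id2[i]
      if (!(a %in% present) || !(b %in% present)) next
      # worse composite rank goes; tie broken by higher accession id
      drop_id <- if (rank_of[a] > rank_of[b]) a
        else if (rank_of[b] > rank_of[a]) b
        else max(a, b)
      keep_id <- if (drop_id == a) b else a
      present <- setdiff(present, drop_id)
      removed <- bind_rows(removed, tibble(
        accession = drop_id,
        reason = sprintf("IBS %.4f > threshold with %s", pairs$ibs[i], keep_id),
        partner = keep_id,
        ibs = pairs$ibs[i]
      ))
    }
  }
  out <- collection |> filter(.data$accession %in% present)
  attr(out, "provenance") <- "post-dedup"
  attr(out, "removed") <- removed
  class(out) <- class(collection)
  out
}
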