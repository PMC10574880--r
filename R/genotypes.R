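#' Genotype matrix container
#'
#' A `geno_matrix` holds biallelic SNP calls for a set of accessions as
#' alt-allele dosages: an integer matrix with accessions in rows, loci in
#' columns, values in `{0, 1, 2}` and `NA` for missing calls. Locus metadata
#' (chromosome, position, ref/alt allele) travels alongside, sorted by
#' (chromosome, position).
#'
#' @param dosages Numeric matrix, accessions x loci, values in `{0, 1, 2}` or
#'   `NA`. Row names are accession identifiers, column names locus identifiers.
#' @param loci Optional tibble with one row per locus: `locus`, `chrom`, `pos`,
#'   `ref`, `alt`. Generated (chrom 1, consecutive positions, A/T alleles) when
#'   omitted.
#' @param imputed Logical; `TRUE` marks a matrix whose missing calls were
#'   replaced by real-valued means. Diversity statistics refuse imputed input.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosages, loci = NULL, imputed = FALSE) {
  if (!is.matrix(dosages)) abort("`dosages` must be a matrix.")
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("ACC%04d", seq_len(nrow(dosages)))
  }
  if (anyDuplicated(rownames(dosages))) {
    abort("Accession identifiers (row names) must be unique.")
  }
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- sprintf("L%05d", seq_len(ncol(dosages)))
  }
  vals <- dosages[!is.na(dosages)]
  if (!imputed && length(vals) && !all(vals %in% c(0, 1, 2))) {
    abort("Dosages must be 0, 1, 2 or NA (unless marked imputed).")
  }
  if (is.null(loci)) {
    loci <- tibble(
      locus = colnames(dosages),
      chrom = "1",
      pos = seq_len(ncol(dosages)),
      ref = "A",
      alt = "T"
    )
  }
  stopifnot(nrow(loci) == ncol(dosages))
  ord <- order(loci$chrom, loci$pos)
  loci <- loci[ord, , drop = FALSE]
  dosages <- dosages[, ord, drop = FALSE]
  colnames(dosages) <- loci$locus
  structure(
    list(dosages = dosages, loci = loci, imputed = imputed),
    class = "geno_matrix"
  )
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' @export
print.geno_matrix <- function(x, ...) {
  cat(
    "<geno_matrix> ", nrow(x$dosages), " accessions x ", ncol(x$dosages),
    " loci", if (x$imputed) " (mean-imputed)" else "",
    "; missing calls: ", sum(is.na(x$dosages)), "\n",
    sep = ""
  )
  invisible(x)
}

#' Accession identifiers of a genotype matrix
#' @param gm A [geno_matrix()].
#' @return Character vector of accession ids, in matrix order.
#' @export
accessions <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  rownames(gm$dosages)
}

#' @describeIn geno_matrix Long-format view: one row per (accession, locus).
#' @param x A `geno_matrix`.
#' @param ... Unused.
#' @method as_tibble geno_matrix
#' @export
as_tibble.geno_matrix <- function(x, ...) {
  tibble(
    accession = rep(rownames(x$dosages), times = ncol(x$dosages)),
    locus = rep(colnames(x$dosages), each = nrow(x$dosages)),
    dosage = as.vector(x$dosages)
  )
}

#' Restrict a genotype matrix to a subset of accessions
#'
#' @param gm A [geno_matrix()].
#' @param ids Accession identifiers to keep (order preserved as given).
#' @return A `geno_matrix` with the selected rows.
#' @export
subset_accessions <- function(gm, ids) {
  stopifnot(inherits(gm, "geno_matrix"))
  missing_ids <- setdiff(ids, accessions(gm))
  if (length(missing_ids)) {
    abort(paste0(
      "Accessions absent from genotype matrix: ",
      paste(head(missing_ids, 5), collapse = ", ")
    ))
  }
  geno_matrix(gm$dosages[ids, , drop = FALSE], gm$loci, imputed = gm$imputed)
}
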