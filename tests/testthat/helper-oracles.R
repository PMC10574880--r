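# Independent brute-force oracles, kept deliberately naive (per-element loops
# and direct textbook formulas) so they share no code path with the package.

brute_ibs <- function(dos) {
  n <- nrow(dos)
  ibs <- matrix(NA_real_, n, n, dimnames = list(rownames(dos), rownames(dos)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ok <- !is.na(dos[i, ]) & !is.na(dos[j, ])
      if (any(ok)) {
        ibs[i, j] <- mean(1 - abs(dos[i, ok] - dos[j, ok]) / 2)
      }
    }
  }
  diag(ibs) <- 1
  ibs
}

brute_molecular <- function(dos) {
  out <- matrix(NA_real_, ncol(dos), 3,
                dimnames = list(colnames(dos), c("ho", "hs", "fis")))
  for (j in seq_len(ncol(dos))) {
    col <- dos[!is.na(dos[, j]), j]
    nn <- length(col)
    if (nn == 0) next
    ho <- sum(col == 1) / nn
    out[j, "ho"] <- ho
    if (nn >= 2) {
      p <- sum(col) / (2 * nn)
      hs <- (nn / (nn - 1)) * (1 - p^2 - (1 - p)^2 - ho / (2 * nn))
      hs <- max(hs, 0)
      out[j, "hs"] <- hs
      out[j, "fis"] <- if (hs > 0) 1 - ho / hs else NA_real_
    }
  }
  out
}

brute_shannon <- function(labels, k) {
  labels <- labels[!is.na(labels)]
  h <- 0
  for (cl in unique(labels)) {
    p <- sum(labels == cl) / length(labels)
    h <- h - p * log(p)
  }
  if (k == 1) 0 else h / log(k)
}

brute_kappa <- function(x, y) {
  a <- sum(x & y); b <- sum(x & !y); c <- sum(!x & y); d <- sum(!x & !y)
  n <- a + b + c + d
  po <- (a + d) / n
  pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  (po - pe) / (1 - pe)
}

as_collection <- function(ids, ranks = seq_along(ids), name = "cc") {
  truncate_collection(
    tibble::tibble(
      accession = ids, composite_score = ranks, rank = ranks, n_traits = 1
    ),
    length(ids), name
  )
}
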