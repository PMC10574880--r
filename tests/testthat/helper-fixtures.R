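# Shared fixtures: tiny genotype matrices and trial records built in code.

make_gm <- function(dosages, ids = NULL) {
  m <- as.matrix(dosages)
  if (!is.null(ids)) rownames(m) <- ids
  geno_matrix(m)
}

# random small panel with missingness, for oracle comparisons
random_gm <- function(n = 20, L = 50, miss = 0.05, seed = 1) {
  set.seed(seed)
  m <- matrix(sample(0:2, n * L, replace = TRUE), n, L)
  if (miss > 0) m[runif(n * L) < miss] <- NA
  rownames(m) <- sprintf("A%03d", seq_len(n))
  geno_matrix(m)
}

# balanced single/multi-environment trial records built by hand
make_records <- function(accessions, environments = "E1", blocks = "B1",
                         trait = "t", values) {
  grid <- expand.grid(
    accession = accessions, environment = environments, block = blocks,
    stringsAsFactors = FALSE
  )
  tibble::tibble(
    accession = grid$accession,
    environment = grid$environment,
    trial = grid$environment,
    block = grid$block,
    trait = trait,
    value = values
  )
}

# dense hand-assembled Henderson mixed-model equations (independent oracle)
dense_mme_solve <- function(records, trait, sigma2) {
  d <- records[records$trait == trait, ]
  y <- d$value
  g <- factor(d$accession)
  bw <- factor(paste(d$environment, d$block, sep = ":"))
  ge <- factor(paste(d$accession, d$environment, sep = ":"))
  X <- matrix(1, length(y), 1)
  blocks <- list(X)
  lam <- numeric(0)
  add <- function(f, s2) {
    Z <- matrix(0, length(y), nlevels(f))
    Z[cbind(seq_along(f), as.integer(f))] <- 1
    blocks[[length(blocks) + 1]] <<- Z
    lam <<- c(lam, sigma2[["e"]] / s2)
  }
  add(g, sigma2[["g"]])
  if (!is.null(sigma2[["b"]]) && sigma2[["b"]] > 0 && nlevels(bw) > 1) add(bw, sigma2[["b"]])
  if (!is.null(sigma2[["ge"]]) && sigma2[["ge"]] > 0 &&
      length(unique(d$environment)) > 1) add(ge, sigma2[["ge"]])
  W <- do.call(cbind, blocks)
  qs <- vapply(blocks[-1], ncol, integer(1))
  M <- crossprod(W) + diag(c(0, rep(lam, qs)))
  s <- solve(M, crossprod(W, y))
  list(mu = s[1], g_hat = s[1 + seq_len(nlevels(g))], levels = levels(g))
}
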