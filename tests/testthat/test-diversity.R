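test_that("quantitative binning follows the half-open-left class convention", {
  scheme <- binning_scheme(c(0, 6), k = 6)
  expect_equal(bin_quantitative(0, scheme), 1L) # class 1 closed at min
  expect_equal(bin_quantitative(6, scheme), 6L)
  expect_equal(bin_quantitative(1.0, scheme), 1L) # boundary belongs below
  expect_equal(bin_quantitative(1.0 + 1e-9, scheme), 2L)
  expect_error(bin_quantitative(7, scheme), "range")

  mono <- binning_scheme(rep(3, 5))
  expect_true(mono$monomorphic)
  expect_equal(bin_quantitative(c(3, 3), mono), c(1L, 1L))
})

test_that("uniform draws fill the six classes near-evenly", {
  set.seed(10)
  v <- runif(6000, 0, 6)
  scheme <- binning_scheme(c(0, 6), k = 6)
  counts <- tabulate(bin_quantitative(v, scheme), 6)
  expect_true(all(abs(counts - 1000) < 5 * sqrt(6000 * (1 / 6) * (5 / 6))))
})

test_that("Shannon-Weaver hits its monomorphic and uniform extremes", {
  expect_equal(shannon_weaver(rep(1, 50), 6), 0)
  expect_equal(shannon_weaver(rep(1:6, each = 10), 6), 1)
  # frequencies (0.5, 0.25, 0.25) over 3 classes
  labels <- c(rep(1, 2), 2, 3)
  expect_equal(shannon_weaver(labels, 3), 1.0397208 / log(3), tolerance = 1e-6)
  expect_equal(round(shannon_weaver(labels, 3), 3), 0.946)
  expect_true(is.na(shannon_weaver(integer(0), 4)))
})

test_that("a sub-collection missing classes is penalized by the defined-class norm", {
  expect_lt(shannon_weaver(rep(1:3, each = 5), 6), 1)
  expect_equal(shannon_weaver(rep(1:3, each = 5), 3), 1)
})

test_that("molecular diversity matches the hand-evaluated corrected formulas", {
  all_het <- make_gm(matrix(1, 10, 1))
  md <- molecular_diversity(all_het)
  expect_equal(md$per_locus$ho, 1)
  expect_equal(md$per_locus$hs, 0.5) # (10/9) * (1 - 0.5 - 0.05)
  expect_equal(md$per_locus$fis, -1)

  mono <- make_gm(matrix(0, 8, 1))
  md2 <- molecular_diversity(mono)
  expect_equal(md2$per_locus$ho, 0)
  expect_equal(md2$per_locus$hs, 0)
  expect_true(is.na(md2$per_locus$fis))
})

test_that("per-locus statistics equal a brute-force counting oracle", {
  for (s in 1:5) {
    gm <- random_gm(n = 15, L = 30, miss = 0.1, seed = 400 + s)
    md <- molecular_diversity(gm)
    oracle <- brute_molecular(gm$dosages)
    expect_equal(md$per_locus$ho, unname(oracle[, "ho"]), tolerance = 1e-12)
    expect_equal(md$per_locus$hs, unname(oracle[, "hs"]), tolerance = 1e-12)
    expect_equal(md$per_locus$fis, unname(oracle[, "fis"]), tolerance = 1e-12)
    # Fis identity wherever Hs > 0
    ok <- !is.na(md$per_locus$hs) & md$per_locus$hs > 0
    expect_equal(
      md$per_locus$fis[ok],
      1 - md$per_locus$ho[ok] / md$per_locus$hs[ok],
      tolerance = 1e-14
    )
  }
})

test_that("imputed matrices are refused by diversity statistics", {
  gm <- impute_mean(random_gm(10, 10, miss = 0.1, seed = 2))
  expect_error(molecular_diversity(gm), "raw")
  expect_error(ibs_matrix(gm), "raw")
})

test_that("allele retention reproduces printed-count arithmetic and subsetting", {
  expect_equal(retention_percent(53251, 58671), 90.76)
  expect_equal(retention_percent(51688, 58671), 88.10)
  expect_equal(retention_percent(52211, 58671), 88.99)

  gm <- random_gm(n = 20, L = 50, miss = 0, seed = 12)
  full <- allele_retention(gm, accessions(gm))
  expect_equal(full$retention_pct, 100)
  sub <- allele_retention(gm, accessions(gm)[1:5])
  expect_lte(sub$n_alleles_subset, sub$n_alleles_reference)
  expect_error(allele_retention(gm, c("A001", "nope")), "contained")
})

test_that("removing all carriers of a private allele drops the count by its plant", {
  set.seed(33)
  base <- matrix(0L, 10, 5, dimnames = list(sprintf("A%02d", 1:10), NULL))
  base[, 1:4][sample(40, 20)] <- 1L
  base[1:2, 5] <- 1L # locus 5 alt allele private to A01/A02
  base[3:10, 5] <- 0L
  gm <- make_gm(base)
  with_c <- allele_retention(gm, accessions(gm))
  without <- allele_retention(gm, accessions(gm)[3:10])
  expect_equal(
    with_c$n_alleles_subset - without$n_alleles_subset,
    1 + sum(vapply(1:4, function(j) {
      col <- base[, j]
      as.numeric((any(col[1:2] > 0) && !any(col[3:10] > 0)) +
        (any(col[1:2] < 2) && !any(col[3:10] < 2)))
    }, numeric(1)))
  )
})

test_that("Kappa agrees with the 2x2-table arithmetic oracle", {
  # identical vectors
  u <- sprintf("A%03d", 1:100)
  k <- kappa_coincidence(list(x = u[1:20], y = u[1:20]), universe = u)
  expect_equal(k["x", "y"], 1)
  expect_equal(diag(k), c(x = 1, y = 1))

  # worked 2x2 table: a=11, b=61, c=53, d=1685
  n <- 11 + 61 + 53 + 1685
  x <- c(rep(TRUE, 72), rep(FALSE, n - 72))
  y <- c(rep(TRUE, 11), rep(FALSE, 61), rep(TRUE, 53), rep(FALSE, 1685))
  m <- cbind(cc1 = x, cc2 = y)
  rownames(m) <- sprintf("U%04d", seq_len(n))
  got <- kappa_coincidence(m)["cc1", "cc2"]
  expect_equal(got, brute_kappa(x, y), tolerance = 1e-12)
  po <- (11 + 1685) / n
  pe <- (72 * 64 + 1738 * 1746) / n^2
  expect_equal(got, (po - pe) / (1 - pe), tolerance = 1e-12)

  # degenerate vector
  k2 <- kappa_coincidence(list(a = u[1:10], b = u), universe = u)
  expect_true(is.na(k2["a", "b"]))
})

test_that("independent sparse selections have near-zero Kappa", {
  set.seed(14)
  u <- sprintf("U%05d", 1:10000)
  x <- u[runif(10000) < 0.04]
  y <- u[runif(10000) < 0.04]
  k <- kappa_coincidence(list(x = x, y = y), universe = u)
  expect_lt(abs(k["x", "y"]), 0.05)
})

test_that("kappa matches brute force on random membership patterns", {
  for (s in 1:20) {
    set.seed(500 + s)
    u <- sprintf("U%03d", 1:60)
    m <- cbind(
      a = runif(60) < 0.3,
      b = runif(60) < 0.5,
      c = runif(60) < 0.2
    )
    rownames(m) <- u
    got <- kappa_coincidence(m)
    for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
      expect_equal(
        got[pair[1], pair[2]],
        brute_kappa(m[, pair[1]], m[, pair[2]]),
        tolerance = 1e-12
      )
      expect_equal(got[pair[1], pair[2]], got[pair[2], pair[1]])
    }
  }
})

test_that("the diversity report assembles all layers coherently", {
  sp <- sim_spec(n_accessions = 40, n_loci = 100, clone_pairs = 0, seed = 60,
                 variance_components = list(t = c(g = 1, b = 0.1, ge = 0.2, e = 1)))
  gm <- simulate_genotypes(sp)
  acc <- accessions(gm)
  quant <- tibble::tibble(accession = acc, trait = "t", value = rnorm(40))
  qual <- tibble::tibble(accession = acc, trait = "q",
                         class = sample(c("a", "b", "c"), 40, TRUE))
  rep <- diversity_report(
    gm,
    collections = list(c1 = acc[1:12], c2 = acc[13:30]),
    quantitative = quant, qualitative = qual,
    kappa_universe = acc
  )
  expect_setequal(unique(rep$shannon$collection), c("entire", "c1", "c2"))
  expect_true(all(rep$shannon$h_prime >= 0 & rep$shannon$h_prime <= 1, na.rm = TRUE))
  expect_equal(rep$molecular$retention_pct[rep$molecular$collection == "entire"], 100)
  expect_true(all(rep$molecular$retention_pct > 0 & rep$molecular$retention_pct <= 100))
  expect_equal(dim(rep$kappa), c(2L, 2L))
})
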