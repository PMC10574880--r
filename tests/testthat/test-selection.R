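theme1 <- theme_config("demo", c(t1 = "lower"), n_target = 2)

test_that("single-trait ranking sorts by the favourable direction", {
  blups <- tibble::tibble(
    accession = c("A", "B", "C"), trait = "t1", g_hat = c(-1, 0, 2)
  )
  ranked <- rank_candidates(blups, theme1)
  expect_equal(ranked$accession, c("A", "B", "C"))

  higher <- theme_config("demo", c(t1 = "higher"), n_target = 2)
  expect_equal(rank_candidates(blups, higher)$accession, c("C", "B", "A"))
})

test_that("perfectly opposed traits tie and fall back to accession-id order", {
  blups <- dplyr::bind_rows(
    tibble::tibble(accession = c("C", "A", "B"), trait = "t1", g_hat = c(1, 2, 3)),
    tibble::tibble(accession = c("C", "A", "B"), trait = "t2", g_hat = c(3, 2, 1))
  )
  th <- theme_config("demo", c(t1 = "higher", t2 = "higher"), n_target = 3)
  ranked <- rank_candidates(blups, th)
  expect_equal(length(unique(ranked$composite_score)), 1L)
  expect_equal(ranked$accession, c("A", "B", "C"))
})

test_that("composite order equals a brute-force mean-rank recomputation", {
  set.seed(5)
  acc <- sprintf("A%02d", 1:20)
  blups <- dplyr::bind_rows(lapply(c("t1", "t2", "t3"), function(tr) {
    tibble::tibble(accession = acc, trait = tr, g_hat = rnorm(20))
  }))
  th <- theme_config("demo", c(t1 = "lower", t2 = "higher", t3 = "lower"),
                     n_target = 20)
  ranked <- rank_candidates(blups, th)

  wide <- matrix(blups$g_hat, 20, 3,
                 dimnames = list(acc, c("t1", "t2", "t3")))
  oracle <- (rank(wide[, "t1"]) + rank(-wide[, "t2"]) + rank(wide[, "t3"])) / 3
  expect_equal(
    setNames(ranked$composite_score, ranked$accession)[acc],
    oracle
  )
  expect_equal(ranked$accession, acc[order(oracle, acc)])
})

test_that("ranking is invariant to monotone transforms of one trait", {
  set.seed(6)
  acc <- sprintf("A%02d", 1:15)
  blups <- dplyr::bind_rows(lapply(c("t1", "t2"), function(tr) {
    tibble::tibble(accession = acc, trait = tr, g_hat = rnorm(15))
  }))
  th <- theme_config("demo", c(t1 = "higher", t2 = "lower"), n_target = 15)
  base <- rank_candidates(blups, th)
  warped <- blups |>
    dplyr::mutate(g_hat = ifelse(trait == "t1", exp(3 * g_hat) + 7, g_hat))
  expect_equal(rank_candidates(warped, th)$accession, base$accession)
})

test_that("low BLUP coverage excludes an accession with a reason", {
  blups <- dplyr::bind_rows(
    tibble::tibble(accession = c("A", "B"), trait = "t1", g_hat = c(1, 2)),
    tibble::tibble(accession = "A", trait = "t2", g_hat = 1),
    tibble::tibble(accession = "A", trait = "t3", g_hat = 1)
  )
  th <- theme_config("demo", c(t1 = "higher", t2 = "higher", t3 = "higher"),
                     n_target = 2)
  ranked <- rank_candidates(blups, th)
  expect_false("B" %in% ranked$accession)
  excl <- attr(ranked, "excluded")
  expect_equal(excl$accession, "B")
  expect_match(excl$reason, "coverage")
})

test_that("eligibility filters implement threshold and class-set logic", {
  candidates <- tibble::tibble(
    accession = c("A", "B", "C"),
    composite_score = c(1, 2, 3), rank = 1:3, n_traits = 1
  )
  traits <- dplyr::bind_rows(
    tibble::tibble(accession = c("A", "B", "C"), trait = "hcn",
                   value = c("3", "5", "7")),
    tibble::tibble(accession = c("A", "B", "C"), trait = "pulp",
                   value = c("cream", "cream", "white"))
  )
  out <- apply_eligibility(
    candidates,
    list(list(trait = "hcn", op = "<", value = 5)),
    traits
  )
  expect_equal(out$accession, "A")
  expect_equal(attr(out, "removed")$accession, c("B", "C"))

  both <- apply_eligibility(
    candidates,
    list(
      list(trait = "hcn", op = "<", value = 7),
      list(trait = "pulp", op = "in", value = c("cream", "yellow"))
    ),
    traits
  )
  expect_equal(both$accession, c("A", "B"))

  expect_error(
    apply_eligibility(candidates, list(list(trait = "nope", op = "<", value = 1)), traits),
    "absent trait"
  )
  expect_equal(apply_eligibility(candidates, list())$accession, c("A", "B", "C"))
})

test_that("survivor sets equal brute-force set intersection over many filters", {
  set.seed(8)
  acc <- sprintf("A%02d", 1:25)
  candidates <- tibble::tibble(
    accession = acc, composite_score = seq_along(acc), rank = seq_along(acc),
    n_traits = 2
  )
  v1 <- sample(1:9, 25, TRUE)
  v2 <- sample(10:40, 25, TRUE)
  v3 <- sample(c("w", "c", "y"), 25, TRUE)
  v4 <- sample(1:4, 25, TRUE)
  traits <- dplyr::bind_rows(
    tibble::tibble(accession = acc, trait = "f1", value = as.character(v1)),
    tibble::tibble(accession = acc, trait = "f2", value = as.character(v2)),
    tibble::tibble(accession = acc, trait = "f3", value = v3),
    tibble::tibble(accession = acc, trait = "f4", value = as.character(v4))
  )
  filters <- list(
    list(trait = "f1", op = "<", value = 5),
    list(trait = "f2", op = ">=", value = 20),
    list(trait = "f3", op = "in", value = c("c", "y")),
    list(trait = "f4", op = "<=", value = 3)
  )
  out <- apply_eligibility(candidates, filters, traits)
  oracle <- acc[v1 < 5 & v2 >= 20 & v3 %in% c("c", "y") & v4 <= 3]
  expect_setequal(out$accession, oracle)
})

test_that("truncation keeps the top of the list and is monotone in k", {
  ranked <- tibble::tibble(
    accession = c("A", "B", "C"), composite_score = 1:3, rank = 1:3, n_traits = 1
  )
  expect_equal(truncate_collection(ranked, 2)$accession, c("A", "B"))
  expect_warning(all3 <- truncate_collection(ranked, 5), "only 3")
  expect_equal(nrow(all3), 3L)
  for (k in 1:2) {
    expect_true(all(
      truncate_collection(ranked, k)$accession %in%
        truncate_collection(ranked, k + 1)$accession
    ))
  }
})

test_that("a dominant trait recovers the true top set at high heritability", {
  sp <- sim_spec(
    n_accessions = 100, n_loci = 10, clone_pairs = 0, seed = 55,
    n_environments = 2, env_prob = 1,
    variance_components = list(t = c(g = 10, b = 0.1, ge = 0.1, e = 0.1)),
    missing_phenotype_rate = 0
  )
  tr <- simulate_trials(sprintf("A%03d", 1:100), sp)
  fit <- fit_blup(tr$records)
  th <- theme_config("top", c(t = "higher"), n_target = 10)
  sel <- truncate_collection(rank_candidates(tidy(fit), th), 10, "top")
  truth <- tr$genetic_values
  true_top <- truth$accession[order(-truth$g_true)][1:10]
  expect_gte(length(intersect(sel$accession, true_top)), 9L)
})
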