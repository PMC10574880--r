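test_that("zero-variance data drives every component to the floor", {
  rec <- make_records(sprintf("A%d", 1:6), environments = c("E1", "E2"),
                      blocks = c("B1", "B2"), values = rep(5, 24))
  vc <- suppressWarnings(fit_reml(rec, "t"))
  expect_true(all(vc$sigma2[c("g", "e")] <= 1e-7))
  expect_true(vc$converged)
})

test_that("single-record shrinkage matches the closed form", {
  set.seed(42)
  y <- rnorm(30, 10, 2)
  rec <- make_records(sprintf("A%02d", 1:30), values = y)
  vc <- list(sigma2 = c(g = 1.5, b = 0, ge = 0, e = 2.5))
  blups <- suppressWarnings(predict_blups(rec, vc, "t"))
  expect_equal(attr(blups, "mu_hat"), mean(y), tolerance = 1e-10)
  shrink <- 1.5 / (1.5 + 2.5)
  expect_equal(blups$g_hat, shrink * (y - mean(y)), tolerance = 1e-10)
})

test_that("BLUPs approach centred genotype means as sigma2_g dominates", {
  set.seed(1)
  y <- rnorm(20)
  rec <- make_records(sprintf("A%02d", 1:20), values = y)
  vc <- list(sigma2 = c(g = 1e7, b = 0, ge = 0, e = 1))
  blups <- suppressWarnings(predict_blups(rec, vc, "t"))
  expect_equal(blups$g_hat, y - mean(y), tolerance = 1e-4)
})

test_that("BLUPs equal a dense hand-assembled Henderson solve on small instances", {
  sp <- sim_spec(
    n_accessions = 8, n_loci = 10, clone_pairs = 0, seed = 17,
    n_environments = 3, n_blocks_per_env = 2, env_prob = 0.8,
    variance_components = list(t = c(g = 1, b = 0.3, ge = 0.5, e = 1)),
    missing_phenotype_rate = 0.1
  )
  tr <- simulate_trials(sprintf("A%02d", 1:8), sp)
  names(tr$records)[names(tr$records) == "trait"] <- "trait"
  vc <- suppressWarnings(fit_reml(tr$records, "t"))
  blups <- predict_blups(tr$records, vc, "t")
  oracle <- dense_mme_solve(tr$records, "t", vc$sigma2)
  expect_equal(attr(blups, "mu_hat"), oracle$mu, tolerance = 1e-8)
  expect_equal(blups$g_hat, unname(oracle$g_hat[match(blups$accession, oracle$levels)]),
               tolerance = 1e-8)
})

test_that("shrunken genotype effects centre near zero and shift only the mean", {
  sp <- sim_spec(
    n_accessions = 40, n_loci = 10, clone_pairs = 0, seed = 23,
    variance_components = list(t = c(g = 1, b = 0.3, ge = 0.5, e = 1))
  )
  tr <- simulate_trials(sprintf("A%02d", 1:40), sp)
  vc <- fit_reml(tr$records, "t")
  b1 <- predict_blups(tr$records, vc, "t")
  expect_lt(abs(mean(b1$g_hat)), 0.05)

  shifted <- tr$records
  shifted$value <- shifted$value + 100
  b2 <- predict_blups(shifted, vc, "t")
  expect_equal(b2$g_hat, b1$g_hat, tolerance = 1e-8)
  expect_equal(attr(b2, "mu_hat"), attr(b1, "mu_hat") + 100, tolerance = 1e-8)
})

test_that("EM iterations never decrease the restricted likelihood", {
  for (s in 1:3) {
    sp <- sim_spec(
      n_accessions = 50, n_loci = 10, clone_pairs = 0, seed = 100 + s,
      variance_components = list(t = c(g = 1, b = 0.3, ge = 0.5, e = 1))
    )
    tr <- simulate_trials(sprintf("A%02d", 1:50), sp)
    vc <- fit_reml(tr$records, "t")
    expect_true(all(diff(vc$minus2loglik) <= 1e-6))
  }
})

test_that("estimates agree with lme4 REML on an unbalanced dataset", {
  skip_if_not_installed("lme4")
  sp <- sim_spec(
    n_accessions = 80, n_loci = 10, clone_pairs = 0, seed = 3,
    variance_components = list(t = c(g = 1, b = 0.3, ge = 0.5, e = 1))
  )
  tr <- simulate_trials(sprintf("A%02d", 1:80), sp)
  vc <- fit_reml(tr$records, "t")
  d <- tr$records
  m <- lme4::lmer(
    value ~ 1 + (1 | accession) + (1 | environment:block) +
      (1 | accession:environment),
    data = d, REML = TRUE
  )
  ref <- as.data.frame(lme4::VarCorr(m))
  ref_map <- setNames(ref$vcov, ref$grp)
  expect_equal(vc$sigma2[["g"]], ref_map[["accession"]], tolerance = 1e-3)
  expect_equal(vc$sigma2[["b"]], ref_map[["environment:block"]], tolerance = 1e-2)
  expect_equal(vc$sigma2[["ge"]], ref_map[["accession:environment"]], tolerance = 1e-2)
  expect_equal(vc$sigma2[["e"]], ref_map[["Residual"]], tolerance = 1e-3)
})

test_that("single-environment fits drop the interaction and match a direct REML oracle", {
  sp <- sim_spec(
    n_accessions = 40, n_loci = 10, clone_pairs = 0, seed = 31,
    n_environments = 1, n_blocks_per_env = 3, env_prob = 1,
    variance_components = list(t = c(g = 1, b = 0.4, ge = 0, e = 1)),
    missing_phenotype_rate = 0
  )
  tr <- simulate_trials(sprintf("A%02d", 1:40), sp)
  expect_warning(vc <- fit_reml(tr$records, "t"), "dropping")
  expect_equal(vc$sigma2[["ge"]], 0)

  # independent oracle: direct dense REML likelihood maximized over
  # (sigma2_g, sigma2_b, sigma2_e) on the log scale
  d <- tr$records
  y <- d$value
  Zg <- outer(d$accession, sort(unique(d$accession)), "==") * 1
  Zb <- outer(paste(d$environment, d$block),
              sort(unique(paste(d$environment, d$block))), "==") * 1
  X <- matrix(1, length(y), 1)
  negll <- function(par) {
    s <- exp(par)
    V <- s[1] * tcrossprod(Zg) + s[2] * tcrossprod(Zb) + s[3] * diag(length(y))
    Vi <- solve(V)
    P <- Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi
    as.numeric(
      determinant(V)$modulus + determinant(t(X) %*% Vi %*% X)$modulus +
        t(y) %*% P %*% y
    )
  }
  fit <- optim(log(c(0.5, 0.5, 0.5)), negll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  oracle <- exp(fit$par)
  expect_equal(vc$sigma2[["g"]], oracle[1], tolerance = 0.02)
  expect_equal(vc$sigma2[["b"]], oracle[2], tolerance = 0.05)
  expect_equal(vc$sigma2[["e"]], oracle[3], tolerance = 0.02)
})

test_that("heritability follows the entry-mean formula", {
  vc <- list(sigma2 = c(g = 1, b = 0, ge = 0, e = 0))
  expect_equal(heritability(vc, 2, 2), 1)
  vc$sigma2 <- c(g = 0, b = 0, ge = 1, e = 1)
  expect_equal(heritability(vc, 2, 2), 0)
  vc$sigma2 <- c(g = 1, b = 0, ge = 1, e = 1)
  expect_equal(heritability(vc, 2, 2), 1 / (1 + 0.5 + 0.25), tolerance = 1e-12)
  vc$sigma2 <- c(g = 0, b = 0, ge = 0, e = 0)
  expect_equal(heritability(vc, 3, 1), 0)
})

test_that("BLUP-truth correlation rises with simulated heritability", {
  cors <- vapply(c(0.2, 1, 5), function(s2g) {
    sp <- sim_spec(
      n_accessions = 120, n_loci = 10, clone_pairs = 0, seed = 77,
      n_environments = 1, n_blocks_per_env = 2, env_prob = 1,
      variance_components = list(t = c(g = s2g, b = 0.2, ge = 0, e = 1)),
      missing_phenotype_rate = 0
    )
    tr <- simulate_trials(sprintf("A%03d", 1:120), sp)
    vc <- suppressWarnings(fit_reml(tr$records, "t"))
    bl <- predict_blups(tr$records, vc, "t")
    truth <- tr$genetic_values
    cor(bl$g_hat, truth$g_true[match(bl$accession, truth$accession)])
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
  expect_gt(cors[3], 0.9)
})

test_that("tidy and glance expose the fitted model in broom shape", {
  sp <- sim_spec(
    n_accessions = 25, n_loci = 10, clone_pairs = 0, seed = 19,
    variance_components = list(
      a = c(g = 1, b = 0.2, ge = 0.3, e = 1),
      b = c(g = 2, b = 0.2, ge = 0.3, e = 0.5)
    ),
    trait_directions = c(a = "higher", b = "lower")
  )
  tr <- simulate_trials(sprintf("A%02d", 1:25), sp)
  fit <- fit_blup(tr$records)
  td <- tidy(fit)
  expect_named(td, c("trait", "accession", "g_hat"))
  expect_setequal(unique(td$trait), c("a", "b"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 2L)
  expect_true(all(gl$h2 >= 0 & gl$h2 <= 1))
  expect_true(all(gl$converged))
})
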