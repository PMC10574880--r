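#' Simulation settings for synthetic germplasm
#'
#' Bundles every knob of the synthetic-germplasm generators: a structured SNP
#' panel with planted near-duplicate clone pairs, unbalanced multi-environment
#' trials generated under the mixed model y = mu + g + b + ge + e, and noisy
#' repeated qualitative scores. Defaults describe the study conditions the
#' pipeline is exercised under: 300 accessions in 3 sub-populations (Fst 0.1)
#' typed at 2,000 SNPs with 5 clone pairs at 1% per-locus discordance, trialled
#' in 4 environments with 2 blocks each under variance components
#' (sigma2_g, sigma2_b, sigma2_ge, sigma2_e) = (1.0, 0.3, 0.5, 1.0).
#'
#' @param n_accessions,n_loci,n_populations Panel dimensions (counts >= 1).
#' @param fst Divergence between sub-populations, in `[0, 1)`; 0 gives a single
#'   panmictic pool.
#' @param clone_pairs Number of planted near-duplicate pairs; `2 * clone_pairs`
#'   must not exceed `n_accessions`.
#' @param clone_error_rate Per-locus probability that a clone's call differs
#'   from its progenitor, in `[0, 0.05]`.
#' @param maf_floor Minimum ancestral allele frequency, in `(0, 0.5)`.
#' @param n_environments,n_blocks_per_env Trial design (counts >= 1).
#' @param env_prob Probability an accession is evaluated in any one
#'   environment; drives the design unbalance.
#' @param variance_components Named list, one entry per trait, each a numeric
#'   vector `c(g, b, ge, e)` of non-negative variances.
#' @param missing_phenotype_rate Probability a trial record is deleted.
#' @param trait_directions Named character vector mapping trait to
#'   `"higher"` or `"lower"` (which direction is favourable).
#' @param seed Integer seed; identical seeds reproduce identical outputs.
#'
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_accessions = 300,
                     n_loci = 2000,
                     n_populations = 3,
                     fst = 0.1,
                     clone_pairs = 5,
                     clone_error_rate = 0.01,
                     maf_floor = 0.05,
                     n_environments = 4,
                     n_blocks_per_env = 2,
                     env_prob = 0.7,
                     variance_components = list(
                       yield = c(g = 1.0, b = 0.3, ge = 0.5, e = 1.0)
                     ),
                     missing_phenotype_rate = 0.1,
                     trait_directions = c(yield = "higher"),
                     seed = 1L) {
  counts <- c(
    n_accessions = n_accessions, n_loci = n_loci,
    n_populations = n_populations, n_environments = n_environments,
    n_blocks_per_env = n_blocks_per_env
  )
  if (any(counts < 1) || any(counts != floor(counts))) {
    abort("All counts must be integers >= 1.")
  }
  if (fst < 0 || fst >= 1) abort("`fst` must lie in [0, 1).")
  if (clone_error_rate < 0 || clone_error_rate > 0.05) {
    abort("`clone_error_rate` must lie in [0, 0.05].")
  }
  if (2 * clone_pairs > n_accessions) {
    abort("Clone budget exceeds accession count (2 * clone_pairs > n_accessions).")
  }
  if (maf_floor <= 0 || maf_floor >= 0.5) abort("`maf_floor` must lie in (0, 0.5).")
  if (missing_phenotype_rate < 0 || missing_phenotype_rate > 1) {
    abort("`missing_phenotype_rate` must be a probability.")
  }
  for (tr in names(variance_components)) {
    vc <- variance_components[[tr]]
    if (length(vc) != 4 || any(vc < 0)) {
      abort(paste0("Variance components for '", tr, "' must be 4 non-negative values."))
    }
  }
  if (!all(trait_directions %in% c("higher", "lower"))) {
    abort("`trait_directions` values must be 'higher' or 'lower'.")
  }
  structure(
    list(
      n_accessions = as.integer(n_accessions), n_loci = as.integer(n_loci),
      n_populations = as.integer(n_populations), fst = fst,
      clone_pairs = as.integer(clone_pairs),
      clone_error_rate = clone_error_rate, maf_floor = maf_floor,
      n_environments = as.integer(n_environments),
      n_blocks_per_env = as.integer(n_blocks_per_env), env_prob = env_prob,
      variance_components = variance_components,
      missing_phenotype_rate = missing_phenotype_rate,
      trait_directions = trait_directions, seed = as.integer(seed)
    ),
    class = "sim_spec"
  )
}

#' Simulate a structured SNP panel with planted clone pairs
#'
#' Two-level Balding-Nichols sampling: each locus draws an ancestral frequency
#' p ~ Uniform(maf_floor, 1 - maf_floor); each sub-population draws its own
#' frequency from Beta(p(1-Fst)/Fst, (1-p)(1-Fst)/Fst) (equal to p when
#' Fst = 0); dosages are Binomial(2, population frequency). Clone pairs are
#' planted by copying a progenitor's row into a clone accession and flipping
#' each locus independently with probability `clone_error_rate` (a flipped
#' call is replaced by a uniform draw from the other two dosage values). Loci
#' receive chromosome/position metadata over 18 chromosomes.
#'
#' @param spec A [sim_spec()].
#' @return A [geno_matrix()] with attributes `population` (named integer
#'   vector) and `clone_pairs` (tibble: `progenitor`, `clone`).
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_accessions
  L <- spec$n_loci
  p_anc <- runif(L, spec$maf_floor, 1 - spec$maf_floor)
  pop <- rep_len(seq_len(spec$n_populations), n)
  acc_ids <- sprintf("ACC%04d", seq_len(n))
  names(pop) <- acc_ids

  pop_freq <- matrix(0, spec$n_populations, L)
  for (k in seq_len(spec$n_populations)) {
    if (spec$fst > 0) {
      a <- p_anc * (1 - spec$fst) / spec$fst
      b <- (1 - p_anc) * (1 - spec$fst) / spec$fst
      pop_freq[k, ] <- rbeta(L, a, b)
    } else {
      pop_freq[k, ] <- p_anc
    }
  }
  dos <- matrix(0L, n, L, dimnames = list(acc_ids, NULL))
  for (i in seq_len(n)) {
    dos[i, ] <- rbinom(L, 2L, pop_freq[pop[i], ])
  }

  pairs <- tibble(progenitor = character(), clone = character())
  if (spec$clone_pairs > 0) {
    prog_idx <- seq_len(spec$clone_pairs)
    clone_idx <- n - spec$clone_pairs + seq_len(spec$clone_pairs)
    for (j in seq_len(spec$clone_pairs)) {
      row <- dos[prog_idx[j], ]
      flip <- runif(L) < spec$clone_error_rate
      if (any(flip)) {
        # uniform draw from the two dosage values other than the current one
        cur <- row[flip]
        pick <- runif(sum(flip)) < 0.5
        alt1 <- (cur + 1L) %% 3L
        alt2 <- (cur + 2L) %% 3L
        row[flip] <- ifelse(pick, alt1, alt2)
      }
      dos[clone_idx[j], ] <- row
      pop[clone_idx[j]] <- pop[prog_idx[j]]
    }
    pairs <- tibble(
      progenitor = acc_ids[prog_idx],
      clone = acc_ids[clone_idx]
    )
  }

  chrom <- sort(rep_len(seq_len(18L), L))
  pos_within <- stats::ave(seq_len(L), chrom, FUN = seq_along)
  loci <- tibble(
    locus = sprintf("S%d_%d", chrom, pos_within * 1000L),
    chrom = sprintf("%02d", chrom),
    pos = pos_within * 1000L,
    ref = "A",
    alt = "T"
  )
  colnames(dos) <- loci$locus
  gm <- geno_matrix(dos, loci)
  attr(gm, "population") <- pop
  attr(gm, "clone_pairs") <- pairs
  gm
}

#' Simulate unbalanced multi-environment trial records
#'
#' Generates phenotypes under the mixed model y = mu + g + b + ge + e, with
#' g ~ N(0, sigma2_g) per accession, b ~ N(0, sigma2_b) per block within
#' environment, ge ~ N(0, sigma2_ge) per accession x environment, and residual
#' e ~ N(0, sigma2_e) per record. Unbalance is induced by enrolling each
#' accession in each environment independently with probability `env_prob`
#' (redrawn for any accession that would otherwise appear nowhere); records
#' are then deleted completely at random at `missing_phenotype_rate`, with the
#' guarantee that every accession keeps at least one record per trait.
#'
#' @param genotypes A [geno_matrix()] supplying accession ids, or a character
#'   vector of accession ids.
#' @param spec A [sim_spec()].
#' @param mu Grand mean per trait (recycled; default 0).
#' @return A list with `records` (tibble: `accession`, `environment`, `trial`,
#'   `block`, `trait`, `value`) and `genetic_values` (tibble: `accession`,
#'   `trait`, `g_true`).
#' @export
simulate_trials <- function(genotypes, spec, mu = 0) {
  stopifnot(inherits(spec, "sim_spec"))
  acc <- if (inherits(genotypes, "geno_matrix")) accessions(genotypes) else genotypes
  set.seed(spec$seed + 1L)
  n <- length(acc)
  traits <- names(spec$variance_components)
  mu <- rep_len(mu, length(traits))
  names(mu) <- traits
  envs <- sprintf("E%02d", seq_len(spec$n_environments))

  # environment enrolment, shared across traits (one field design)
  enrol <- matrix(
    runif(n * spec$n_environments) < spec$env_prob, n, spec$n_environments
  )
  empty <- which(rowSums(enrol) == 0)
  while (length(empty)) {
    enrol[empty, ] <- runif(length(empty) * spec$n_environments) < spec$env_prob
    empty <- which(rowSums(enrol) == 0)
  }

  design <- tidyr::expand_grid(
    acc_i = seq_len(n),
    env_i = seq_len(spec$n_environments),
    block = seq_len(spec$n_blocks_per_env)
  ) |>
    filter(enrol[cbind(.data$acc_i, .data$env_i)])

  records <- list()
  truth <- list()
  clone_pairs <- if (inherits(genotypes, "geno_matrix")) {
    attr(genotypes, "clone_pairs")
  }
  for (tr in traits) {
    vc <- spec$variance_components[[tr]]
    g <- rnorm(n, 0, sqrt(vc[[1]]))
    b <- matrix(
      rnorm(spec$n_environments * spec$n_blocks_per_env, 0, sqrt(vc[[2]])),
      spec$n_environments, spec$n_blocks_per_env
    )
    ge <- matrix(rnorm(n * spec$n_environments, 0, sqrt(vc[[3]])), n, spec$n_environments)
    if (!is.null(clone_pairs) && nrow(clone_pairs)) {
      # a planted duplicate is the same genotype under another name: it shares
      # its progenitor's genetic value and interaction profile exactly
      pi <- match(clone_pairs$progenitor, acc)
      ci <- match(clone_pairs$clone, acc)
      g[ci] <- g[pi]
      ge[ci, ] <- ge[pi, , drop = FALSE]
    }
    e <- rnorm(nrow(design), 0, sqrt(vc[[4]]))
    y <- mu[[tr]] + g[design$acc_i] + b[cbind(design$env_i, design$block)] +
      ge[cbind(design$acc_i, design$env_i)] + e
    rec <- tibble(
      accession = acc[design$acc_i],
      environment = envs[design$env_i],
      trial = envs[design$env_i],
      block = sprintf("B%d", design$block),
      trait = tr,
      value = y
    )
    if (spec$missing_phenotype_rate > 0) {
      drop <- runif(nrow(rec)) < spec$missing_phenotype_rate
      # never orphan an accession: keep one record for any fully-dropped one
      lost <- setdiff(acc, rec$accession[!drop])
      if (length(lost)) {
        keep_one <- vapply(
          lost, function(a) which(rec$accession == a)[1], integer(1)
        )
        drop[keep_one] <- FALSE
      }
      rec <- rec[!drop, , drop = FALSE]
    }
    records[[tr]] <- rec
    truth[[tr]] <- tibble(accession = acc, trait = tr, g_true = g)
  }
  list(records = bind_rows(records), genetic_values = bind_rows(truth))
}

#' Simulate repeated qualitative scores across years
#'
#' Each accession carries a latent class drawn from `class_probs`; every year's
#' observation equals the latent class with probability `retain_prob` and is
#' otherwise a uniform draw from the remaining classes. Emulates the minor
#' year-to-year fluctuation of ordinal descriptor scores that the data-mode
#' aggregation step is designed to absorb.
#'
#' @param spec A [sim_spec()] (supplies accession count and seed).
#' @param class_probs Named list mapping trait to a probability vector over its
#'   classes (must sum to 1); class codes are the vector's names, or
#'   `1..k` when unnamed.
#' @param n_years Number of repeated annual observations.
#' @param retain_prob Probability a year's score equals the latent class.
#' @return A list with `scores` (tibble: `accession`, `year`, `trait`,
#'   `class`) and `latent` (tibble: `accession`, `trait`, `class`).
#' @export
simulate_qualitative <- function(spec, class_probs, n_years = 3, retain_prob = 0.9) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed + 2L)
  acc <- sprintf("ACC%04d", seq_len(spec$n_accessions))
  years <- 2020L + seq_len(n_years) - 1L
  scores <- list()
  latent <- list()
  for (tr in names(class_probs)) {
    probs <- class_probs[[tr]]
    if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8) {
      abort(paste0("Class probabilities for '", tr, "' must be a stochastic vector."))
    }
    k <- length(probs)
    classes <- names(probs) %||% as.character(seq_len(k))
    lat <- sample(seq_len(k), spec$n_accessions, replace = TRUE, prob = probs)
    obs <- matrix(rep(lat, n_years), ncol = n_years)
    if (k > 1 && retain_prob < 1) {
      perturb <- matrix(runif(length(obs)) > retain_prob, nrow(obs), n_years)
      if (any(perturb)) {
        cur <- obs[perturb]
        shift <- 1L + floor(runif(length(cur)) * (k - 1L))
        obs[perturb] <- 1L + (cur - 1L + shift) %% k
      }
    }
    scores[[tr]] <- tibble(
      accession = rep(acc, n_years),
      year = rep(years, each = spec$n_accessions),
      trait = tr,
      class = classes[as.vector(obs)]
    )
    latent[[tr]] <- tibble(accession = acc, trait = tr, class = classes[lat])
  }
  list(scores = bind_rows(scores), latent = bind_rows(latent))
}
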