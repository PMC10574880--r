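#' @title EM-REML variance components and BLUPs for multi-environment trials
#'
#' @description
#' The workhorse mixed model is y = mu + Zg + Wb + Ti + e: a grand mean plus
#' random genotype effects g ~ N(0, sigma2_g I), random block-within-
#' environment effects b ~ N(0, sigma2_b I), random genotype-by-environment
#' interaction i ~ N(0, sigma2_ge I), and residual e ~ N(0, sigma2_e I).
#' Variance components are estimated by EM-REML iterating Henderson's
#' mixed-model equations; the interaction (usually the largest factor) is
#' absorbed through its diagonal block so each iteration costs a dense solve
#' only in the small remaining dimension.
#'
#' @name reml
NULL

# Build the model frame for one trait: response, fixed intercept, and the
# random-effect factors actually identifiable from the incidence structure.
build_design <- function(records, trait) {
  need <- c("accession", "environment", "block", "trait", "value")
  stopifnot(all(need %in% names(records)))
  d <- records[records$trait == trait, , drop = FALSE]
  if (!nrow(d)) abort(paste0("No records for trait '", trait, "'."))
  if (any(!is.finite(d$value))) abort("Phenotype values must be finite.")
  if (length(unique(d$accession)) < 2) {
    abort("Need at least two accessions with records.")
  }
  n <- nrow(d)
  g <- factor(d$accession)
  bw <- factor(paste(d$environment, d$block, sep = ":"))
  ge <- factor(paste(d$accession, d$environment, sep = ":"))
  terms <- list(g = g)
  dropped <- character()
  if (nlevels(bw) >= 2 && nlevels(bw) < n) {
    terms$b <- bw
  } else {
    dropped <- c(dropped, "b")
  }
  if (length(unique(d$environment)) >= 2 && nlevels(ge) < n) {
    terms$ge <- ge
  } else {
    dropped <- c(dropped, "ge")
  }
  list(y = d$value, terms = terms, dropped = dropped, data = d)
}

sparse_incidence <- function(f) {
  Matrix::sparseMatrix(
    i = seq_along(f), j = as.integer(f),
    x = 1, dims = c(length(f), nlevels(f)),
    dimnames = list(NULL, levels(f))
  )
}

# One pass through Henderson's equations with the largest random factor
# absorbed. Returns solutions, block traces of the inverse coefficient
# matrix, and log|M| for the REML log-likelihood.
mme_pass <- function(y, Zs, lambdas, absorb = NULL) {
  n <- length(y)
  k <- length(Zs)
  if (is.null(absorb)) {
    sizes <- vapply(Zs, ncol, integer(1))
    absorb <- if (max(sizes) > 50) which.max(sizes) else 0L
  }
  X <- Matrix::Matrix(1, n, 1)
  small_idx <- if (absorb > 0) setdiff(seq_len(k), absorb) else seq_len(k)
  W <- do.call(cbind, c(list(X), Zs[small_idx]))
  q_small <- vapply(Zs[small_idx], ncol, integer(1))
  pen <- c(0, rep(lambdas[small_idx], q_small))
  A <- as.matrix(Matrix::crossprod(W)) + diag(pen, length(pen))
  rhs_w <- as.vector(Matrix::crossprod(W, y))

  if (absorb > 0) {
    Za <- Zs[[absorb]]
    d <- as.vector(Matrix::colSums(Za)) + lambdas[absorb]
    B <- as.matrix(Matrix::crossprod(W, Za))
    rhs_a <- as.vector(Matrix::crossprod(Za, y))
    Bd <- sweep(B, 2, d, "/")
    S <- A - tcrossprod(Bd, B)
    Sinv <- chol2inv(chol(S))
    s_w <- as.vector(Sinv %*% (rhs_w - Bd %*% rhs_a))
    s_a <- (rhs_a - as.vector(crossprod(B, s_w))) / d
    diag_small <- diag(Sinv)
    tr_absorb <- sum(1 / d) + sum(Bd * (Sinv %*% Bd))
    logdet <- sum(log(d)) + as.numeric(determinant(S, logarithm = TRUE)$modulus)
    rhs_full_dot <- sum(s_w * rhs_w) + sum(s_a * rhs_a)
  } else {
    Sinv <- chol2inv(chol(A))
    s_w <- as.vector(Sinv %*% rhs_w)
    s_a <- numeric(0)
    diag_small <- diag(Sinv)
    tr_absorb <- NA_real_
    logdet <- as.numeric(determinant(A, logarithm = TRUE)$modulus)
    rhs_full_dot <- sum(s_w * rhs_w)
  }

  # unpack per-term solutions and traces
  sol <- vector("list", k)
  trC <- numeric(k)
  off <- 1L
  for (j in small_idx) {
    qj <- ncol(Zs[[j]])
    sol[[j]] <- s_w[off + seq_len(qj)]
    trC[j] <- sum(diag_small[off + seq_len(qj)])
    off <- off + qj
  }
  if (absorb > 0) {
    sol[[absorb]] <- s_a
    trC[absorb] <- tr_absorb
  }
  list(
    beta = s_w[1], sol = sol, trC = trC, logdet = logdet,
    quad = sum(y^2) - rhs_full_dot
  )
}

#' Estimate variance components by EM-REML
#'
#' Fits the multi-environment mixed model for one trait and returns REML
#' estimates of (sigma2_g, sigma2_b, sigma2_ge, sigma2_e) obtained by EM
#' iterations on Henderson's mixed-model equations. Components whose factor is
#' degenerate in the data (a single block level, a single environment, or an
#' incidence confounded with the residual) are dropped with a warning and
#' reported as 0. Estimates are clamped at a floor of 1e-8; convergence is
#' declared when the change in -2 log restricted likelihood falls below `tol`.
#'
#' @param records Trial records tibble: `accession`, `environment`, `block`,
#'   `trait`, `value`.
#' @param trait Trait name to fit.
#' @param max_iter Iteration cap (default 200).
#' @param tol Convergence tolerance on the -2 log-likelihood change.
#' @param floor Lower clamp for variance estimates.
#' @return An object of class `variance_components`: named `sigma2` vector
#'   (`g`, `b`, `ge`, `e`), `converged`, `n_iter`, `minus2loglik` trace,
#'   `dropped` component names, `n_obs`.
#' @export
fit_reml <- function(records, trait, max_iter = 200, tol = 1e-6, floor = 1e-8) {
  des <- build_design(records, trait)
  y <- des$y
  n <- length(y)
  terms <- des$terms
  if (length(des$dropped)) {
    warn(paste0(
      "Trait '", trait, "': dropping degenerate component(s): ",
      paste(des$dropped, collapse = ", ")
    ))
  }
  Zs <- map(terms, sparse_incidence)
  k <- length(Zs)
  qk <- vapply(Zs, ncol, integer(1))
  vy <- var(y)
  if (!is.finite(vy) || vy <= 0) {
    # zero-variance data: every component at the floor
    sigma2 <- setNames(rep(floor, 4), c("g", "b", "ge", "e"))
    sigma2[setdiff(c("g", "b", "ge"), names(terms))] <- 0
    return(structure(
      list(trait = trait, sigma2 = sigma2, converged = TRUE, n_iter = 0L,
           minus2loglik = numeric(0), dropped = des$dropped, n_obs = n),
      class = "variance_components"
    ))
  }
  s2 <- rep(vy / (k + 1), k + 1) # random components then residual
  m2l_trace <- numeric(0)
  m2l_old <- Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    lambdas <- s2[k + 1] / s2[seq_len(k)]
    pass <- mme_pass(y, Zs, lambdas)
    s2e <- s2[k + 1]
    # -2 log restricted likelihood (up to an additive constant)
    m2l <- (n - 1 - sum(qk)) * log(s2e) + sum(qk * log(s2[seq_len(k)])) +
      pass$logdet + pass$quad / s2e
    m2l_trace <- c(m2l_trace, m2l)
    new_e <- pass$quad / (n - 1)
    new_r <- vapply(seq_len(k), function(j) {
      (sum(pass$sol[[j]]^2) + s2e * pass$trC[j]) / qk[j]
    }, numeric(1))
    s2 <- pmax(c(new_r, new_e), floor)
    if (abs(m2l_old - m2l) < tol) {
      converged <- TRUE
      break
    }
    m2l_old <- m2l
  }
  sigma2 <- setNames(rep(0, 4), c("g", "b", "ge", "e"))
  sigma2[names(terms)] <- s2[seq_len(k)]
  sigma2["e"] <- s2[k + 1]
  structure(
    list(trait = trait, sigma2 = sigma2, converged = converged,
         n_iter = iter, minus2loglik = m2l_trace, dropped = des$dropped,
         n_obs = n),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat("<variance_components> trait:", x$trait, "\n")
  print(round(x$sigma2, 6))
  cat(
    "converged:", x$converged, "after", x$n_iter, "iterations",
    if (length(x$dropped)) paste0(" (dropped: ", paste(x$dropped, collapse = ","), ")"),
    "\n"
  )
  invisible(x)
}

#' Predict genotypic BLUPs at given variance components
#'
#' Solves Henderson's mixed-model equations at the supplied variance
#' components and returns the grand mean and the shrunken genotype effects.
#' Components with zero (or floored) variance are omitted from the equations.
#' Accessions without records for the trait are absent from the result. An
#' ill-conditioned coefficient matrix falls back to a pseudo-inverse with the
#' condition number attached as attribute `condition_number`.
#'
#' @param records Trial records tibble.
#' @param vc A [fit_reml()] result (or a list with a named `sigma2` vector).
#' @param trait Trait name.
#' @return Tibble (`accession`, `trait`, `g_hat`) with attribute `mu_hat`.
#' @export
predict_blups <- function(records, vc, trait) {
  des <- build_design(records, trait)
  sigma2 <- vc$sigma2
  stopifnot(all(is.finite(sigma2)), sigma2["e"] > 0)
  active <- names(des$terms)[sigma2[names(des$terms)] > 1e-7]
  if (!("g" %in% active)) active <- union("g", active) # always predict g
  terms <- des$terms[active]
  Zs <- map(terms, sparse_incidence)
  lambdas <- sigma2["e"] / pmax(sigma2[active], 1e-12)
  pass <- tryCatch(
    mme_pass(des$y, Zs, lambdas),
    error = function(e) NULL
  )
  cond <- NA_real_
  if (is.null(pass)) {
    # dense pseudo-inverse fallback
    W <- do.call(cbind, c(list(Matrix::Matrix(1, length(des$y), 1)),
                          map(terms, sparse_incidence)))
    qs <- vapply(Zs, ncol, integer(1))
    M <- as.matrix(Matrix::crossprod(W)) + diag(c(0, rep(lambdas, qs)))
    cond <- kappa(M)
    warn(sprintf("Ill-conditioned mixed-model equations (kappa = %.3g); using pseudo-inverse.", cond))
    s <- as.vector(MASS::ginv(M) %*% as.vector(Matrix::crossprod(W, des$y)))
    beta <- s[1]
    g_hat <- s[1 + seq_len(qs[["g"]])]
  } else {
    beta <- pass$beta
    g_hat <- pass$sol[[which(active == "g")]]
  }
  out <- tibble(
    accession = levels(terms$g),
    trait = trait,
    g_hat = g_hat
  )
  attr(out, "mu_hat") <- beta
  attr(out, "condition_number") <- cond
  out
}

#' Broad-sense heritability on an entry-mean basis
#'
#' h2 = sigma2_g / (sigma2_g + sigma2_ge / n_env + sigma2_e / (n_env * n_rep)).
#' An all-zero denominator yields 0.
#'
#' @param vc A [fit_reml()] result (or list with named `sigma2`).
#' @param n_env Number of environments an entry mean averages over.
#' @param n_rep Number of replicates per environment.
#' @return Heritability in `[0, 1]`.
#' @export
heritability <- function(vc, n_env, n_rep) {
  stopifnot(n_env >= 1, n_rep >= 1)
  s <- vc$sigma2
  den <- s[["g"]] + s[["ge"]] / n_env + s[["e"]] / (n_env * n_rep)
  if (den <= 0) return(0)
  unname(s[["g"]] / den)
}

#' Fit REML/BLUP for every (or selected) trait
#'
#' Convenience wrapper running [fit_reml()], [predict_blups()] and
#' [heritability()] per trait. Entry-mean h2 uses the average number of
#' environments per accession and the average number of records per
#' accession-environment cell observed in the data.
#'
#' @param records Trial records tibble.
#' @param traits Traits to fit (default: all in `records`).
#' @param ... Passed to [fit_reml()].
#' @return An object of class `blup_fit` with elements `blups` (tibble:
#'   `accession`, `trait`, `g_hat`), `vc` (list of `variance_components`),
#'   `mu` and `h2` (named per trait).
#' @export
fit_blup <- function(records, traits = NULL, ...) {
  traits <- traits %||% unique(records$trait)
  vc <- list()
  mu <- h2 <- setNames(numeric(length(traits)), traits)
  blups <- list()
  for (tr in traits) {
    vc[[tr]] <- fit_reml(records, tr, ...)
    tab <- predict_blups(records, vc[[tr]], tr)
    mu[tr] <- attr(tab, "mu_hat")
    d <- records[records$trait == tr, ]
    n_env <- mean(tapply(d$environment, d$accession, function(x) length(unique(x))))
    n_rep <- nrow(d) / nrow(unique(d[, c("accession", "environment")]))
    h2[tr] <- heritability(vc[[tr]], max(n_env, 1), max(n_rep, 1))
    blups[[tr]] <- tab
  }
  structure(
    list(blups = bind_rows(blups), vc = vc, mu = mu, h2 = h2),
    class = "blup_fit"
  )
}

#' @export
print.blup_fit <- function(x, ...) {
  cat("<blup_fit>", length(x$vc), "trait(s),",
      length(unique(x$blups$accession)), "accessions\n")
  print(glance(x))
  invisible(x)
}

#' Tidy per-accession BLUPs
#' @param x A `blup_fit`.
#' @param ... Unused.
#' @return Tibble (`trait`, `accession`, `g_hat`).
#' @method tidy blup_fit
#' @export
tidy.blup_fit <- function(x, ...) {
  x$blups |> select("trait", "accession", "g_hat") |> arrange(.data$trait, .data$accession)
}

#' One-row-per-trait model summary
#' @param x A `blup_fit`.
#' @param ... Unused.
#' @return Tibble with variance components, heritability and convergence info.
#' @method glance blup_fit
#' @export
glance.blup_fit <- function(x, ...) {
  bind_rows(map(names(x$vc), function(tr) {
    v <- x$vc[[tr]]
    tibble(
      trait = tr,
      mu_hat = unname(x$mu[tr]),
      sigma2_g = v$sigma2[["g"]], sigma2_b = v$sigma2[["b"]],
      sigma2_ge = v$sigma2[["ge"]], sigma2_e = v$sigma2[["e"]],
      h2 = unname(x$h2[tr]),
      converged = v$converged, n_iter = v$n_iter, n_obs = v$n_obs
    )
  }))
}
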