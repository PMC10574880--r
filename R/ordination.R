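#' Principal component analysis with a deterministic sign convention
#'
#' Eigen-decomposition of the covariance (or correlation, when `scale = TRUE`)
#' structure of a samples x features matrix. Zero-variance features are
#' dropped when scaling. Each component's sign is fixed so that its
#' largest-magnitude loading is positive, making scores reproducible across
#' platforms.
#'
#' @param x Numeric matrix or data frame, samples in rows; no missing values
#'   (mean-impute genotypes first).
#' @param center,scale Centering/scaling flags (defaults `TRUE`/`FALSE`).
#' @return A `pca_ordination`: list with `scores`, `loadings`,
#'   `explained` (variance fractions), `sdev`.
#' @export
pca_ordination <- function(x, center = TRUE, scale = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("PCA needs at least two samples.")
  if (anyNA(x)) abort("PCA input must be complete; impute missing values first.")
  if (scale) {
    v <- apply(x, 2, var)
    if (any(v == 0)) x <- x[, v > 0, drop = FALSE]
  }
  p <- prcomp(x, center = center, scale. = scale)
  flip <- apply(p$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  p$rotation <- sweep(p$rotation, 2, flip, "*")
  p$x <- sweep(p$x, 2, flip, "*")
  structure(
    list(
      scores = p$x, loadings = p$rotation,
      explained = p$sdev^2 / sum(p$sdev^2), sdev = p$sdev,
      center = p$center, scale = p$scale
    ),
    class = "pca_ordination"
  )
}

#' @export
print.pca_ordination <- function(x, ...) {
  cat("<pca_ordination>", nrow(x$scores), "samples,", ncol(x$scores),
      "components; PC1-PC2 explain",
      sprintf("%.1f%% + %.1f%%", 100 * x$explained[1],
              100 * (x$explained[2] %||% 0)), "\n")
  invisible(x)
}

#' Tidy PCA scores
#' @param x A `pca_ordination`.
#' @param ... Unused.
#' @return Tibble (`sample`, `component`, `score`, `explained`).
#' @method tidy pca_ordination
#' @export
tidy.pca_ordination <- function(x, ...) {
  s <- x$scores
  tibble(
    sample = rep(rownames(s) %||% as.character(seq_len(nrow(s))), ncol(s)),
    component = rep(colnames(s), each = nrow(s)),
    score = as.vector(s),
    explained = rep(x$explained, each = nrow(s))
  )
}

#' Discriminant analysis of principal components (DAPC)
#'
#' PCA dimension reduction followed by a linear discriminant on the retained
#' scores, with collections as a-priori groups: the minimal number of leading
#' PCs whose cumulative explained variance reaches `variance_fraction`
#' (default 0.80) is retained — capped at `n - g - 1` to guard against
#' overfitting — and group separation is modelled with `MASS::lda`.
#'
#' @param x Samples x features matrix (complete; mean-impute first).
#' @param groups A-priori group labels (>= 2 groups, each with >= 2 members).
#' @param variance_fraction Cumulative variance to retain in the PCA step.
#' @param center,scale Passed to the PCA step.
#' @return A `dapc_fit`: retained PC count, discriminant axis count,
#'   `scores` (discriminant coordinates), `assignment` tibble (`sample`,
#'   `prior_group`, `posterior_group`, `posterior_prob`), per-group
#'   `accuracy`, overall `reassignment_accuracy`, and the underlying
#'   `pca`/`lda` objects.
#' @export
dapc_fit <- function(x, groups, variance_fraction = 0.80,
                     center = TRUE, scale = FALSE) {
  x <- as.matrix(x)
  groups <- factor(groups)
  if (nlevels(groups) < 2) abort("DAPC needs at least two groups.")
  if (any(table(groups) < 2)) abort("Every group needs at least two members.")
  if (variance_fraction <= 0 || variance_fraction > 1) {
    abort("`variance_fraction` must lie in (0, 1].")
  }
  pca <- pca_ordination(x, center = center, scale = scale)
  cum <- cumsum(pca$explained)
  n_pc <- which(cum >= variance_fraction)[1]
  if (is.na(n_pc)) n_pc <- length(cum)
  max_pc <- nrow(x) - nlevels(groups) - 1L
  if (n_pc > max_pc) {
    warn(sprintf("Retained PCs reduced from %d to %d to avoid overfitting.",
                 n_pc, max_pc))
    n_pc <- max(1L, max_pc)
  }
  keep <- pca$scores[, seq_len(n_pc), drop = FALSE]
  fit <- MASS::lda(keep, grouping = groups)
  pred <- predict(fit, keep)
  assignment <- tibble(
    sample = rownames(x) %||% as.character(seq_len(nrow(x))),
    prior_group = as.character(groups),
    posterior_group = as.character(pred$class),
    posterior_prob = apply(pred$posterior, 1, max)
  )
  acc_by_group <- assignment |>
    group_by(.data$prior_group) |>
    summarise(
      accuracy = mean(.data$posterior_group == .data$prior_group),
      n = n(), .groups = "drop"
    )
  structure(
    list(
      n_pc = n_pc, n_axes = min(nlevels(groups) - 1L, n_pc),
      scores = pred$x, assignment = assignment,
      accuracy = acc_by_group,
      reassignment_accuracy = mean(
        assignment$posterior_group == assignment$prior_group
      ),
      explained = pca$explained, pca = pca, lda = fit
    ),
    class = "dapc_fit"
  )
}

#' @export
print.dapc_fit <- function(x, ...) {
  cat("<dapc_fit>", x$n_pc, "retained PCs,", x$n_axes,
      "discriminant axes; reassignment accuracy",
      sprintf("%.1f%%", 100 * x$reassignment_accuracy), "\n")
  invisible(x)
}

#' Tidy DAPC assignments
#' @param x A `dapc_fit`.
#' @param ... Unused.
#' @method tidy dapc_fit
#' @export
tidy.dapc_fit <- function(x, ...) x$assignment

#' One-row DAPC summary
#' @param x A `dapc_fit`.
#' @param ... Unused.
#' @method glance dapc_fit
#' @export
glance.dapc_fit <- function(x, ...) {
  tibble(
    n_pc = x$n_pc, n_axes = x$n_axes,
    reassignment_accuracy = x$reassignment_accuracy,
    variance_retained = sum(x$explained[seq_len(x$n_pc)])
  )
}

#' Permutation null for DAPC reassignment accuracy
#'
#' Refits the DAPC under `n_perm` random permutations of the group labels and
#' returns the permutation p-value for the observed reassignment accuracy
#' (with the add-one correction), together with the null accuracies.
#'
#' @param x Samples x features matrix.
#' @param groups A-priori labels.
#' @param n_perm Number of permutations (default 199).
#' @param variance_fraction Passed to [dapc_fit()].
#' @param seed Seed for the permutations.
#' @return List with `observed`, `null` (vector), `p_value`.
#' @export
dapc_permutation_test <- function(x, groups, n_perm = 199,
                                  variance_fraction = 0.80, seed = 1L) {
  obs <- dapc_fit(x, groups, variance_fraction)$reassignment_accuracy
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    dapc_fit(x, sample(groups), variance_fraction)$reassignment_accuracy
  }, numeric(1))
  list(
    observed = obs,
    null = null,
    p_value = (1 + sum(null >= obs)) / (n_perm + 1)
  )
}

#' @describeIn pca_ordination Scatter plot of two score components.
#' @param object A `pca_ordination`.
#' @param components Two component indices to plot.
#' @param groups Optional labels to colour samples by.
#' @param ... Unused.
#' @method autoplot pca_ordination
#' @export
autoplot.pca_ordination <- function(object, components = c(1, 2),
                                    groups = NULL, ...) {
  s <- object$scores[, components, drop = FALSE]
  df <- tibble(
    x = s[, 1], y = s[, 2],
    group = if (is.null(groups)) "all" else as.character(groups)
  )
  labs <- sprintf("PC%d (%.1f%%)", components, 100 * object$explained[components])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = labs[1], y = labs[2], colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn dapc_fit Scatter plot of the first two discriminant axes
#'   (density plot when only one axis exists).
#' @param object A `dapc_fit`.
#' @param ... Unused.
#' @method autoplot dapc_fit
#' @export
autoplot.dapc_fit <- function(object, ...) {
  s <- object$scores
  grp <- object$assignment$prior_group
  if (ncol(s) >= 2) {
    df <- tibble(x = s[, 1], y = s[, 2], group = grp)
    ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$group)) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::labs(x = "LD1", y = "LD2", colour = NULL) +
      ggplot2::theme_minimal()
  } else {
    df <- tibble(x = s[, 1], group = grp)
    ggplot2::ggplot(df, ggplot2::aes(.data$x, fill = .data$group)) +
      ggplot2::geom_density(alpha = 0.5) +
      ggplot2::labs(x = "LD1", fill = NULL) +
      ggplot2::theme_minimal()
  }
}
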