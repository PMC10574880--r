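#' Rank accessions for a thematic collection
#'
#' Per theme trait, accessions are ranked on their BLUPs — ascending when the
#' favourable direction is `"lower"`, descending when `"higher"` — and the
#' composite score is the (weighted) mean of per-trait ranks over the traits
#' where the accession has a BLUP. Accessions covering fewer than
#' `min_coverage` of the theme's traits are excluded with a reason. Ties in
#' the composite score are broken by accession id so runs are reproducible.
#'
#' @param blups Tibble (`accession`, `trait`, `g_hat`), e.g. `tidy(fit_blup(...))`.
#' @param theme A [theme_config()].
#' @param min_coverage Minimum fraction of theme traits an accession must have
#'   BLUPs for (default 0.5).
#' @return Tibble (`accession`, `composite_score`, `rank`, `n_traits`) sorted
#'   best-first, with attribute `excluded` (tibble `accession`, `reason`).
#' @export
rank_candidates <- function(blups, theme, min_coverage = 0.5) {
  stopifnot(inherits(theme, "theme"))
  traits <- names(theme$directions)
  usable <- intersect(traits, unique(blups$trait))
  if (!length(usable)) {
    abort(paste0("Theme '", theme$name, "' has no usable traits in the BLUP table."))
  }
  per_trait <- blups |>
    filter(.data$trait %in% usable) |>
    group_by(.data$trait) |>
    mutate(
      trait_rank = if (theme$directions[[.data$trait[1]]] == "lower") {
        rank(.data$g_hat, ties.method = "average")
      } else {
        rank(-.data$g_hat, ties.method = "average")
      },
      weight = theme$weights[[.data$trait[1]]]
    ) |>
    ungroup()
  scores <- per_trait |>
    group_by(.data$accession) |>
    summarise(
      composite_score = sum(.data$trait_rank * .data$weight) / sum(.data$weight),
      n_traits = n(),
      .groups = "drop"
    )
  low_cov <- scores$n_traits < min_coverage * length(usable)
  excluded <- tibble(
    accession = scores$accession[low_cov],
    reason = sprintf(
      "BLUP coverage %d/%d below %.0f%%",
      scores$n_traits[low_cov], length(usable), 100 * min_coverage
    )
  )
  out <- scores[!low_cov, , drop = FALSE] |>
    arrange(.data$composite_score, .data$accession) |>
    mutate(rank = row_number()) |>
    select("accession", "composite_score", "rank", "n_traits")
  attr(out, "excluded") <- excluded
  out
}

#' Apply hard eligibility filters to a ranked candidate list
#'
#' Removes candidates violating any of the theme's hard filters (for example
#' an ordinal cyanogenic-potential score that must stay below 5, or a pulp
#' colour that must fall in an allowed class set). Quantitative comparators
#' (`<`, `<=`, `>`, `>=`) are evaluated on numeric trait values; `"in"` keeps
#' accessions whose class is in the allowed set. An accession with no value
#' for a filtered trait fails that filter (it cannot demonstrate eligibility).
#'
#' @param candidates Ranked tibble from [rank_candidates()].
#' @param filters Filter list from a [theme_config()].
#' @param trait_table Long tibble (`accession`, `trait`, `value`) holding the
#'   trait values the filters refer to (modal qualitative classes and/or
#'   quantitative summaries); `value` may be numeric or character.
#' @return The filtered tibble (ranks recomputed), with attribute `removed`
#'   (tibble `accession`, `reason`).
#' @export
apply_eligibility <- function(candidates, filters, trait_table = NULL) {
  if (!length(filters)) {
    attr(candidates, "removed") <- tibble(accession = character(), reason = character())
    return(candidates)
  }
  stopifnot(!is.null(trait_table),
            all(c("accession", "trait", "value") %in% names(trait_table)))
  removed <- list()
  keep <- candidates$accession
  for (f in filters) {
    if (!(f$trait %in% trait_table$trait)) {
      abort(paste0("Eligibility filter references absent trait: ", f$trait))
    }
    tt <- trait_table[trait_table$trait == f$trait, ]
    vals <- setNames(tt$value, tt$accession)
    v <- vals[keep]
    ok <- switch(f$op,
      "<" = as.numeric(v) < f$value,
      "<=" = as.numeric(v) <= f$value,
      ">" = as.numeric(v) > f$value,
      ">=" = as.numeric(v) >= f$value,
      "in" = as.character(v) %in% as.character(f$value)
    )
    ok[is.na(ok)] <- FALSE
    if (any(!ok)) {
      removed[[length(removed) + 1L]] <- tibble(
        accession = keep[!ok],
        reason = sprintf(
          "%s %s %s violated", f$trait, f$op, paste(f$value, collapse = ",")
        )
      )
    }
    keep <- keep[ok]
  }
  out <- candidates |>
    filter(.data$accession %in% keep) |>
    arrange(.data$composite_score, .data$accession) |>
    mutate(rank = row_number())
  attr(out, "removed") <- bind_rows(removed) %||%
    tibble(accession = character(), reason = character())
  out
}

#' Truncate a ranked list into a thematic collection
#'
#' Keeps the top `n_target` candidates by composite score. If fewer remain,
#' all are taken with a warning.
#'
#' @param filtered Ranked tibble (from [rank_candidates()] or
#'   [apply_eligibility()]).
#' @param n_target Target collection size.
#' @param name Collection name.
#' @return A `thematic_collection`: tibble (`collection`, `accession`,
#'   `composite_score`, `rank`, `status`) with attributes `provenance`
#'   (`"initial"`) and `removed` (empty tibble, filled by pruning).
#' @export
truncate_collection <- function(filtered, n_target, name = "collection") {
  stopifnot(n_target >= 1)
  if (nrow(filtered) < n_target) {
    warn(sprintf(
      "Theme '%s': only %d candidates available for target size %d.",
      name, nrow(filtered), n_target
    ))
  }
  members <- head(filtered, n_target) |>
    mutate(collection = name, status = "kept") |>
    select("collection", "accession", "composite_score", "rank", "status")
  structure(
    members,
    provenance = "initial",
    removed = tibble(
      accession = character(), reason = character(),
      partner = character(), ibs = numeric()
    ),
    class = c("thematic_collection", class(members))
  )
}

#' @export
print.thematic_collection <- function(x, ...) {
  cat(
    "<thematic_collection> '", x$collection[1], "' (", attr(x, "provenance"),
    "): ", nrow(x), " members, ", nrow(attr(x, "removed")), " removed\n",
    sep = ""
  )
  NextMethod()
}
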