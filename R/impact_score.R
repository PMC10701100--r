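#' Configuration for the mutation impact score
#'
#' The impact of a degron-mapped missense mutation is a weighted sum of a
#' per-category weight and the mean of three normalized biochemical-change
#' terms (|delta hydropathy| / 9, |delta formal charge| / 2,
#' |delta side-chain volume| / range), clamped to `[0, 1]`:
#'
#' `score = w_category + biochem_weight * mean(hydropathy, charge, volume)`
#'
#' Normalization is by construction — the weights are validated so the
#' maximum attainable raw score is exactly 1 — not by per-batch min-max, so a
#' score does not depend on what else is in the batch. The default weights
#' (`altering_motif` 0.6, `blocking_phospho` 0.6, `blocking_ubiq` 0.6,
#' `substituting_flanking_lysine` 0.4, `rewiring_network` 0.2; biochemical
#' weight 0.4) are this package's defaults for the published weighting
#' scheme, whose exact constants are not public; any user-supplied
#' configuration is validated under the same constraint.
#'
#' @param category_weights Named numeric vector over the five categories,
#'   each in `[0, 1]`.
#' @param biochem_weight Weight of the biochemical-change term, in `[0, 1]`;
#'   `max(category_weights) + biochem_weight` must equal 1.
#' @return An object of class `impact_config`.
#' @export
impact_config <- function(category_weights = c(altering_motif = 0.6,
                                               blocking_phospho = 0.6,
                                               blocking_ubiq = 0.6,
                                               substituting_flanking_lysine = 0.4,
                                               rewiring_network = 0.2),
                          biochem_weight = 0.4) {
  if (!setequal(names(category_weights), MUTATION_CATEGORIES))
    abort("category_weights must be named by the five categories: %s",
          paste(MUTATION_CATEGORIES, collapse = ", "))
  if (any(category_weights < 0 | category_weights > 1) ||
      biochem_weight < 0 || biochem_weight > 1)
    abort("all weights must lie in [0, 1]")
  if (abs(max(category_weights) + biochem_weight - 1) > 1e-9)
    abort("max(category_weights) + biochem_weight must equal 1 (got %.3f) so the maximum attainable score is 1",
          max(category_weights) + biochem_weight)
  structure(list(category_weights = category_weights,
                 biochem_weight = biochem_weight,
                 hydropathy_range = 9.0, charge_range = 2.0,
                 volume_range = diff(range(AA_VOLUME))),
            class = "impact_config")
}

#' Score the impact of degron-mapped mutations
#'
#' One score per annotation, in `[0, 1]`; a mutation is *actionable* when its
#' score strictly exceeds 0.5 (predicted to directly disrupt degron-mediated
#' degradation).
#'
#' @param annotations Output of [classify_mutations()] (needs `ref_aa`,
#'   `alt_aa`, `category`).
#' @param config An [impact_config()].
#' @return `annotations` with component columns (`category_term`,
#'   `hydropathy_term`, `charge_term`, `volume_term`), `score`, and
#'   `actionable`; the actionable count is attached as attribute
#'   `"n_actionable"`.
#' @export
score_mutations <- function(annotations, config = impact_config()) {
  stopifnot(inherits(config, "impact_config"))
  if (nrow(annotations)) {
    if (any(annotations$ref_aa == annotations$alt_aa))
      abort("synonymous input (ref_aa == alt_aa): upstream filter failure")
    bad <- !annotations$category %in% MUTATION_CATEGORIES
    if (any(bad))
      abort("unknown category value(s): %s",
            paste(unique(annotations$category[bad]), collapse = ", "))
  }
  ref <- annotations$ref_aa; alt <- annotations$alt_aa
  hyd <- abs(AA_HYDROPATHY[alt] - AA_HYDROPATHY[ref]) / config$hydropathy_range
  chg <- abs(AA_CHARGE[alt] - AA_CHARGE[ref]) / config$charge_range
  vol <- abs(AA_VOLUME[alt] - AA_VOLUME[ref]) / config$volume_range
  cat_term <- unname(config$category_weights[annotations$category])
  score <- cat_term + config$biochem_weight * (hyd + chg + vol) / 3
  score <- pmin(1, pmax(0, score))
  annotations$category_term <- cat_term
  annotations$hydropathy_term <- unname(hyd)
  annotations$charge_term <- unname(chg)
  annotations$volume_term <- unname(vol)
  annotations$score <- unname(score)
  annotations$actionable <- unname(score > 0.5)
  attr(annotations, "n_actionable") <- sum(annotations$actionable)
  annotations
}

#' Summarize impact-score distributions per category
#'
#' @param scored Output of [score_mutations()].
#' @return A `data.frame` with per-category n, median/mean score, and
#'   actionable counts.
#' @export
impact_summary <- function(scored) {
  cats <- MUTATION_CATEGORIES
  do.call(rbind, lapply(cats, function(cc) {
    s <- scored$score[scored$category == cc]
    data.frame(category = cc, n = length(s),
               median_score = if (length(s)) stats::median(s) else NA_real_,
               mean_score = if (length(s)) mean(s) else NA_real_,
               n_actionable = sum(scored$actionable[scored$category == cc]),
               stringsAsFactors = FALSE)
  }))
}
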