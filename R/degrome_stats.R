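#' Two-tailed Mann-Whitney U test
#'
#' Computes the U statistic (number of (x, y) pairs with x > y, counting ties
#' as 1/2) and a two-tailed p-value. For small samples
#' (`n_x + n_y <= exact_limit`, default 12) the exact null distribution is
#' enumerated over all assignments of the combined values to the two groups
#' (ties handled naturally); otherwise a tie-corrected normal approximation
#' with continuity correction is used. The two-tailed exact p-value is the
#' probability of a U at least as far from its null mean `n_x n_y / 2` as
#' observed.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param exact_limit Combined sample size up to which the exact branch is
#'   used.
#' @return `list(u = ..., p = ..., method = "exact"|"normal")`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # exact two-tailed p = 1/3
mann_whitney_u <- function(x, y, exact_limit = 12L) {
  if (!length(x) || !length(y)) abort("both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  u_of <- function(ix, r) sum(r[ix]) - nx * (nx + 1) / 2
  r_all <- rank(c(x, y))
  u_obs <- u_of(seq_len(nx), r_all)
  e_u <- nx * ny / 2

  if (nx + ny <= exact_limit) {
    splits <- utils::combn(nx + ny, nx)
    u_null <- apply(splits, 2, u_of, r = r_all)
    p <- mean(abs(u_null - e_u) >= abs(u_obs - e_u) - 1e-9)
    return(list(u = u_obs, p = p, method = "exact"))
  }
  n <- nx + ny
  ties <- table(c(x, y))
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(u = u_obs, p = 1, method = "normal"))
  z <- (abs(u_obs - e_u) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-max(0, z)))
  list(u = u_obs, p = p, method = "normal")
}

#' Compare degron and background feature distributions
#'
#' One two-tailed Mann-Whitney comparison per feature — the degron vs
#' length-matched background battery (conservation, disorder, accessibility,
#' PTM counts, ...). Direction is reported through the two medians. Raw
#' p-values are the primary output; a Benjamini-Hochberg column is appended
#' as an additive extra and never alters the per-feature p.
#'
#' @param degron_features,background_features Feature tables (e.g. from
#'   [aggregate_features()]); both non-empty.
#' @param features Character vector of feature columns to compare.
#' @param exact_limit Passed to [mann_whitney_u()].
#' @return A `data.frame`: `feature_name`, `n_degron`, `n_background`,
#'   `median_degron`, `median_background`, `u_statistic`, `p_two_tailed`,
#'   `p_bh`.
#' @export
compare_feature_sets <- function(degron_features, background_features,
                                 features = c("disorder", "accessibility",
                                              "conservation_flank_delta",
                                              "n_phospho", "n_ubiq"),
                                 exact_limit = 12L) {
  if (!nrow(degron_features) || !nrow(background_features))
    abort("both feature sets must be non-empty")
  missing <- setdiff(features, intersect(names(degron_features),
                                         names(background_features)))
  if (length(missing))
    abort("feature(s) missing from one of the sets: %s",
          paste(missing, collapse = ", "))
  rows <- lapply(features, function(f) {
    x <- degron_features[[f]]; y <- background_features[[f]]
    mw <- mann_whitney_u(x, y, exact_limit)
    data.frame(feature_name = f, n_degron = length(x),
               n_background = length(y),
               median_degron = stats::median(x),
               median_background = stats::median(y),
               u_statistic = mw$u, p_two_tailed = mw$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_bh <- stats::p.adjust(res$p_two_tailed, method = "BH")
  res
}
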