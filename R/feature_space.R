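#' Aggregate per-residue tracks into candidate feature vectors
#'
#' For each candidate span the per-residue annotation tracks are averaged
#' over the span, and window-based features are added: the conservation
#' contrast between the span and its flanks
#' (`conservation_flank_delta = mean(span) - mean(flanks)`; positive means
#' the candidate is more conserved than its neighborhood), PTM counts within
#' the span extended by `flank` residues on both sides (clipped at the
#' termini), and the flanking-lysine distribution (count, distance in
#' residues from the span to the nearest flank lysine — 0 with
#' `flank_lysine_present = 0` when there is none).
#'
#' Proteins absent from `tracks` have their track-derived features imputed as
#' the proteome-wide mean of that feature, and the row is flagged
#' `imputed = TRUE` so downstream models can exclude it.
#'
#' @param candidates `data.frame` with columns `protein_id`, `start`, `end`
#'   (1-based inclusive) and optionally `motif_name`.
#' @param proteome Proteome `data.frame`.
#' @param tracks Track table from [read_track_table()] (or
#'   [proxy_tracks()]); must contain every registry feature column.
#' @param ptm_sites PTM table from [read_ptm_table()] (may have zero rows).
#' @param flank Flank width in residues (default 11).
#' @return A `data.frame`: candidate reference columns, the aggregated
#'   feature registry columns, and an `imputed` flag.
#' @export
aggregate_features <- function(candidates, proteome, tracks, ptm_sites = NULL,
                               flank = 11L) {
  stopifnot(flank >= 0)
  if (is.null(ptm_sites))
    ptm_sites <- data.frame(protein_id = character(0), position = integer(0),
                            ptm_type = character(0))
  track_feats <- setdiff(TRACK_REGISTRY, "conservation")
  missing_cols <- setdiff(TRACK_REGISTRY, names(tracks))
  if (length(missing_cols))
    abort("tracks lack registry feature(s): %s (see proxy_tracks() for a built-in fallback)",
          paste(missing_cols, collapse = ", "))

  global_means <- vapply(TRACK_REGISTRY, function(f)
    mean(tracks[[f]], na.rm = TRUE), numeric(1))

  n <- nrow(candidates)
  feat <- matrix(NA_real_, n, length(FEATURE_REGISTRY),
                 dimnames = list(NULL, FEATURE_REGISTRY))
  imputed <- logical(n)

  for (i in seq_len(n)) {
    pid <- candidates$protein_id[i]
    start <- candidates$start[i]; end <- candidates$end[i]
    seq <- get_sequence(proteome, pid)
    len <- nchar(seq)
    if (start < 1L || end > len || start > end)
      abort("candidate span [%d, %d] outside protein '%s' (length %d)",
            start, end, pid, len)

    tr <- tracks[tracks$protein_id == pid, , drop = FALSE]
    have_tracks <- nrow(tr) == len
    if (have_tracks) tr <- tr[order(tr$position), , drop = FALSE]
    imputed[i] <- !have_tracks

    span <- start:end
    lflank <- if (start > 1L) max(1L, start - flank):(start - 1L) else integer(0)
    rflank <- if (end < len) (end + 1L):min(len, end + flank) else integer(0)

    for (f in track_feats) {
      feat[i, f] <- if (have_tracks) mean(tr[[f]][span]) else global_means[[f]]
    }
    if (have_tracks) {
      cons <- tr$conservation
      fl <- c(lflank, rflank)
      feat[i, "conservation_flank_delta"] <-
        if (length(fl)) mean(cons[span]) - mean(cons[fl]) else 0
    } else {
      feat[i, "conservation_flank_delta"] <- 0
    }

    win <- max(1L, start - flank):min(len, end + flank)
    ptm <- ptm_sites[ptm_sites$protein_id == pid &
                       ptm_sites$position %in% win, , drop = FALSE]
    feat[i, "n_phospho"] <- sum(ptm$ptm_type == "phosphorylation")
    feat[i, "n_ubiq"] <- sum(ptm$ptm_type == "ubiquitination")

    res <- residues(seq)
    lys <- c(lflank, rflank)[res[c(lflank, rflank)] == "K"]
    feat[i, "flank_lysine_count"] <- length(lys)
    if (length(lys)) {
      dist <- ifelse(lys < start, start - lys, lys - end)
      feat[i, "flank_lysine_min_dist"] <- min(dist)
      feat[i, "flank_lysine_present"] <- 1
    } else {
      feat[i, "flank_lysine_min_dist"] <- 0
      feat[i, "flank_lysine_present"] <- 0
    }
  }

  ref_cols <- intersect(c("protein_id", "motif_name", "start", "end"),
                        names(candidates))
  cbind(candidates[ref_cols], as.data.frame(feat), imputed = imputed)
}

#' Crude built-in per-residue track fallback
#'
#' Generates the full registry of per-residue tracks from sequence alone so
#' the pipeline stays runnable without external structure/conservation
#' predictors. These are clearly labeled proxies, not predictions: disorder
#' and accessibility are window-smoothed inverse Kyte-Doolittle hydropathy
#' rescaled to `[0, 1]`, conservation is flat 0.5, secondary-structure
#' fractions are uniform thirds, rigidity/stabilization are flat 0.5, and
#' `domain_flag` is 0. Real tracks should be supplied whenever available.
#'
#' @param proteome Proteome `data.frame`.
#' @param window Smoothing window (odd integer) for the hydropathy proxy.
#' @return A track table accepted by [aggregate_features()].
#' @export
proxy_tracks <- function(proteome, window = 9L) {
  out <- lapply(seq_len(nrow(proteome)), function(i) {
    seq <- proteome$sequence[i]
    len <- nchar(seq)
    hyd <- AA_HYDROPATHY[residues(seq)]
    hyd[is.na(hyd)] <- 0                       # unknown residue 'X'
    sm <- stats::filter(hyd, rep(1 / window, window), sides = 2)
    sm[is.na(sm)] <- hyd[is.na(sm)]
    dis <- (4.5 - as.numeric(sm)) / 9          # inverse hydropathy in [0,1]
    dis <- pmin(1, pmax(0, dis))
    data.frame(protein_id = proteome$protein_id[i], position = seq_len(len),
               disorder = dis, accessibility = dis, conservation = 0.5,
               coil = 1 / 3, helix = 1 / 3, sheet = 1 / 3,
               rigidity = 0.5, stabilization = 0.5, domain_flag = 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Sample length-matched background peptides
#'
#' For every positive span, draws up to `k_per_positive` peptides of the same
#' length from the same protein, uniformly over all placements that do not
#' overlap any annotated degron span on that protein. When a positive has no
#' valid placement a warning is raised and fewer peptides are returned; an
#' overlap is never emitted.
#'
#' @param proteome Proteome `data.frame`.
#' @param positives `data.frame` with `protein_id`, `start`, `end`: the
#'   annotated degron spans (these define the exclusion zones).
#' @param k_per_positive Background peptides requested per positive.
#' @param seed Integer seed; the draw is reproducible.
#' @return `data.frame` with `protein_id`, `start`, `end`,
#'   `source = "background"`.
#' @export
sample_background <- function(proteome, positives, k_per_positive = 10L,
                              seed = 1L) {
  withr::with_seed(seed, {
    out <- vector("list", nrow(positives))
    for (i in seq_len(nrow(positives))) {
      pid <- positives$protein_id[i]
      len <- positives$end[i] - positives$start[i] + 1L
      plen <- protein_length(proteome, pid)
      spans <- positives[positives$protein_id == pid, c("start", "end"),
                         drop = FALSE]
      starts <- seq_len(max(0L, plen - len + 1L))
      ok <- vapply(starts, function(s) {
        e <- s + len - 1L
        !any(s <= spans$end & e >= spans$start)
      }, logical(1))
      valid <- starts[ok]
      if (!length(valid)) {
        warn("no non-overlapping length-%d placement on protein '%s'; 0 background peptides for positive %d",
             len, pid, i)
        next
      }
      take <- min(k_per_positive, length(valid))
      if (take < k_per_positive)
        warn("only %d of %d background placement(s) available on protein '%s'",
             take, k_per_positive, pid)
      s <- if (length(valid) == 1L) valid else sample(valid, take)
      out[[i]] <- data.frame(protein_id = pid, start = s, end = s + len - 1L,
                             source = "background", stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    if (is.null(res))
      res <- data.frame(protein_id = character(0), start = integer(0),
                        end = integer(0), source = character(0))
    rownames(res) <- NULL
    res
  })
}

#' Unify candidate spans into fixed-length centered fragments
#'
#' Each fragment is centered on the span midpoint (even-length spans round
#' the midpoint toward the N-terminus: `c = floor((start + end) / 2)`) and
#' padded with `X` beyond the protein termini, so all fragments are exactly
#' `length` residues. These aligned fragments feed
#' [position_preferences()] for motif-logo analysis.
#'
#' @param candidates `data.frame` with `protein_id`, `start`, `end`.
#' @param proteome Proteome `data.frame`.
#' @param length Fragment length; must be at least the longest span.
#' @return Character vector of fragments (one per candidate).
#' @export
unify_fragments <- function(candidates, proteome, length = 20L) {
  if (nrow(candidates) == 0L) return(character(0))
  span_len <- candidates$end - candidates$start + 1L
  if (length < max(span_len))
    abort("fragment length %d is below the longest span (%d)",
          length, max(span_len))
  vapply(seq_len(nrow(candidates)), function(i) {
    seq <- get_sequence(proteome, candidates$protein_id[i])
    ctr <- (candidates$start[i] + candidates$end[i]) %/% 2L
    from <- ctr - (length - 1L) %/% 2L
    to <- from + length - 1L
    padded_substring(seq, from, to)
  }, character(1))
}

# Substring with 'X' padding for coordinates beyond [1, nchar(seq)].
padded_substring <- function(seq, from, to) {
  len <- nchar(seq)
  left <- max(0L, 1L - from)
  right <- max(0L, to - len)
  core <- substr(seq, max(1L, from), min(len, to))
  paste0(strrep("X", left), core, strrep("X", right))
}

#' Position-wise amino-acid preferences of aligned fragments
#'
#' Computes the position frequency matrix of a set of equal-length fragments:
#' one row per position, one column per standard residue. Unknown residues
#' (`X`, including terminus padding) carry no mass — frequencies are
#' renormalized over observed residues, so every defined row sums to 1. A
#' position consisting only of `X` is returned as a row of `NA` and listed in
#' the `"undefined_positions"` attribute rather than propagating NaN.
#'
#' @param fragments Character vector of equal-length fragments
#'   (see [unify_fragments()]).
#' @return A numeric matrix (`length x 20`) with attribute
#'   `"undefined_positions"`.
#' @export
position_preferences <- function(fragments) {
  if (!length(fragments)) abort("at least one fragment is required")
  lens <- nchar(fragments)
  if (length(unique(lens)) != 1L)
    abort("fragments must all have the same length")
  L <- lens[1]
  mat <- matrix(0, L, length(AA_ALPHABET),
                dimnames = list(NULL, AA_ALPHABET))
  chars <- do.call(rbind, strsplit(fragments, "", fixed = TRUE))
  undef <- integer(0)
  for (p in seq_len(L)) {
    col <- chars[, p]
    col <- col[col != AA_UNKNOWN]
    if (!length(col)) {
      mat[p, ] <- NA_real_
      undef <- c(undef, p)
    } else {
      tab <- table(factor(col, levels = AA_ALPHABET))
      mat[p, ] <- as.numeric(tab) / length(col)
    }
  }
  attr(mat, "undefined_positions") <- undef
  mat
}
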