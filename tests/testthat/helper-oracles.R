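# Independent oracles used across the suite.  They deliberately take a
# different computational route from the package implementation.

# Brute-force every-offset scanner for fixed-length patterns: position-wise
# residue-set membership, vectorized over starts.  `tokens` come from the
# compiled motif, but matching here never touches the regex path.
oracle_scan_fixed <- function(seq, motif) {
  tokens <- motif$compiled$tokens
  stopifnot(all(vapply(tokens, function(t) t$min == t$max && t$min == 1L,
                       logical(1))))
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  k <- length(tokens)
  n <- length(res)
  if (n < k) return(data.frame(start = integer(0), end = integer(0)))
  starts <- seq_len(n - k + 1L)
  ok <- rep(TRUE, length(starts))
  for (i in seq_len(k)) {
    tok <- tokens[[i]]
    r <- res[starts + i - 1L]
    ok <- ok & if (tok$wildcard) TRUE else r %in% tok$allowed
  }
  data.frame(start = starts[ok], end = starts[ok] + k - 1L)
}

# Greedy recursive matcher supporting bounded repetitions: earlier tokens
# take as many residues as possible, backtracking on failure (the declared
# maximal-per-start semantics).  Returns the matched length at `pos` or NA.
oracle_match_at <- function(tokens, res, pos) {
  rec <- function(ti, p) {
    if (ti > length(tokens)) return(p)
    tok <- tokens[[ti]]
    for (k in tok$max:tok$min) {
      if (p + k - 1L > length(res)) next
      seg <- if (k > 0L) res[p:(p + k - 1L)] else character(0)
      fits <- if (tok$wildcard) TRUE else all(seg %in% tok$allowed)
      if (k == 0L || fits) {
        out <- rec(ti + 1L, p + k)
        if (!is.na(out)) return(out)
      }
    }
    NA_integer_
  }
  endp <- rec(1L, pos)
  if (is.na(endp)) NA_integer_ else endp - pos
}

oracle_scan_general <- function(seq, motif) {
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  hits <- lapply(seq_along(res), function(s) {
    len <- oracle_match_at(motif$compiled$tokens, res, s)
    if (is.na(len) || len == 0L) NULL else c(s, s + len - 1L)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) data.frame(start = integer(0), end = integer(0))
  else data.frame(start = hits[, 1], end = hits[, 2])
}

# Exhaustive two-tailed Mann-Whitney oracle: enumerate every assignment of
# the combined values to group x and count pairwise wins directly.
oracle_mann_whitney_p <- function(x, y) {
  comb <- c(x, y)
  nx <- length(x); ny <- length(y)
  u_pairs <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_pairs(x, y)
  e_u <- nx * ny / 2
  splits <- utils::combn(length(comb), nx)
  u_all <- apply(splits, 2, function(ix)
    u_pairs(comb[ix], comb[-ix]))
  mean(abs(u_all - e_u) >= abs(u_obs - e_u) - 1e-9)
}

# Random protein sequence.
random_sequence <- function(len, with_x = FALSE) {
  alpha <- if (with_x) c(degronr::AA_ALPHABET, "X") else degronr::AA_ALPHABET
  paste0(sample(alpha, len, replace = TRUE), collapse = "")
}

# A tiny proteome + tracks + PTM fixture shared by feature tests.
make_small_fixture <- function(seed = 1L, n = 10L, len = c(60L, 150L),
                               effects = c(disorder = 0.4,
                                           accessibility = 0.4,
                                           conservation = 0.4),
                               noise = 0.1) {
  mots <- example_motifs()
  gp <- generate_proteome(n, len, mots, implant_rate = 1, seed = seed)
  tracks <- generate_tracks(gp$proteome, gp$manifest, effects, noise,
                            seed = seed + 1L)
  ptm <- generate_ptm_sites(gp$proteome, gp$manifest, seed = seed + 2L)
  list(proteome = gp$proteome, manifest = gp$manifest, tracks = tracks,
       ptm = ptm, motifs = mots)
}

# The PARP1-style worked fixture: degron VAATPPPS at [365, 372].
make_parp1_fixture <- function() {
  set.seed(424)
  left <- paste0(sample(degronr::AA_ALPHABET, 364, replace = TRUE),
                 collapse = "")
  right <- paste0(sample(degronr::AA_ALPHABET, 40, replace = TRUE),
                  collapse = "")
  seq <- paste0(left, "VAATPPPS", right)
  substr(seq, 360, 360) <- "K"   # a flank lysine, for the substitution rule
  substr(seq, 375, 375) <- "S"   # a flank serine, for the phospho rule
  proteome <- as_proteome(c(PARP1 = seq))
  degrons <- data.frame(protein_id = "PARP1", start = 365L, end = 372L,
                        motif_name = "CULT_degron",
                        stringsAsFactors = FALSE)
  list(proteome = proteome, degrons = degrons)
}
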