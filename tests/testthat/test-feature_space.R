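make_flat_tracks <- function(proteome, disorder = 0.5) {
  tr <- proxy_tracks(proteome)
  tr$disorder <- disorder
  tr$conservation <- 0.5
  tr
}

test_that("track features average over the span and PTM counts follow the window rule", {
  seq <- paste0(strrep("A", 25))
  prot <- as_proteome(c(P = seq))
  tr <- make_flat_tracks(prot)
  tr$disorder <- c(0.2, 0.4, rep(0.3, 23))   # span [1,2] -> mean 0.3
  cand <- data.frame(protein_id = "P", start = 1L, end = 2L)
  f <- aggregate_features(cand, prot, tr, flank = 11L)
  expect_equal(f$disorder, 0.3)

  # degron [5,8], phospho sites at 3 and 20: window [1,19] excludes site 20
  seq2 <- paste0("MK", "T", "A", "AAAA", strrep("A", 11), "S", strrep("A", 5))
  prot2 <- as_proteome(c(Q = seq2))
  ptm <- data.frame(protein_id = "Q", position = c(3L, 20L),
                    ptm_type = "phosphorylation")
  f2 <- aggregate_features(data.frame(protein_id = "Q", start = 5L, end = 8L),
                           prot2, make_flat_tracks(prot2), ptm, flank = 11L)
  expect_equal(f2$n_phospho, 1)

  # uniform conservation -> zero flank contrast
  expect_equal(f$conservation_flank_delta, 0)
})

test_that("flanking-lysine features report count, nearest distance, and presence", {
  seq <- paste0("MK", strrep("A", 3), "LLLL", strrep("A", 4), "K",
                strrep("A", 10))
  prot <- as_proteome(c(P = seq))
  tr <- make_flat_tracks(prot)
  f <- aggregate_features(data.frame(protein_id = "P", start = 6L, end = 9L),
                          prot, tr, flank = 11L)
  expect_equal(f$flank_lysine_count, 2)      # K at 2 (left) and 14 (right)
  expect_equal(f$flank_lysine_min_dist, 4)   # min(6-2, 14-9)
  expect_equal(f$flank_lysine_present, 1)

  bare <- as_proteome(c(P = paste0(strrep("A", 5), "LLLL", strrep("A", 5))))
  f0 <- aggregate_features(data.frame(protein_id = "P", start = 6L, end = 9L),
                           bare, make_flat_tracks(bare), flank = 11L)
  expect_equal(f0$flank_lysine_count, 0)
  expect_equal(f0$flank_lysine_min_dist, 0)
  expect_equal(f0$flank_lysine_present, 0)
})

test_that("feature aggregation is translation-equivariant", {
  core <- "RAALQQV"
  pad1 <- 10L; pad2 <- 40L
  mk <- function(pad) {
    set.seed(31)
    left <- random_sequence(pad); right <- random_sequence(60L - pad)
    prot <- as_proteome(c(P = paste0(left, core, right)))
    tr <- proxy_tracks(prot)
    # tracks shifted with the span: same local profile around the core
    tr$disorder <- 0.2
    tr$disorder[(pad + 1):(pad + 7)] <- 0.9
    tr$conservation <- tr$disorder
    ptm <- data.frame(protein_id = character(0), position = integer(0),
                      ptm_type = character(0))
    aggregate_features(data.frame(protein_id = "P", start = pad + 1L,
                                  end = pad + 7L), prot, tr, ptm)
  }
  f1 <- mk(pad1); f2 <- mk(pad2)
  for (col in c("disorder", "conservation_flank_delta", "n_phospho"))
    expect_equal(f1[[col]], f2[[col]])
})

test_that("missing per-protein tracks are imputed and flagged", {
  fx <- make_small_fixture(seed = 21, n = 4)
  tracks_partial <- fx$tracks[fx$tracks$protein_id != fx$proteome$protein_id[1], ]
  cand <- fx$manifest$implants[1:2, ]
  f <- aggregate_features(cand, fx$proteome, tracks_partial, fx$ptm)
  expect_true(f$imputed[f$protein_id == fx$proteome$protein_id[1]][1])
  expect_equal(f$disorder[f$imputed][1], mean(tracks_partial$disorder))
})

test_that("background sampling is length-matched, non-overlapping, seeded", {
  # pigeonhole: a 7-mer positive on a 9-residue protein leaves no placement
  prot <- as_proteome(c(P = "MRAALQQVK"))
  pos <- data.frame(protein_id = "P", start = 2L, end = 8L)
  expect_warning(bg0 <- sample_background(prot, pos, 1L, seed = 1),
                 "no non-overlapping")
  expect_equal(nrow(bg0), 0L)

  fx <- make_small_fixture(seed = 23, n = 8)
  imp <- fx$manifest$implants
  bg <- sample_background(fx$proteome, imp, 5L, seed = 7)
  bg2 <- sample_background(fx$proteome, imp, 5L, seed = 7)
  expect_identical(bg, bg2)
  # never overlaps any annotated degron on the same protein
  for (i in seq_len(nrow(bg))) {
    sp <- imp[imp$protein_id == bg$protein_id[i], ]
    expect_false(any(bg$start[i] <= sp$end & bg$end[i] >= sp$start))
  }
  # exact length matching per positive
  expect_equal(sort(unique(bg$end - bg$start)),
               sort(unique(imp$end - imp$start)))
})

test_that("fragment unification centers spans and pads with X", {
  prot <- as_proteome(c(P = paste0(strrep("A", 4), "KENQ", strrep("C", 40))))
  # span [5,8]: midpoint floor((5+8)/2)=6, window [-3,16]; the four
  # positions -3..0 fall before the N-terminus and are X-padded
  fr <- unify_fragments(data.frame(protein_id = "P", start = 5L, end = 8L),
                        prot, length = 20L)
  expect_equal(nchar(fr), 20L)
  expect_equal(substr(fr, 1, 4), "XXXX")
  expect_equal(substr(fr, 5, 12), "AAAAKENQ")

  # a span exactly as long as the fragment is returned unchanged
  long <- as_proteome(c(Q = strrep("W", 20)))
  fr2 <- unify_fragments(data.frame(protein_id = "Q", start = 1L, end = 20L),
                         long, length = 20L)
  expect_equal(fr2, strrep("W", 20))
  expect_error(unify_fragments(data.frame(protein_id = "Q", start = 1L,
                                          end = 20L), long, length = 10L),
               "longest span")
})

test_that("position preferences renormalize over observed residues and flag all-X columns", {
  frs <- rep("XXAKENQXXX", 10)
  pp <- position_preferences(frs)
  expect_equal(dim(pp), c(10L, 20L))
  expect_true(all(is.na(pp[1, ])))
  expect_equal(attr(pp, "undefined_positions"), c(1L, 2L, 8L, 9L, 10L))
  expect_equal(unname(pp[4, "K"]), 1.0)

  two <- c("AKENA", "GKENA")
  pp2 <- position_preferences(two)
  expect_equal(unname(pp2[1, "A"]), 0.5)
  expect_equal(unname(pp2[1, "G"]), 0.5)

  withr::local_seed(3)
  rnd <- vapply(1:25, function(i) random_sequence(12), character(1))
  pp3 <- position_preferences(rnd)
  expect_true(all(abs(rowSums(pp3) - 1) < 1e-9))
})
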