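test_that("degron mapping uses the inclusive ±11 window and in/flank regions", {
  fx <- make_parp1_fixture()
  mk_mut <- function(pos) {
    ref <- substr(fx$proteome$sequence[1], pos, pos)
    alt <- setdiff(c("M", "A"), ref)[1]
    data.frame(protein_id = "PARP1", position = pos, ref_aa = ref,
               alt_aa = alt, sample_id = "S1", source = "toy",
               stringsAsFactors = FALSE)
  }
  hit <- map_to_degrons(mk_mut(368L), fx$degrons)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$region, "in_degron")

  edge <- map_to_degrons(mk_mut(354L), fx$degrons)   # 365 - 11 = 354
  expect_equal(edge$region, "in_flank")

  out <- map_to_degrons(mk_mut(353L), fx$degrons)    # just outside
  expect_equal(nrow(out), 0L)
})

test_that("a mutation hitting several degrons yields one annotation each", {
  prot <- as_proteome(c(P = strrep("A", 60)))
  degrons <- data.frame(protein_id = "P", start = c(10L, 20L),
                        end = c(13L, 23L), motif_name = c("m1", "m2"))
  mut <- data.frame(protein_id = "P", position = 16L, ref_aa = "A",
                    alt_aa = "G", sample_id = "S", source = "t")
  hits <- map_to_degrons(mut, degrons)
  expect_equal(nrow(hits), 2L)
  expect_setequal(hits$motif_name, c("m1", "m2"))
})

test_that("the five classification rules fire in precedence order", {
  fx <- make_parp1_fixture()
  seq <- fx$proteome$sequence[1]
  mut <- function(pos, alt) data.frame(
    protein_id = "PARP1", position = pos,
    ref_aa = substr(seq, pos, pos), alt_aa = alt,
    sample_id = "S", source = "t", stringsAsFactors = FALSE)

  # in-degron, no PTM annotation: altering_motif with the mutant sequence
  ann <- annotate_mutations(mut(368L, "M"), fx$degrons, fx$proteome)
  expect_equal(ann$category, "altering_motif")
  expect_equal(ann$mutant_degron_seq, "VAAMPPPS")

  # flank lysine without ubiquitination annotation
  kpos <- which(strsplit(seq, "")[[1]] == "K")
  kfl <- kpos[kpos >= 354 & kpos < 365][1]
  if (!is.na(kfl)) {
    annk <- annotate_mutations(mut(kfl, "R"), fx$degrons, fx$proteome)
    expect_equal(annk$category, "substituting_flanking_lysine")
    # with the site annotated as ubiquitination the PTM rule wins
    ptm <- data.frame(protein_id = "PARP1", position = kfl,
                      ptm_type = "ubiquitination")
    annu <- annotate_mutations(mut(kfl, "R"), fx$degrons, fx$proteome, ptm)
    expect_equal(annu$category, "blocking_ubiq")
  }

  # flank S/T/Y annotated as phosphosite
  spos <- which(strsplit(seq, "")[[1]] %in% c("S", "T", "Y"))
  sfl <- spos[spos > 372 & spos <= 383][1]
  if (!is.na(sfl)) {
    ptm <- data.frame(protein_id = "PARP1", position = sfl,
                      ptm_type = "phosphorylation")
    anns <- annotate_mutations(mut(sfl, "A"), fx$degrons, fx$proteome, ptm)
    expect_equal(anns$category, "blocking_phospho")
    # same position without the annotation falls through to rewiring
    ann0 <- annotate_mutations(mut(sfl, "A"), fx$degrons, fx$proteome)
    expect_equal(ann0$category, "rewiring_network")
  }
})

test_that("precedence is configurable and classification is pure", {
  fx <- make_parp1_fixture()
  seq <- fx$proteome$sequence[1]
  # an in-degron position that is also an annotated phosphosite: position 368 (T)
  ptm <- data.frame(protein_id = "PARP1", position = 368L,
                    ptm_type = "phosphorylation")
  mut <- data.frame(protein_id = "PARP1", position = 368L, ref_aa = "T",
                    alt_aa = "M", sample_id = "S", source = "t")
  default <- annotate_mutations(mut, fx$degrons, fx$proteome, ptm)
  expect_equal(default$category, "blocking_phospho")

  flipped <- annotate_mutations(mut, fx$degrons, fx$proteome, ptm,
                                precedence = c("altering_motif",
                                               "blocking_phospho",
                                               "blocking_ubiq",
                                               "substituting_flanking_lysine",
                                               "rewiring_network"))
  expect_equal(flipped$category, "altering_motif")

  again <- annotate_mutations(mut, fx$degrons, fx$proteome, ptm)
  expect_identical(default, again)
})

test_that("category counts partition the annotations", {
  expect_equal(unname(category_summary(data.frame(category = character(0)))),
               rep(0L, 5L))

  fx <- make_small_fixture(seed = 13, n = 12)
  want <- c(altering_motif = 4L, blocking_phospho = 2L, blocking_ubiq = 1L,
            substituting_flanking_lysine = 3L, rewiring_network = 5L)
  mu <- generate_mutations(fx$proteome, fx$manifest, want, fx$ptm, seed = 14)
  ann <- annotate_mutations(mu[setdiff(names(mu), "intended_category")],
                            fx$manifest$implants, fx$proteome, fx$ptm)
  cs <- category_summary(ann)
  expect_equal(sum(cs), nrow(ann))
})
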