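test_that("proteome generation is seeded, respects the implant rate, and implants match their motifs", {
  mots <- example_motifs()
  a <- generate_proteome(15, c(60, 120), mots, implant_rate = 1, seed = 5)
  b <- generate_proteome(15, c(60, 120), mots, implant_rate = 1, seed = 5)
  expect_identical(a, b)

  none <- generate_proteome(10, c(60, 120), mots, implant_rate = 0, seed = 5)
  expect_equal(nrow(none$manifest$implants), 0L)

  # every implant is re-found by the scanner at its recorded span
  sc <- scan_proteome(a$proteome, mots)
  imp <- a$manifest$implants
  found <- vapply(seq_len(nrow(imp)), function(i)
    any(sc$protein_id == imp$protein_id[i] & sc$start == imp$start[i] &
          sc$end == imp$end[i] & sc$motif_name == imp$motif_name[i]),
    logical(1))
  expect_true(all(found))

  # implants are internal
  len <- nchar(a$proteome$sequence)[match(imp$protein_id,
                                          a$proteome$protein_id)]
  expect_true(all(imp$start > 1 & imp$end < len))

  expect_error(generate_proteome(5, c(4, 6), mots, 1, seed = 1),
               "could not place")
})

test_that("generated tracks carry the configured effect size and stay in range", {
  fx <- make_small_fixture(seed = 71, n = 10)
  tr <- fx$tracks
  expect_true(all(tr$disorder >= 0 & tr$disorder <= 1))
  expect_true(all(abs(tr$coil + tr$helix + tr$sheet - 1) < 1e-9))

  imp <- fx$manifest$implants
  in_span <- rep(FALSE, nrow(tr))
  for (i in seq_len(nrow(imp))) {
    sel <- tr$protein_id == imp$protein_id[i] &
      tr$position >= imp$start[i] & tr$position <= imp$end[i]
    in_span <- in_span | sel
  }
  expect_gt(mean(tr$disorder[in_span]) - mean(tr$disorder[!in_span]), 0.25)

  # zero effect: no systematic shift
  null <- generate_tracks(fx$proteome, fx$manifest,
                          effect_sizes = c(disorder = 0), noise_sd = 0.1,
                          seed = 72)
  expect_lt(abs(mean(null$disorder[in_span]) - mean(null$disorder[!in_span])),
            0.05)
})

test_that("PTM sites are enriched near degrons and respect residue identity", {
  fx <- make_small_fixture(seed = 81, n = 20)
  # the validator (residue identity, bounds) accepts the generated table
  expect_silent(v <- degronr:::validate_ptm_sites(fx$ptm, fx$proteome))
  expect_equal(nrow(v), nrow(fx$ptm))
})

test_that("engineered mutations recover their intended category exactly", {
  fx <- make_small_fixture(seed = 91, n = 15)
  want <- c(altering_motif = 5L, substituting_flanking_lysine = 3L,
            rewiring_network = 4L, blocking_phospho = 2L, blocking_ubiq = 1L)
  mu <- generate_mutations(fx$proteome, fx$manifest, want, fx$ptm, seed = 92)
  expect_equal(as.integer(table(mu$intended_category)[names(sort(want))]),
               unname(sort(want)))

  ann <- annotate_mutations(mu[setdiff(names(mu), "intended_category")],
                            fx$manifest$implants, fx$proteome, fx$ptm)
  key <- paste(ann$protein_id, ann$position, ann$sample_id)
  intended <- mu$intended_category[match(key, paste(mu$protein_id,
                                                    mu$position,
                                                    mu$sample_id))]
  expect_equal(mean(ann$category == intended), 1.0)
  expect_equal(sum(category_summary(ann)), nrow(ann))

  mu2 <- generate_mutations(fx$proteome, fx$manifest, want, fx$ptm, seed = 92)
  expect_identical(mu, mu2)

  expect_error(generate_mutations(fx$proteome, fx$manifest,
                                  c(blocking_ubiq = 10000L), fx$ptm,
                                  seed = 1),
               "blocking_ubiq")
})

test_that("drug-response generation produces positive IC50s and a truthful manifest", {
  fx <- make_small_fixture(seed = 95, n = 4)
  imp <- fx$manifest$implants
  tre <- data.frame(drug = c("A", "B"), substrate = imp$protein_id[1:2],
                    cancer_type = "SYN", fold_change = c(4, 1))
  dr <- generate_drug_response(fx$proteome, imp, tre, seed = 96)
  expect_true(all(dr$responses$ic50_um > 0))
  expect_equal(dr$manifest$treatments$intended_resistant, c(TRUE, FALSE))
  dr2 <- generate_drug_response(fx$proteome, imp, tre, seed = 96)
  expect_identical(dr$responses, dr2$responses)
})

test_that("a full simulated study writes every table and reloads cleanly", {
  dir <- withr::local_tempdir()
  res <- simulate_degron_study(dir, n_proteins = 12L, seed = 7)
  files <- c("proteome.fasta", "tracks.tsv", "ptm.tsv", "mutations.tsv",
             "drug_response.tsv", "cell_line_mutations.tsv",
             "drug_targets.tsv", "implants.tsv", "params.txt")
  expect_true(all(file.exists(file.path(dir, files))))

  prot <- read_proteome_fasta(file.path(dir, "proteome.fasta"))
  expect_equal(prot, res$proteome)
  tr <- read_track_table(file.path(dir, "tracks.tsv"), prot)
  expect_equal(nrow(tr), sum(nchar(prot$sequence)))
  expect_silent(read_ptm_table(file.path(dir, "ptm.tsv"), prot))
})
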