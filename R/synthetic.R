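#' Generate a synthetic proteome with implanted degrons
#'
#' Residue sequences are drawn uniformly over the 20 standard residues (an
#' optional frequency table allows human-like composition), and degrons are
#' implanted at uniformly chosen internal, non-overlapping positions: each
#' implant instantiates its motif pattern (class members and bounded
#' repetitions sampled uniformly), so every implant matches its motif by
#' construction. The manifest records every implant and suffices, together
#' with the seed, to reproduce the fixture exactly.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Two integers: protein length bounds (uniform).
#' @param motifs List of [degron_motif()] objects to implant.
#' @param implant_rate Probability that a protein receives one implant.
#' @param seed Integer seed.
#' @param residue_freqs Optional named probability vector over the alphabet.
#' @param max_retries Placement retries before erroring on a too-short
#'   protein.
#' @return `list(proteome = ..., manifest = ...)`; the manifest contains the
#'   generator parameters and an `implants` table (`protein_id`,
#'   `motif_name`, `start`, `end`, `implanted_seq`).
#' @export
generate_proteome <- function(n_proteins = 100L, length_range = c(80L, 300L),
                              motifs, implant_rate = 1, seed = 1L,
                              residue_freqs = NULL, max_retries = 50L) {
  stopifnot(implant_rate >= 0, implant_rate <= 1)
  if (inherits(motifs, "degron_motif")) motifs <- list(motifs)
  probs <- if (is.null(residue_freqs)) rep(1 / 20, 20) else
    residue_freqs[AA_ALPHABET] / sum(residue_freqs[AA_ALPHABET])

  withr::with_seed(seed, {
    ids <- sprintf("SYN%04d", seq_len(n_proteins))
    lens <- sample(length_range[1]:length_range[2], n_proteins, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste0(sample(AA_ALPHABET, L, replace = TRUE, prob = probs),
             collapse = ""), character(1))
    implants <- list()
    for (i in seq_len(n_proteins)) {
      if (stats::runif(1) > implant_rate) next
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        mot <- motifs[[sample.int(length(motifs), 1L)]]
        inst <- instantiate_motif(mot$compiled)
        L <- lens[i]; ilen <- nchar(inst)
        if (L - ilen - 1L < 2L) next          # needs an internal placement
        s <- sample(2:(L - ilen), 1L)
        seqs[i] <- paste0(substr(seqs[i], 1L, s - 1L), inst,
                          substr(seqs[i], s + ilen, L))
        implants[[length(implants) + 1L]] <- data.frame(
          protein_id = ids[i], motif_name = mot$motif_name,
          start = s, end = s + ilen - 1L, implanted_seq = inst,
          stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed)
        abort("could not place an implant on protein %s (length %d) after %d retries",
              ids[i], lens[i], max_retries)
    }
    implants <- if (length(implants)) do.call(rbind, implants) else
      data.frame(protein_id = character(0), motif_name = character(0),
                 start = integer(0), end = integer(0),
                 implanted_seq = character(0), stringsAsFactors = FALSE)
    list(proteome = as_proteome(data.frame(protein_id = ids, sequence = seqs,
                                           stringsAsFactors = FALSE)),
         manifest = list(seed = seed, n_proteins = n_proteins,
                         length_range = length_range,
                         implant_rate = implant_rate,
                         motif_patterns = vapply(motifs, `[[`, character(1),
                                                 "pattern"),
                         implants = implants))
  })
}

# Draw one concrete sequence realizing a compiled pattern.
instantiate_motif <- function(compiled) {
  paste0(vapply(compiled$tokens, function(tok) {
    k <- if (tok$min == tok$max) tok$min else sample(tok$min:tok$max, 1L)
    if (k == 0L) return("")
    paste0(sample(tok$allowed, k, replace = TRUE), collapse = "")
  }, character(1)), collapse = "")
}

#' Generate per-residue tracks with configurable degron effect sizes
#'
#' Baseline values are clipped Gaussians; residues inside implanted degron
#' spans are shifted by the configured per-feature effect size — the
#' structure the degron-vs-background comparisons probe (more disordered,
#' more accessible, more conserved degrons). Secondary-structure fractions
#' are normalized to sum to 1 per residue.
#'
#' @param proteome Proteome from [generate_proteome()].
#' @param manifest Matching manifest (provides the implant spans).
#' @param effect_sizes Named mean shifts applied inside implanted spans
#'   (keys from the track registry).
#' @param noise_sd Baseline Gaussian noise SD.
#' @param baseline Baseline mean for the unit-interval tracks.
#' @param seed Integer seed.
#' @return A track table accepted by [aggregate_features()].
#' @export
generate_tracks <- function(proteome, manifest,
                            effect_sizes = c(disorder = 0.4,
                                             accessibility = 0.4,
                                             conservation = 0.4),
                            noise_sd = 0.1, baseline = 0.3, seed = 1L) {
  unknown <- setdiff(names(effect_sizes), TRACK_REGISTRY)
  if (length(unknown))
    abort("effect size(s) for unknown feature(s): %s",
          paste(unknown, collapse = ", "))
  implants <- manifest$implants
  withr::with_seed(seed, {
    out <- lapply(seq_len(nrow(proteome)), function(i) {
      pid <- proteome$protein_id[i]
      L <- nchar(proteome$sequence[i])
      in_span <- rep(FALSE, L)
      sp <- implants[implants$protein_id == pid, , drop = FALSE]
      for (j in seq_len(nrow(sp))) in_span[sp$start[j]:sp$end[j]] <- TRUE

      tr <- data.frame(protein_id = pid, position = seq_len(L),
                       stringsAsFactors = FALSE)
      for (f in c("disorder", "accessibility", "conservation")) {
        v <- baseline + stats::rnorm(L, sd = noise_sd)
        if (f %in% names(effect_sizes)) v[in_span] <- v[in_span] + effect_sizes[[f]]
        tr[[f]] <- pmin(1, pmax(0, v))
      }
      ss <- matrix(abs(stats::rnorm(3 * L, mean = 1, sd = 0.3)), L, 3)
      colnames(ss) <- c("coil", "helix", "sheet")
      for (f in colnames(ss)) {
        if (f %in% names(effect_sizes))
          ss[in_span, f] <- ss[in_span, f] + effect_sizes[[f]]
      }
      ss <- ss / rowSums(ss)
      tr$coil <- ss[, "coil"]; tr$helix <- ss[, "helix"]; tr$sheet <- ss[, "sheet"]
      for (f in c("rigidity", "stabilization")) {
        v <- 0.5 + stats::rnorm(L, sd = noise_sd)
        if (f %in% names(effect_sizes)) v[in_span] <- v[in_span] + effect_sizes[[f]]
        tr[[f]] <- pmin(1, pmax(0, v))
      }
      v <- stats::rbinom(L, 1L, 0.1)
      tr$domain_flag <- as.numeric(v)
      tr
    })
    do.call(rbind, out)
  })
}

#' Generate PTM sites enriched near implanted degrons
#'
#' Each eligible residue (S/T/Y for phosphorylation, K for ubiquitination)
#' becomes an annotated site with a background probability, raised to an
#' enriched probability within the degron window (span plus `flank` residues
#' each side).
#'
#' @param proteome,manifest Fixture pieces from [generate_proteome()].
#' @param p_background Per-residue background site probability.
#' @param p_near_degron Per-residue probability within the degron window.
#' @param flank Window flank width (default 11).
#' @param seed Integer seed.
#' @return A PTM table accepted by [read_ptm_table()]'s validator.
#' @export
generate_ptm_sites <- function(proteome, manifest, p_background = 0.02,
                               p_near_degron = 0.15, flank = 11L, seed = 1L) {
  implants <- manifest$implants
  withr::with_seed(seed, {
    out <- lapply(seq_len(nrow(proteome)), function(i) {
      pid <- proteome$protein_id[i]
      res <- residues(proteome$sequence[i])
      L <- length(res)
      near <- rep(FALSE, L)
      sp <- implants[implants$protein_id == pid, , drop = FALSE]
      for (j in seq_len(nrow(sp)))
        near[max(1L, sp$start[j] - flank):min(L, sp$end[j] + flank)] <- TRUE
      p <- ifelse(near, p_near_degron, p_background)
      phos <- which(res %in% c("S", "T", "Y") & stats::runif(L) < p)
      ubiq <- which(res == "K" & stats::runif(L) < p)
      rbind(
        if (length(phos)) data.frame(protein_id = pid, position = phos,
                                     ptm_type = "phosphorylation",
                                     stringsAsFactors = FALSE),
        if (length(ubiq)) data.frame(protein_id = pid, position = ubiq,
                                     ptm_type = "ubiquitination",
                                     stringsAsFactors = FALSE))
    })
    res <- do.call(rbind, out)
    if (is.null(res))
      res <- data.frame(protein_id = character(0), position = integer(0),
                        ptm_type = character(0), stringsAsFactors = FALSE)
    rownames(res) <- NULL
    res
  })
}

#' Generate mutations engineered for each functional category
#'
#' Mutations are constructed by inverting the default classification rules,
#' so the intended category is exactly the one [classify_mutations()]
#' assigns under default precedence: altering-motif mutations sit inside a
#' degron span away from annotated PTM positions, PTM-blocking mutations sit
#' on annotated sites within the window, flanking-lysine substitutions hit
#' unannotated flank lysines, and rewiring mutations hit unannotated
#' non-lysine flank residues. An unachievable request errors naming the
#' category.
#'
#' @param proteome,manifest Fixture pieces from [generate_proteome()].
#' @param per_category_counts Named integer vector over (a subset of) the
#'   five categories.
#' @param ptm_sites PTM table (e.g. from [generate_ptm_sites()]).
#' @param flank Window flank width (default 11).
#' @param seed Integer seed.
#' @return A mutation table with an extra `intended_category` label column
#'   (drop it before feeding pipelines that expect the plain schema).
#' @export
generate_mutations <- function(proteome, manifest, per_category_counts,
                               ptm_sites, flank = 11L, seed = 1L) {
  bad <- setdiff(names(per_category_counts), MUTATION_CATEGORIES)
  if (length(bad))
    abort("unknown category name(s): %s", paste(bad, collapse = ", "))
  implants <- manifest$implants
  if (!nrow(implants)) abort("fixture has no implanted degrons")

  # Candidate (protein, position) pools per category, by rule inversion.
  pools <- list(altering_motif = list(), blocking_phospho = list(),
                blocking_ubiq = list(), substituting_flanking_lysine = list(),
                rewiring_network = list())
  is_ptm <- function(pid, pos)
    any(ptm_sites$protein_id == pid & ptm_sites$position == pos)
  for (j in seq_len(nrow(implants))) {
    pid <- implants$protein_id[j]
    seq <- get_sequence(proteome, pid)
    L <- nchar(seq)
    s <- implants$start[j]; e <- implants$end[j]
    win <- max(1L, s - flank):min(L, e + flank)
    fl <- setdiff(win, s:e)
    res <- residues(seq)
    add <- function(cat, pos) {
      if (length(pos))
        pools[[cat]][[length(pools[[cat]]) + 1L]] <<-
          data.frame(protein_id = pid, position = pos,
                     stringsAsFactors = FALSE)
    }
    in_ptm <- vapply(win, function(p) is_ptm(pid, p), logical(1))
    names(in_ptm) <- win
    add("altering_motif", (s:e)[!in_ptm[as.character(s:e)]])
    ph <- ptm_sites[ptm_sites$protein_id == pid &
                      ptm_sites$position %in% win, , drop = FALSE]
    add("blocking_phospho", ph$position[ph$ptm_type == "phosphorylation"])
    add("blocking_ubiq", ph$position[ph$ptm_type == "ubiquitination"])
    add("substituting_flanking_lysine",
        fl[res[fl] == "K" & !in_ptm[as.character(fl)]])
    add("rewiring_network", fl[res[fl] != "K" & !in_ptm[as.character(fl)]])
  }

  withr::with_seed(seed, {
    rows <- list()
    for (cat in names(per_category_counts)) {
      want <- per_category_counts[[cat]]
      pool <- if (length(pools[[cat]])) unique(do.call(rbind, pools[[cat]]))
              else data.frame()
      if (nrow(pool) < want)
        abort("cannot engineer %d '%s' mutation(s): only %d eligible position(s) in the fixture",
              want, cat, nrow(pool))
      pick <- pool[sample.int(nrow(pool), want), , drop = FALSE]
      ref <- substr(get_sequence_vec(proteome, pick$protein_id),
                    pick$position, pick$position)
      alt <- vapply(ref, function(r) sample(setdiff(AA_ALPHABET, r), 1L),
                    character(1))
      rows[[cat]] <- data.frame(
        protein_id = pick$protein_id, position = pick$position,
        ref_aa = unname(ref), alt_aa = unname(alt),
        sample_id = sprintf("SAMPLE%03d", seq_len(want)),
        source = "synthetic", intended_category = cat,
        stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    res
  })
}

# Vectorized sequence lookup.
get_sequence_vec <- function(proteome, protein_ids) {
  proteome$sequence[match(protein_ids, proteome$protein_id)]
}

#' Generate drug-response and cell-line mutation tables with engineered
#' resistance
#'
#' Per treatment (drug, substrate, cancer type), baseline IC50 values are
#' lognormal around `baseline_ic50_um`; the designated degron-mutant (G1)
#' cell lines have their IC50 multiplied by the treatment's fold change, and
#' each receives one mutation inside a degron of the substrate so the
#' grouping step reproduces the design. The manifest marks treatments with
#' fold change > 1 as intended resistance events.
#'
#' @param proteome Proteome providing the substrate sequences.
#' @param degrons Degron catalog (`protein_id`, `start`, `end`) for the
#'   substrates.
#' @param treatments `data.frame` with `drug`, `substrate`, `cancer_type`,
#'   `fold_change` (> 0).
#' @param n_g1,n_g2 Cell lines per group.
#' @param baseline_ic50_um Geometric-mean baseline IC50 (micromolar).
#' @param noise_sd_log10 Lognormal noise SD on the log10 scale.
#' @param seed Integer seed.
#' @return `list(responses, mutations, drug_targets, manifest)`.
#' @export
generate_drug_response <- function(proteome, degrons, treatments,
                                   n_g1 = 5L, n_g2 = 5L,
                                   baseline_ic50_um = 1,
                                   noise_sd_log10 = 0.2, seed = 1L) {
  stopifnot(all(treatments$fold_change > 0))
  withr::with_seed(seed, {
    resp <- list(); muts <- list()
    for (i in seq_len(nrow(treatments))) {
      tt <- treatments[i, ]
      dg <- degrons[degrons$protein_id == tt$substrate, , drop = FALSE]
      if (!nrow(dg))
        abort("substrate '%s' has no degron in the catalog", tt$substrate)
      g1 <- sprintf("CL%03d_G1_%02d", i, seq_len(n_g1))
      g2 <- sprintf("CL%03d_G2_%02d", i, seq_len(n_g2))
      base <- log10(baseline_ic50_um)
      ic50 <- c(10^(base + log10(tt$fold_change) +
                      stats::rnorm(n_g1, sd = noise_sd_log10)),
                10^(base + stats::rnorm(n_g2, sd = noise_sd_log10)))
      resp[[i]] <- data.frame(cell_line = c(g1, g2),
                              cancer_type = tt$cancer_type, drug = tt$drug,
                              ic50_um = ic50, stringsAsFactors = FALSE)
      pos <- dg$start[1]
      ref <- substr(get_sequence(proteome, tt$substrate), pos, pos)
      muts[[i]] <- data.frame(
        protein_id = tt$substrate, position = pos, ref_aa = ref,
        alt_aa = vapply(seq_len(n_g1), function(k)
          sample(setdiff(AA_ALPHABET, ref), 1L), character(1)),
        sample_id = g1, source = "synthetic", stringsAsFactors = FALSE)
    }
    list(responses = do.call(rbind, resp),
         mutations = do.call(rbind, muts),
         drug_targets = unique(data.frame(drug = treatments$drug,
                                          protein_id = treatments$substrate,
                                          stringsAsFactors = FALSE)),
         manifest = list(seed = seed, n_g1 = n_g1, n_g2 = n_g2,
                         noise_sd_log10 = noise_sd_log10,
                         treatments = transform(treatments,
                                                intended_resistant =
                                                  fold_change > 1)))
  })
}

#' Write a complete synthetic study to a directory
#'
#' Generates proteome, tracks, PTM sites, category-labeled mutations, drug
#' response, and the ground-truth manifest, and writes them as plain-text
#' files (`proteome.fasta`, `tracks.tsv`, `ptm.tsv`, `mutations.tsv`,
#' `drug_response.tsv`, `cell_line_mutations.tsv`, `drug_targets.tsv`,
#' `implants.tsv`, `params.txt`).
#'
#' @param dir Output directory (created if needed).
#' @param motifs Motif list (default: the example motif file shipped with
#'   the package).
#' @param n_proteins,length_range,implant_rate,effect_sizes,noise_sd
#'   Passed to the generators.
#' @param per_category_counts Mutation counts per category.
#' @param treatments Treatment design for [generate_drug_response()]
#'   (default: one engineered resistant and one neutral treatment).
#' @param seed Integer seed (child seeds are derived per generator).
#' @return The manifest list, invisibly; files are written to `dir`.
#' @export
simulate_degron_study <- function(dir, motifs = example_motifs(),
                                  n_proteins = 60L,
                                  length_range = c(80L, 300L),
                                  implant_rate = 1,
                                  effect_sizes = c(disorder = 0.4,
                                                   accessibility = 0.4,
                                                   conservation = 0.4),
                                  noise_sd = 0.1,
                                  per_category_counts = c(
                                    altering_motif = 5L, blocking_phospho = 2L,
                                    blocking_ubiq = 1L,
                                    substituting_flanking_lysine = 3L,
                                    rewiring_network = 4L),
                                  treatments = NULL, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, 5L)
  gp <- generate_proteome(n_proteins, length_range, motifs, implant_rate,
                          seed = seeds[1])
  tracks <- generate_tracks(gp$proteome, gp$manifest, effect_sizes, noise_sd,
                            seed = seeds[2])
  ptm <- generate_ptm_sites(gp$proteome, gp$manifest, seed = seeds[3])
  mut <- generate_mutations(gp$proteome, gp$manifest, per_category_counts,
                            ptm, seed = seeds[4])
  if (is.null(treatments)) {
    subs <- gp$manifest$implants$protein_id[1:2]
    treatments <- data.frame(drug = c("DRUG_A", "DRUG_B"),
                             substrate = subs, cancer_type = "SYNCAN",
                             fold_change = c(8, 1), stringsAsFactors = FALSE)
  }
  dr <- generate_drug_response(gp$proteome,
                               gp$manifest$implants, treatments,
                               seed = seeds[5])
  write_proteome_fasta(gp$proteome, file.path(dir, "proteome.fasta"))
  write_tsv_file(tracks, file.path(dir, "tracks.tsv"))
  write_tsv_file(ptm, file.path(dir, "ptm.tsv"))
  write_tsv_file(mut, file.path(dir, "mutations.tsv"))
  write_tsv_file(dr$responses, file.path(dir, "drug_response.tsv"))
  write_tsv_file(dr$mutations, file.path(dir, "cell_line_mutations.tsv"))
  write_tsv_file(dr$drug_targets, file.path(dir, "drug_targets.tsv"))
  write_tsv_file(gp$manifest$implants, file.path(dir, "implants.tsv"))
  writeLines(c(sprintf("seed=%d", seed),
               sprintf("n_proteins=%d", n_proteins),
               sprintf("length_range=%d..%d", length_range[1], length_range[2]),
               sprintf("implant_rate=%g", implant_rate),
               sprintf("noise_sd=%g", noise_sd),
               sprintf("effect_sizes=%s",
                       paste(sprintf("%s:%g", names(effect_sizes),
                                     effect_sizes), collapse = ","))),
             file.path(dir, "params.txt"))
  invisible(list(proteome = gp$proteome, manifest = gp$manifest,
                 tracks = tracks, ptm = ptm, mutations = mut,
                 drug = dr))
}

#' Example degron motif set
#'
#' Loads the small motif definition file shipped with the package
#' (`inst/extdata/degron_motifs.tsv`): a handful of well-known E3-ligase
#' consensus patterns (APC/C D-box and KEN-box, SCF beta-TrCP phosphodegron,
#' MDM2, KEAP1 Kelch, SPOP) meant for examples and fixtures; real analyses
#' should supply their own curated motif table.
#'
#' @return A list of [degron_motif()] objects.
#' @export
example_motifs <- function() {
  read_motif_table(system.file("extdata", "degron_motifs.tsv",
                               package = "degronr", mustWork = TRUE))
}
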