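#' Read a protein FASTA file into a proteome table
#'
#' Each FASTA entry becomes one row with `protein_id` (the header token before
#' the first whitespace) and an uppercased `sequence`. Only the 20 standard
#' residues plus `X` (unknown) are accepted; duplicate IDs and empty sequences
#' are load errors. All residue coordinates in this package are 1-based
#' inclusive, matching protein variant nomenclature such as T368M.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` with columns `protein_id`, `sequence`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 example", "MRAALQQVK"), fa)
#' read_proteome_fasta(fa)
read_proteome_fasta <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    abort("duplicate protein ID(s) in %s: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- vapply(seq_along(ss), function(i) {
    check_sequence(as.character(ss[[i]]), ids[i])
  }, character(1))
  as_proteome(data.frame(protein_id = ids, sequence = seqs,
                         stringsAsFactors = FALSE))
}

#' Construct a proteome table from IDs and sequences
#'
#' @param x A `data.frame` with columns `protein_id` and `sequence`, or a
#'   named character vector of sequences.
#' @return A validated proteome `data.frame`.
#' @export
as_proteome <- function(x) {
  if (is.character(x)) {
    if (is.null(names(x))) abort("a character proteome must be named")
    x <- data.frame(protein_id = names(x), sequence = unname(x),
                    stringsAsFactors = FALSE)
  }
  stopifnot(all(c("protein_id", "sequence") %in% names(x)))
  if (anyDuplicated(x$protein_id))
    abort("duplicate protein ID(s): %s",
          paste(unique(x$protein_id[duplicated(x$protein_id)]), collapse = ", "))
  x$sequence <- vapply(seq_len(nrow(x)),
                       function(i) check_sequence(x$sequence[i], x$protein_id[i]),
                       character(1))
  rownames(x) <- NULL
  x
}

# Sequence lookup; errors on unknown protein.
get_sequence <- function(proteome, protein_id) {
  i <- match(protein_id, proteome$protein_id)
  if (is.na(i)) abort("unknown protein '%s'", protein_id)
  proteome$sequence[i]
}

protein_length <- function(proteome, protein_id) {
  nchar(get_sequence(proteome, protein_id))
}

#' Write a proteome table to FASTA
#'
#' @param proteome Proteome `data.frame` (see [read_proteome_fasta()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_proteome_fasta <- function(proteome, path) {
  ss <- Biostrings::BStringSet(proteome$sequence)
  names(ss) <- proteome$protein_id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Parse compact protein-variant strings such as "T368M"
#'
#' @param x Character vector of `<ref><pos><alt>` variant strings.
#' @return A `data.frame` with columns `ref_aa`, `position`, `alt_aa`.
#' @export
#' @examples
#' parse_protein_variant("T368M")
parse_protein_variant <- function(x) {
  m <- regmatches(x, regexec("^([A-Z])([0-9]+)([A-Z])$", toupper(x)))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad))
    abort("malformed variant string(s): %s", paste(x[bad], collapse = ", "))
  ref <- vapply(m, `[`, character(1), 2L)
  alt <- vapply(m, `[`, character(1), 4L)
  pos <- as.integer(vapply(m, `[`, character(1), 3L))
  ok <- ref %in% AA_ALPHABET & alt %in% AA_ALPHABET & pos >= 1L
  if (any(!ok))
    abort("invalid variant string(s): %s", paste(x[!ok], collapse = ", "))
  data.frame(ref_aa = ref, position = pos, alt_aa = alt,
             stringsAsFactors = FALSE)
}

#' Read and validate a protein-level missense mutation table
#'
#' Expects a tab-separated file with header columns `protein_id`, `position`,
#' `ref_aa`, `alt_aa`, `sample_id`, `source` (alternatively a `variant`
#' column with compact "T368M" strings in place of the three variant
#' columns). Rows are validated against the proteome: records whose reference
#' residue does not match the sequence, synonymous records
#' (`ref_aa == alt_aa`), and records whose position falls outside the protein
#' are dropped — never fatally — and the counts by reason are attached as the
#' `"dropped"` attribute and reported via `message()`.
#'
#' @param path Path to the TSV.
#' @param proteome Proteome `data.frame` used for validation.
#' @return A `data.frame` of retained `MutationRecord` rows with a `dropped`
#'   attribute (named integer vector: `mismatch`, `synonymous`,
#'   `out_of_bounds`, `unknown_protein`).
#' @export
read_mutation_table <- function(path, proteome) {
  df <- read_tsv_file(path, "protein_id")
  if ("variant" %in% names(df) && !all(c("ref_aa", "position", "alt_aa") %in% names(df))) {
    pv <- parse_protein_variant(df$variant)
    df$ref_aa <- pv$ref_aa; df$position <- pv$position; df$alt_aa <- pv$alt_aa
  }
  need <- c("protein_id", "position", "ref_aa", "alt_aa", "sample_id", "source")
  missing <- setdiff(need, names(df))
  if (length(missing))
    abort("%s: missing required column(s): %s", path,
          paste(missing, collapse = ", "))
  df <- df[need]
  df$position <- as.integer(df$position)
  df$ref_aa <- toupper(df$ref_aa); df$alt_aa <- toupper(df$alt_aa)
  validate_mutations(df, proteome)
}

# Shared validation for mutation tables (file-based or in-memory).
validate_mutations <- function(df, proteome) {
  dropped <- c(mismatch = 0L, synonymous = 0L, out_of_bounds = 0L,
               unknown_protein = 0L)
  known <- df$protein_id %in% proteome$protein_id
  dropped["unknown_protein"] <- sum(!known)
  df <- df[known, , drop = FALSE]

  if (nrow(df)) {
    len <- nchar(proteome$sequence)[match(df$protein_id, proteome$protein_id)]
    inb <- df$position >= 1L & df$position <= len
    dropped["out_of_bounds"] <- sum(!inb)
    df <- df[inb, , drop = FALSE]
  }
  if (nrow(df)) {
    syn <- df$ref_aa == df$alt_aa
    dropped["synonymous"] <- sum(syn)
    df <- df[!syn, , drop = FALSE]
  }
  if (nrow(df)) {
    seqs <- proteome$sequence[match(df$protein_id, proteome$protein_id)]
    obs <- substr(seqs, df$position, df$position)
    ok <- obs == df$ref_aa
    dropped["mismatch"] <- sum(!ok)
    df <- df[ok, , drop = FALSE]
  }
  rownames(df) <- NULL
  attr(df, "dropped") <- dropped
  if (sum(dropped) > 0)
    message(sprintf("dropped %d mutation record(s): %s", sum(dropped),
                    paste(sprintf("%s=%d", names(dropped), dropped),
                          collapse = ", ")))
  df
}

#' Read a PTM site table
#'
#' Tab-separated columns `protein_id`, `position`, `ptm_type` with
#' `ptm_type` in `phosphorylation`/`ubiquitination`. Residue identity is
#' enforced against the proteome: phosphorylation sites must sit on S/T/Y and
#' ubiquitination sites on K; violations are load errors.
#'
#' @param path Path to the TSV.
#' @param proteome Proteome `data.frame`.
#' @return A validated `data.frame` of PTM sites.
#' @export
read_ptm_table <- function(path, proteome) {
  df <- read_tsv_file(path, c("protein_id", "position", "ptm_type"))
  df$position <- as.integer(df$position)
  validate_ptm_sites(df, proteome)
}

validate_ptm_sites <- function(df, proteome) {
  bad_type <- !df$ptm_type %in% PTM_TYPES
  if (any(bad_type))
    abort("unknown ptm_type value(s): %s (expected %s)",
          paste(unique(df$ptm_type[bad_type]), collapse = ", "),
          paste(PTM_TYPES, collapse = ", "))
  for (i in seq_len(nrow(df))) {
    seq <- get_sequence(proteome, df$protein_id[i])
    pos <- df$position[i]
    if (pos < 1L || pos > nchar(seq))
      abort("PTM site %s:%d outside protein bounds", df$protein_id[i], pos)
    res <- substr(seq, pos, pos)
    ok <- if (df$ptm_type[i] == "phosphorylation") res %in% c("S", "T", "Y")
          else res == "K"
    if (!ok)
      abort("PTM site %s:%d (%s) sits on residue '%s', violating residue identity",
            df$protein_id[i], pos, df$ptm_type[i], res)
  }
  rownames(df) <- NULL
  df
}

#' Read per-residue annotation tracks
#'
#' Long-to-wide TSV with columns `protein_id`, `position` and one column per
#' feature drawn from the track registry (`disorder`, `accessibility`,
#' `conservation`, `coil`, `helix`, `sheet`, `rigidity`, `stabilization`,
#' `domain_flag`). Every protein present must be covered by exactly one row
#' per residue; unit-interval tracks are range-checked and the three
#' secondary-structure fractions must sum to 1 per residue when all present.
#'
#' @param path Path to the TSV.
#' @param proteome Proteome `data.frame`.
#' @return A `data.frame` of validated tracks (one row per residue).
#' @export
read_track_table <- function(path, proteome) {
  df <- read_tsv_file(path, c("protein_id", "position"))
  feats <- setdiff(names(df), c("protein_id", "position"))
  unknown <- setdiff(feats, TRACK_REGISTRY)
  if (length(unknown))
    abort("unknown feature name(s): %s; track registry is: %s",
          paste(unknown, collapse = ", "),
          paste(TRACK_REGISTRY, collapse = ", "))
  df$position <- as.integer(df$position)
  for (f in feats) df[[f]] <- as.numeric(df[[f]])
  validate_tracks(df, proteome)
}

validate_tracks <- function(df, proteome) {
  feats <- intersect(TRACK_REGISTRY, names(df))
  for (pid in unique(df$protein_id)) {
    len <- protein_length(proteome, pid)
    sub <- df[df$protein_id == pid, , drop = FALSE]
    if (nrow(sub) != len || !setequal(sub$position, seq_len(len)))
      abort("track for '%s' covers %d position(s) but protein has %d residues",
            pid, nrow(sub), len)
  }
  for (f in intersect(feats, UNIT_TRACKS)) {
    v <- df[[f]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      abort("track '%s' has values outside [0, 1]", f)
  }
  ss <- c("coil", "helix", "sheet")
  if (all(ss %in% feats)) {
    tot <- df$coil + df$helix + df$sheet
    if (any(!is.na(tot) & abs(tot - 1) > 1e-6))
      abort("coil + helix + sheet must sum to 1 per residue (max deviation %.3g)",
            max(abs(tot - 1), na.rm = TRUE))
  }
  df[order(df$protein_id, df$position), , drop = FALSE]
}

#' Read a drug-response table
#'
#' Tab-separated columns `cell_line`, `cancer_type`, `drug`, `ic50_um`
#' (micromolar, strictly positive).
#'
#' @param path Path to the TSV.
#' @return A validated `data.frame`.
#' @export
read_drug_response_table <- function(path) {
  df <- read_tsv_file(path, c("cell_line", "cancer_type", "drug", "ic50_um"))
  df$ic50_um <- as.numeric(df$ic50_um)
  if (any(is.na(df$ic50_um) | df$ic50_um <= 0))
    abort("ic50_um must be a positive number for every row")
  df
}

#' Read a degron motif definition table
#'
#' Tab-separated columns `motif_name`, `e3_ligase`, `pattern`; each pattern is
#' compiled under the motif grammar (see [compile_motif()]).
#'
#' @param path Path to the TSV.
#' @return A list of compiled motifs (see [degron_motif()]).
#' @export
read_motif_table <- function(path) {
  df <- read_tsv_file(path, c("motif_name", "e3_ligase", "pattern"))
  if (anyDuplicated(df$motif_name))
    abort("duplicate motif_name(s): %s",
          paste(unique(df$motif_name[duplicated(df$motif_name)]), collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    degron_motif(df$motif_name[i], df$e3_ligase[i], df$pattern[i]))
}

#' Write a table as TSV
#'
#' Tab-separated, header row, UTF-8, no quoting — the format every reader in
#' the package accepts back (round-trip safe).
#'
#' @param df A `data.frame`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_table_tsv <- function(df, path) write_tsv_file(df, path)
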