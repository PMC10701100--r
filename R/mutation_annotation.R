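#' Map missense mutations onto degrons and their flanks
#'
#' A mutation hits a degron when its position lies within the degron span
#' extended by `flank` residues on both sides (clipped to the protein). The
#' region is `in_degron` when the position lies inside the span itself,
#' `in_flank` otherwise. A mutation may hit several degrons; each hit is one
#' row.
#'
#' @param mutations Validated mutation table (see [read_mutation_table()]).
#' @param degrons `data.frame` with `protein_id`, `start`, `end` and
#'   optionally `motif_name`.
#' @param flank Flank width in residues (default 11).
#' @return A `data.frame` joining each mutation to each degron it hits, with
#'   a `region` column.
#' @export
map_to_degrons <- function(mutations, degrons, flank = 11L) {
  out <- list()
  for (i in seq_len(nrow(mutations))) {
    mu <- mutations[i, , drop = FALSE]
    dg <- degrons[degrons$protein_id == mu$protein_id, , drop = FALSE]
    if (!nrow(dg)) next
    hit <- mu$position >= dg$start - flank & mu$position <= dg$end + flank
    dg <- dg[hit, , drop = FALSE]
    if (!nrow(dg)) next
    region <- ifelse(mu$position >= dg$start & mu$position <= dg$end,
                     "in_degron", "in_flank")
    out[[length(out) + 1L]] <- data.frame(
      mu[rep(1L, nrow(dg)), , drop = FALSE],
      degron_start = dg$start, degron_end = dg$end,
      motif_name = if ("motif_name" %in% names(dg)) dg$motif_name else NA_character_,
      region = region, row.names = NULL, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(protein_id = character(0), position = integer(0),
                      ref_aa = character(0), alt_aa = character(0),
                      sample_id = character(0), source = character(0),
                      degron_start = integer(0), degron_end = integer(0),
                      motif_name = character(0), region = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify degron-mapped mutations into five functional categories
#'
#' Each (mutation, degron) hit receives exactly one category, assigned by the
#' first matching rule in a configurable precedence order. The default
#' order puts the PTM-blocking rules first because they name a specific
#' regulatory mechanism:
#'
#' 1. `blocking_phospho` — the position is an annotated phosphorylation site
#'    within the window and the reference residue is S/T/Y;
#' 2. `blocking_ubiq` — the position is an annotated ubiquitination site
#'    within the window and the reference residue is K;
#' 3. `altering_motif` — the position lies inside the degron span; the
#'    mutant degron sequence (wild type with the single substituted residue)
#'    is reported;
#' 4. `substituting_flanking_lysine` — a flank position whose reference
#'    residue is a lysine not annotated as a ubiquitination site;
#' 5. `rewiring_network` — everything else (the fallback; it cannot be
#'    removed from the precedence).
#'
#' @param hits Output of [map_to_degrons()].
#' @param proteome Proteome `data.frame`.
#' @param ptm_sites PTM table (see [read_ptm_table()]); may be `NULL`.
#' @param precedence Character vector ordering the non-fallback rules.
#' @return `hits` with `category` and `mutant_degron_seq` columns
#'   (`mutant_degron_seq` is `NA` outside the degron).
#' @export
classify_mutations <- function(hits, proteome, ptm_sites = NULL,
                               precedence = MUTATION_CATEGORIES) {
  stopifnot(setequal(precedence, MUTATION_CATEGORIES))
  if (is.null(ptm_sites))
    ptm_sites <- data.frame(protein_id = character(0), position = integer(0),
                            ptm_type = character(0))
  n <- nrow(hits)
  category <- character(n)
  mutant <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    h <- hits[i, ]
    is_phospho <- any(ptm_sites$protein_id == h$protein_id &
                        ptm_sites$position == h$position &
                        ptm_sites$ptm_type == "phosphorylation")
    is_ubiq <- any(ptm_sites$protein_id == h$protein_id &
                     ptm_sites$position == h$position &
                     ptm_sites$ptm_type == "ubiquitination")
    rule_fires <- c(
      blocking_phospho = is_phospho && h$ref_aa %in% c("S", "T", "Y"),
      blocking_ubiq = is_ubiq && h$ref_aa == "K",
      altering_motif = h$region == "in_degron",
      substituting_flanking_lysine =
        h$region == "in_flank" && h$ref_aa == "K" && !is_ubiq,
      rewiring_network = TRUE)
    category[i] <- precedence[which(rule_fires[precedence])[1]]
    if (h$region == "in_degron") {
      wt <- substr(get_sequence(proteome, h$protein_id),
                   h$degron_start, h$degron_end)
      off <- h$position - h$degron_start + 1L
      substr(wt, off, off) <- h$alt_aa
      mutant[i] <- wt
    }
  }
  hits$category <- category
  hits$mutant_degron_seq <- mutant
  hits
}

#' Per-category counts of annotated mutations
#'
#' The five categories partition the annotated hits, so the counts always sum
#' to the number of annotations.
#'
#' @param annotations Output of [classify_mutations()].
#' @return Named integer vector over the five categories.
#' @export
category_summary <- function(annotations) {
  counts <- table(factor(annotations$category, levels = MUTATION_CATEGORIES))
  stats::setNames(as.integer(counts), MUTATION_CATEGORIES)
}

#' Annotate a mutation table against a degron catalog in one step
#'
#' Convenience wrapper: [map_to_degrons()] then [classify_mutations()].
#'
#' @inheritParams map_to_degrons
#' @inheritParams classify_mutations
#' @return Annotated hit table.
#' @export
annotate_mutations <- function(mutations, degrons, proteome, ptm_sites = NULL,
                               flank = 11L, precedence = MUTATION_CATEGORIES) {
  classify_mutations(map_to_degrons(mutations, degrons, flank), proteome,
                     ptm_sites, precedence)
}
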