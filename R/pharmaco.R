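#' Split cell lines into degron-mutant (G1) and wild-type (G2) groups
#'
#' A cell line belongs to G1 when it carries at least one mutation mapping
#' (same window rule as [map_to_degrons()]) to any degron of the substrate
#' protein; otherwise it belongs to G2. The two groups partition the input.
#' Duplicated cell-line entries are de-duplicated with a warning.
#'
#' @param cell_lines Character vector of cell-line names (one cancer type;
#'   the per-cancer-type grouping happens upstream).
#' @param mutations Mutation table whose `sample_id` is the cell line.
#' @param degrons Degron catalog (`protein_id`, `start`, `end`).
#' @param substrate Substrate protein ID.
#' @param flank Flank width in residues (default 11).
#' @return `list(g1 = ..., g2 = ...)` of cell-line name vectors.
#' @export
split_cell_lines <- function(cell_lines, mutations, degrons, substrate,
                             flank = 11L) {
  if (anyDuplicated(cell_lines)) {
    warn("duplicated cell line(s) de-duplicated: %s",
         paste(unique(cell_lines[duplicated(cell_lines)]), collapse = ", "))
    cell_lines <- unique(cell_lines)
  }
  dg <- degrons[degrons$protein_id == substrate, , drop = FALSE]
  mu <- mutations[mutations$protein_id == substrate &
                    mutations$sample_id %in% cell_lines, , drop = FALSE]
  mutant <- character(0)
  if (nrow(dg) && nrow(mu)) {
    hit <- vapply(seq_len(nrow(mu)), function(i)
      any(mu$position[i] >= dg$start - flank &
            mu$position[i] <= dg$end + flank), logical(1))
    mutant <- unique(mu$sample_id[hit])
  }
  list(g1 = cell_lines[cell_lines %in% mutant],
       g2 = cell_lines[!cell_lines %in% mutant])
}

#' Call drug resistance for one treatment
#'
#' A treatment is a (drug, substrate, cancer type) triple. The per-group mean
#' IC50 is the arithmetic mean on the linear micromolar scale; the treatment
#' is flagged resistant when the degron-mutant group mean strictly exceeds
#' the wild-type group mean. No significance test is attached — the call is a
#' raw mean comparison, whose false-positive behavior under no effect is
#' documented (and tested) as roughly a coin flip.
#'
#' @param drug,substrate,cancer_type Treatment identifiers.
#' @param responses Drug-response table (see [read_drug_response_table()]).
#' @param g1,g2 Cell-line vectors from [split_cell_lines()].
#' @param min_group Minimum group size to emit a call (default 1).
#' @return One-row `data.frame` (`TreatmentCall`), or `NULL` when either
#'   group is smaller than `min_group` (a message states the reason).
#' @export
call_treatment <- function(drug, substrate, cancer_type, responses, g1, g2,
                           min_group = 1L) {
  rr <- responses[responses$drug == drug &
                    responses$cancer_type == cancer_type, , drop = FALSE]
  ic1 <- rr$ic50_um[rr$cell_line %in% g1]
  ic2 <- rr$ic50_um[rr$cell_line %in% g2]
  if (length(ic1) < min_group || length(ic2) < min_group) {
    message(sprintf("skipping %s / %s / %s: group sizes %d vs %d below min_group %d",
                    drug, substrate, cancer_type, length(ic1), length(ic2),
                    min_group))
    return(NULL)
  }
  m1 <- mean(ic1); m2 <- mean(ic2)
  data.frame(drug = drug, substrate = substrate, cancer_type = cancer_type,
             n_g1 = length(ic1), n_g2 = length(ic2),
             g1_mean_ic50 = m1, g2_mean_ic50 = m2,
             fold_change = m1 / m2, resistant = m1 > m2,
             stringsAsFactors = FALSE)
}

#' Scan all treatments for potential degron-linked drug resistance
#'
#' For every (drug, cancer type) with response data, and every degron
#' substrate the drug targets, cell lines of that cancer type are split into
#' degron-mutant/wild-type groups and the mean IC50s are compared. Only drugs
#' with a target mapping are analyzed; unmapped drugs are skipped with a
#' warning. The output is deterministic and independent of input row order.
#'
#' @param responses Drug-response table.
#' @param mutations Per-cell-line mutation table (`sample_id` = cell line).
#' @param degrons Degron catalog.
#' @param drug_targets `data.frame` with columns `drug`, `protein_id`.
#' @param min_group Minimum per-group size to emit a call.
#' @param flank Flank width (default 11).
#' @return `data.frame` of treatment calls, sorted by
#'   (`drug`, `substrate`, `cancer_type`).
#' @export
resistance_scan <- function(responses, mutations, degrons, drug_targets,
                            min_group = 1L, flank = 11L) {
  empty <- data.frame(drug = character(0), substrate = character(0),
                      cancer_type = character(0), n_g1 = integer(0),
                      n_g2 = integer(0), g1_mean_ic50 = numeric(0),
                      g2_mean_ic50 = numeric(0), fold_change = numeric(0),
                      resistant = logical(0), stringsAsFactors = FALSE)
  if (!nrow(responses)) return(empty)
  combos <- unique(responses[c("drug", "cancer_type")])
  combos <- combos[order(combos$drug, combos$cancer_type), , drop = FALSE]
  out <- list()
  unmapped <- character(0)
  for (i in seq_len(nrow(combos))) {
    drug <- combos$drug[i]; ct <- combos$cancer_type[i]
    targets <- sort(unique(drug_targets$protein_id[drug_targets$drug == drug]))
    if (!length(targets)) {
      unmapped <- c(unmapped, drug)
      next
    }
    lines <- sort(unique(responses$cell_line[responses$drug == drug &
                                               responses$cancer_type == ct]))
    for (substrate in targets) {
      if (!substrate %in% degrons$protein_id) next
      gg <- split_cell_lines(lines, mutations, degrons, substrate, flank)
      call <- call_treatment(drug, substrate, ct, responses, gg$g1, gg$g2,
                             min_group)
      if (!is.null(call)) out[[length(out) + 1L]] <- call
    }
  }
  if (length(unmapped))
    warn("drug(s) without a target mapping skipped: %s",
         paste(sort(unique(unmapped)), collapse = ", "))
  res <- if (length(out)) do.call(rbind, out) else empty
  res <- res[order(res$drug, res$substrate, res$cancer_type), , drop = FALSE]
  rownames(res) <- NULL
  res
}
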