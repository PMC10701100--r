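#' Compile a degron consensus pattern
#'
#' Patterns use a deliberately small, auditable ELM-style grammar rather than
#' full regular expressions:
#'
#' * an uppercase letter is an exact residue (e.g. `R`);
#' * `x` or `.` matches any residue, including the unknown residue `X`;
#' * `[...]` is an allowed residue class, `[^...]` an excluded class — an
#'   unknown `X` in the sequence never satisfies a literal or a class;
#' * `{m,n}` bounds repetition of the preceding element (`m <= n <= 10`).
#'
#' The compiled matcher reports, for each start offset, the maximal match
#' (greedy repetition), so there is exactly one match per (motif, start).
#'
#' @param pattern Consensus pattern string, e.g. `"RxxLxx[LIVM]"`.
#' @return An object of class `compiled_motif`: the token list, the derived
#'   Perl regex used for scanning, and the minimum/maximum match lengths.
#' @export
#' @examples
#' compile_motif("RxxLxx[LIVM]")
compile_motif <- function(pattern) {
  tokens <- parse_motif_pattern(pattern)
  rx <- paste0(vapply(tokens, token_regex, character(1)), collapse = "")
  structure(
    list(pattern = pattern, tokens = tokens,
         regex = paste0("(?=(", rx, "))"),
         min_length = sum(vapply(tokens, `[[`, integer(1), "min")),
         max_length = sum(vapply(tokens, `[[`, integer(1), "max"))),
    class = "compiled_motif")
}

# Tokenizer for the motif grammar.  Offsets in error messages are 0-based.
parse_motif_pattern <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern))
    abort("pattern must be a non-empty string")
  chars <- residues(pattern)
  tokens <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    off <- i - 1L
    if (ch %in% AA_ALPHABET) {
      tokens[[length(tokens) + 1L]] <-
        list(allowed = ch, wildcard = FALSE, min = 1L, max = 1L)
      i <- i + 1L
    } else if (ch %in% c("x", ".")) {
      tokens[[length(tokens) + 1L]] <-
        list(allowed = AA_ALPHABET, wildcard = TRUE, min = 1L, max = 1L)
      i <- i + 1L
    } else if (ch == "[") {
      close <- which(chars == "]" & seq_len(n) > i)
      if (!length(close))
        abort("pattern '%s': unbalanced '[' at offset %d", pattern, off)
      close <- close[1]
      body <- chars[(i + 1L):(close - 1L)]
      if (close == i + 1L)
        abort("pattern '%s': empty class at offset %d", pattern, off)
      negated <- body[1] == "^"
      if (negated) body <- body[-1]
      if (!length(body))
        abort("pattern '%s': empty class at offset %d", pattern, off)
      bad <- setdiff(body, AA_ALPHABET)
      if (length(bad))
        abort("pattern '%s': invalid class member(s) %s at offset %d",
              pattern, paste(bad, collapse = ", "), off)
      allowed <- if (negated) setdiff(AA_ALPHABET, body) else unique(body)
      if (!length(allowed))
        abort("pattern '%s': class at offset %d excludes every residue",
              pattern, off)
      tokens[[length(tokens) + 1L]] <-
        list(allowed = allowed, wildcard = FALSE, min = 1L, max = 1L)
      i <- close + 1L
    } else if (ch == "{") {
      if (!length(tokens))
        abort("pattern '%s': repetition with no preceding element at offset %d",
              pattern, off)
      close <- which(chars == "}" & seq_len(n) > i)
      if (!length(close))
        abort("pattern '%s': unbalanced '{' at offset %d", pattern, off)
      close <- close[1]
      body <- paste0(chars[(i + 1L):(close - 1L)], collapse = "")
      m <- regmatches(body, regexec("^([0-9]+),([0-9]+)$", body))[[1]]
      if (length(m) != 3L)
        abort("pattern '%s': malformed repetition '{%s}' at offset %d",
              pattern, body, off)
      lo <- as.integer(m[2]); hi <- as.integer(m[3])
      if (lo > hi)
        abort("pattern '%s': repetition bounds %d > %d at offset %d",
              pattern, lo, hi, off)
      if (hi > 10L)
        abort("pattern '%s': repetition upper bound %d exceeds 10 at offset %d",
              pattern, hi, off)
      last <- tokens[[length(tokens)]]
      if (last$min != 1L || last$max != 1L)
        abort("pattern '%s': double repetition at offset %d", pattern, off)
      last$min <- lo; last$max <- hi
      tokens[[length(tokens)]] <- last
      i <- close + 1L
    } else {
      abort("pattern '%s': unexpected character '%s' at offset %d",
            pattern, ch, off)
    }
  }
  if (!length(tokens)) abort("pattern '%s' contains no elements", pattern)
  tokens
}

token_regex <- function(tok) {
  base <- if (tok$wildcard) "." else paste0("[", paste0(tok$allowed, collapse = ""), "]")
  if (tok$min == 1L && tok$max == 1L) base
  else paste0(base, "{", tok$min, ",", tok$max, "}")
}

#' Define a degron motif bound to an E3 ligase
#'
#' @param motif_name Motif identifier (e.g. `"APC_DBox"`).
#' @param e3_ligase The recognizing E3 ubiquitin ligase.
#' @param pattern Consensus pattern under the grammar of [compile_motif()];
#'   the minimum match length must be at least 3 residues.
#' @return An object of class `degron_motif`.
#' @export
degron_motif <- function(motif_name, e3_ligase, pattern) {
  compiled <- compile_motif(pattern)
  if (compiled$min_length < 3L)
    abort("motif '%s': minimum match length %d is below 3",
          motif_name, compiled$min_length)
  structure(list(motif_name = motif_name, e3_ligase = e3_ligase,
                 pattern = pattern, compiled = compiled),
            class = "degron_motif")
}

#' @export
print.degron_motif <- function(x, ...) {
  cat(sprintf("<degron_motif> %s (%s): %s\n", x$motif_name, x$e3_ligase,
              x$pattern))
  invisible(x)
}

# Scan one sequence string with one compiled motif; returns start/end pairs.
scan_sequence <- function(seq, compiled) {
  m <- gregexpr(compiled$regex, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(0), end = integer(0)))
  starts <- as.integer(attr(m, "capture.start")[, 1])
  lens <- as.integer(attr(m, "capture.length")[, 1])
  keep <- lens > 0L
  data.frame(start = starts[keep], end = starts[keep] + lens[keep] - 1L)
}

#' Scan a proteome for degron motif matches
#'
#' Reports every maximal-position match at every offset: overlapping matches
#' are allowed and there is one match per (motif, start). With
#' `internal_only = TRUE` (the default), matches touching the first or the
#' last residue of the protein are discarded, restricting the scan to
#' internal motifs.
#'
#' @param proteome Proteome `data.frame` (see [read_proteome_fasta()]); a
#'   single-row proteome scans a single protein.
#' @param motifs A `degron_motif`, or a list of them (see
#'   [read_motif_table()]).
#' @param internal_only Drop matches touching either protein terminus.
#' @return A `data.frame` with columns `protein_id`, `motif_name`, `start`,
#'   `end`, `matched_seq`, sorted by (`protein_id`, `start`, `motif_name`).
#' @export
#' @examples
#' prot <- as_proteome(c(P1 = "MRAALQQVK"))
#' scan_proteome(prot, degron_motif("APC_DBox", "APC/C", "RxxLxx[LIVM]"))
scan_proteome <- function(proteome, motifs, internal_only = TRUE) {
  if (inherits(motifs, "degron_motif")) motifs <- list(motifs)
  out <- vector("list", nrow(proteome) * length(motifs))
  k <- 0L
  for (i in seq_len(nrow(proteome))) {
    seq <- proteome$sequence[i]
    len <- nchar(seq)
    for (mot in motifs) {
      hits <- scan_sequence(seq, mot$compiled)
      if (internal_only && nrow(hits))
        hits <- hits[hits$start > 1L & hits$end < len, , drop = FALSE]
      if (nrow(hits)) {
        k <- k + 1L
        out[[k]] <- data.frame(
          protein_id = proteome$protein_id[i],
          motif_name = mot$motif_name,
          start = hits$start, end = hits$end,
          matched_seq = substring(seq, hits$start, hits$end),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (k) do.call(rbind, out[seq_len(k)]) else
    data.frame(protein_id = character(0), motif_name = character(0),
               start = integer(0), end = integer(0),
               matched_seq = character(0), stringsAsFactors = FALSE)
  res <- unique(res)
  res <- res[order(res$protein_id, res$start, res$motif_name), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Correlation between per-protein match count and protein length
#'
#' The false-positive diagnostic used before and after classifier filtering:
#' raw motif matches tend to scale with protein length, while genuine degrons
#' do not, so effective filtering lowers this Pearson correlation.
#'
#' @param matches Match table from [scan_proteome()] (possibly filtered).
#' @param proteome Proteome `data.frame`; proteins without matches count 0.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
match_length_correlation <- function(matches, proteome) {
  if (nrow(proteome) < 3L) abort("at least 3 proteins are required")
  counts <- table(factor(matches$protein_id, levels = proteome$protein_id))
  counts <- as.numeric(counts)
  lengths <- nchar(proteome$sequence)
  if (stats::sd(counts) == 0 || stats::sd(lengths) == 0)
    abort("correlation undefined: zero variance in match counts or lengths")
  stats::cor(counts, lengths)
}
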