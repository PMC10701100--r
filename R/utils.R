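# Internal helpers shared across modules.

# Stop with a consistent prefix-free message built via sprintf.
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Validate a protein sequence string; returns the uppercased sequence.
check_sequence <- function(seq, id = "<sequence>") {
  seq <- toupper(seq)
  if (nchar(seq) < 1L)
    abort("protein '%s' has an empty sequence", id)
  bad <- setdiff(strsplit(seq, "", fixed = TRUE)[[1]],
                 c(AA_ALPHABET, AA_UNKNOWN))
  if (length(bad))
    abort("protein '%s' contains invalid residue characters: %s",
          id, paste(unique(bad), collapse = ", "))
  seq
}

# Split a sequence into a character vector of residues.
residues <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# Area under the ROC curve by the rank (Mann-Whitney) formula.
# labels: 0/1 vector; scores: numeric. Used as an internal diagnostic;
# tests cross-check it against an independent implementation.
roc_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg))
    abort("AUC requires both positive and negative labels")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Derive a stream of child seeds from a single integer seed, kept below 2^31.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Read a TSV with a header row, '#' comments, UTF-8; all columns character
# unless colClasses given.  Thin wrapper so every reader shares conventions.
read_tsv_file <- function(path, required_cols) {
  if (!file.exists(path)) abort("file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    abort("%s: missing required column(s): %s",
          path, paste(missing, collapse = ", "))
  df
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
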