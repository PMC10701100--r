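#' Amino-acid alphabets and physicochemical scales
#'
#' Constants shared across the package: the 20-letter amino-acid alphabet
#' (plus `"X"` for an unknown residue), the Kyte-Doolittle hydropathy scale,
#' formal side-chain charge at pH 7, and side-chain volumes (Angstrom^3,
#' Zamyatnin). The scale ranges used to normalize biochemical-change terms in
#' the mutation impact score are derived from these tables.
#'
#' @format `AA_ALPHABET` is a character vector of the 20 standard residues;
#'   `AA_HYDROPATHY`, `AA_CHARGE` and `AA_VOLUME` are named numeric vectors
#'   over that alphabet.
#' @name aa_tables
NULL

#' @rdname aa_tables
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname aa_tables
#' @export
AA_UNKNOWN <- "X"

#' @rdname aa_tables
#' @export
AA_HYDROPATHY <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3)

#' @rdname aa_tables
#' @export
AA_CHARGE <- c(
  A = 0, C = 0, D = -1, E = -1, F = 0,
  G = 0, H = 0, I = 0, K = 1, L = 0,
  M = 0, N = 0, P = 0, Q = 0, R = 1,
  S = 0, T = 0, V = 0, W = 0, Y = 0)

#' @rdname aa_tables
#' @export
AA_VOLUME <- c(
  A =  88.6, C = 108.5, D = 111.1, E = 138.4, F = 189.9,
  G =  60.1, H = 153.2, I = 166.7, K = 168.6, L = 166.7,
  M = 162.9, N = 114.1, P = 112.7, Q = 143.8, R = 173.4,
  S =  89.0, T = 116.1, V = 140.0, W = 227.8, Y = 193.6)

# Registry of per-residue annotation tracks accepted by the track reader and
# the feature aggregator.  domain_flag is 0/1; secondary-structure fractions
# (coil/helix/sheet) must sum to 1 per residue when all three are present.
TRACK_REGISTRY <- c("disorder", "accessibility", "conservation",
                    "coil", "helix", "sheet",
                    "rigidity", "stabilization", "domain_flag")

# Unit-interval tracks validated to lie in [0, 1] at load time.
UNIT_TRACKS <- c("disorder", "accessibility", "conservation")

# Names of the aggregated candidate features consumed by the classifier.
FEATURE_REGISTRY <- c("disorder", "accessibility", "coil", "helix", "sheet",
                      "rigidity", "stabilization", "conservation_flank_delta",
                      "domain_flag", "n_phospho", "n_ubiq",
                      "flank_lysine_count", "flank_lysine_min_dist",
                      "flank_lysine_present")

# Functional categories for degron-mapped missense mutations, in default
# precedence order (first matching rule wins; rewiring_network is the
# fallback).
MUTATION_CATEGORIES <- c("blocking_phospho", "blocking_ubiq", "altering_motif",
                         "substituting_flanking_lysine", "rewiring_network")

PTM_TYPES <- c("phosphorylation", "ubiquitination")
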