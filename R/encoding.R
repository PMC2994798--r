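#' Residue encoding schemes
#'
#' Builds one of the two residue-to-vector encodings used as network input.
#' Under the sparse scheme each residue maps to a 20-vector with
#' `sparse_hi` at its own index and `sparse_lo` elsewhere; under the blosum
#' scheme a residue maps to its BLOSUM50 row divided by `blosum_scale`.
#' The wildcard residue ("X") always encodes to the zero vector, which is
#' how unknown positions in benchmark proteins are handled.
#'
#' @param kind "sparse" or "blosum".
#' @param sparse_hi,sparse_lo Values for the sparse one-hot-like encoding.
#' @param blosum_scale Divisor applied to BLOSUM50 rows.
#' @param matrix Substitution matrix for the blosum kind; defaults to the
#'   packaged BLOSUM50.
#' @return An object of class `mhc2_scheme` holding the 21 x 20 lookup
#'   table (20 residues plus the wildcard row).
#' @export
#' @examples
#' sp <- encoding_scheme("sparse")
#' encode_residue("A", sp)[1]   # 0.9
encoding_scheme <- function(kind = c("sparse", "blosum"), sparse_hi = 0.9,
                            sparse_lo = 0.05, blosum_scale = 5,
                            matrix = NULL) {
  kind <- match.arg(kind)
  if (kind == "sparse") {
    enc <- base::matrix(sparse_lo, 20L, 20L)
    diag(enc) <- sparse_hi
  } else {
    if (is.null(matrix)) matrix <- blosum50()
    if (!all(AA_ALPHABET %in% rownames(matrix)))
      stop("substitution matrix must cover the 20 standard residues")
    enc <- matrix[AA_ALPHABET, AA_ALPHABET] / blosum_scale
  }
  enc <- rbind(enc, 0)  # wildcard row
  rownames(enc) <- c(AA_ALPHABET, AA_WILDCARD)
  structure(list(kind = kind, enc = enc, sparse_hi = sparse_hi,
                 sparse_lo = sparse_lo, blosum_scale = blosum_scale),
            class = "mhc2_scheme")
}

#' @export
print.mhc2_scheme <- function(x, ...) {
  cat("<mhc2_scheme>", x$kind, "encoding, 20 values per residue\n")
  invisible(x)
}

# Map residue characters to row indices of the scheme lookup table.
residue_index <- function(chars, scheme) {
  idx <- match(chars, rownames(scheme$enc))
  if (anyNA(idx))
    stop("illegal residue(s): ", paste(unique(chars[is.na(idx)]),
                                       collapse = ", "))
  idx
}

#' Encode one residue as 20 values
#'
#' @param aa Single residue character (or the wildcard "X", which yields
#'   the zero vector).
#' @param scheme An [encoding_scheme()].
#' @return Numeric vector of length 20.
#' @export
encode_residue <- function(aa, scheme) {
  stopifnot(inherits(scheme, "mhc2_scheme"), nchar(aa) == 1L)
  as.numeric(scheme$enc[residue_index(aa, scheme), ])
}

#' Logistic pair encoding of a scalar count
#'
#' Lengths (of the whole peptide and of each flanking region) enter the
#' network as the complementary pair (p, 1 - p) with
#' p = sigma((x - half_point) / slope).  Strictly monotone in x and bounded
#' in (0, 1), matching the output range of the logistic units.
#'
#' @param x Non-negative count.
#' @param half_point Value of x at which the pair is (0.5, 0.5).
#' @param slope Softness of the transition, in the same units as x.
#' @return Numeric vector of length 2.
#' @export
encode_scalar_pair <- function(x, half_point, slope) {
  p <- plogis((x - half_point) / slope)
  c(p, 1 - p)
}

#' Total network input length for a given pseudo-sequence length
#'
#' 20 values per core and pseudo residue, two 20-value flanking-region
#' summaries, 2 peptide-length inputs and 2 x 2 flank-length inputs:
#' 20 * (core_len + pseudo_len) + 44.  646 at the defaults (9-mer core,
#' 21-residue pseudo sequence).
#'
#' @param pseudo_len Pseudo-sequence length (default 21).
#' @param core_len Binding-core length (default 9).
#' @return Integer input length.
#' @export
input_length <- function(pseudo_len = 21L, core_len = CORE_LEN) {
  as.integer(20L * (core_len + pseudo_len) + 2L * 20L + 2L + 4L)
}

# Frozen input layout (0-based core offset `o`, peptide length L,
# pseudo length P):
#   [  1..180 ]  core residues o..o+8, 20 values each
#   [181..180+20P]  pseudo-sequence residues
#   [ +1..+20 ]  N-terminal PFR summary: mean encoding of up to `pfr_cap`
#                residues immediately N of the core (zero vector if none)
#   [ +1..+20 ]  C-terminal PFR summary, same rule on the C side
#   [ +1..+2  ]  logistic pair of L           (half_point 15, slope 2)
#   [ +1..+2  ]  logistic pair of N-PFR length (half_point 2, slope 1)
#   [ +1..+2  ]  logistic pair of C-PFR length
# PFR length features use the full (uncapped) flank lengths.

#' Encode a (peptide, core offset, allele) example
#'
#' Builds the full network input vector for one candidate binding core.
#' See the package vignette for the frozen block layout; at the defaults
#' the vector has 646 entries.
#'
#' @param peptide Peptide string (length >= 9).
#' @param offset 0-based start of the 9-mer core within the peptide.
#' @param pseudo MHC pseudo-sequence string.
#' @param scheme An [encoding_scheme()].
#' @param pfr_cap Maximum number of flank residues averaged into each PFR
#'   summary (default 3).
#' @param len_half,len_slope Logistic-pair parameters for peptide length.
#' @param pfr_half,pfr_slope Logistic-pair parameters for PFR lengths.
#' @return Numeric vector of length `input_length(nchar(pseudo))`.
#' @export
encode_example <- function(peptide, offset, pseudo, scheme, pfr_cap = 3L,
                           len_half = 15, len_slope = 2, pfr_half = 2,
                           pfr_slope = 1) {
  L <- nchar(peptide)
  if (L < CORE_LEN) stop("peptide shorter than the 9-residue core")
  if (offset < 0L || offset > L - CORE_LEN)
    stop("core offset ", offset, " out of range for a ", L, "-mer")
  encode_candidates(peptide, pseudo, scheme, pfr_cap = pfr_cap,
                    len_half = len_half, len_slope = len_slope,
                    pfr_half = pfr_half, pfr_slope = pfr_slope)[, offset + 1L]
}

#' Encode all candidate cores of one peptide as a matrix
#'
#' One column per 0-based core offset (length(peptide) - 8 columns); the
#' pseudo-sequence block is shared across columns.  This is the unit the
#' trainer and predictor operate on.
#'
#' @inheritParams encode_example
#' @return Numeric matrix, `input_length(nchar(pseudo))` rows.
#' @export
encode_candidates <- function(peptide, pseudo, scheme, pfr_cap = 3L,
                              len_half = 15, len_slope = 2, pfr_half = 2,
                              pfr_slope = 1) {
  L <- nchar(peptide)
  if (L < CORE_LEN) stop("peptide shorter than the 9-residue core")
  E <- scheme$enc[residue_index(strsplit(peptide, "")[[1]], scheme), ,
                  drop = FALSE]               # L x 20 per-residue encodings
  P <- scheme$enc[residue_index(strsplit(pseudo, "")[[1]], scheme), ,
                  drop = FALSE]
  pseudo_block <- as.numeric(t(P))
  len_pair <- encode_scalar_pair(L, len_half, len_slope)
  n_off <- L - CORE_LEN + 1L
  out <- base::matrix(0, nrow = 180L + length(pseudo_block) + 46L,
                      ncol = n_off)
  for (o in seq_len(n_off) - 1L) {
    core <- as.numeric(t(E[(o + 1L):(o + CORE_LEN), , drop = FALSE]))
    n_len <- o
    c_len <- L - CORE_LEN - o
    n_sum <- if (n_len > 0L)
      colMeans(E[max(1L, o - pfr_cap + 1L):o, , drop = FALSE]) else numeric(20L)
    c_sum <- if (c_len > 0L)
      colMeans(E[(o + CORE_LEN + 1L):min(L, o + CORE_LEN + pfr_cap), ,
                 drop = FALSE]) else numeric(20L)
    out[, o + 1L] <- c(core, pseudo_block, n_sum, c_sum, len_pair,
                       encode_scalar_pair(n_len, pfr_half, pfr_slope),
                       encode_scalar_pair(c_len, pfr_half, pfr_slope))
  }
  out
}
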