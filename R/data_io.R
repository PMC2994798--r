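#' Affinity transform between IC50 (nM) and the regression target
#'
#' Measured IC50 values are mapped onto the network's output range as
#' `1 - log(aff) / log(base)` and clamped to \[0, 1\]; affinities at or
#' above `base` (default 15,000 nM) therefore score 0 and affinities of
#' 1 nM or stronger score 1.  `target_to_ic50()` is the inverse
#' `base^(1 - target)`.
#'
#' @param affinity_nM Positive IC50 values in nM.
#' @param target Transformed values in \[0, 1\].
#' @param base Logarithm base of the transform in nM; 15,000 by default,
#'   50,000 for compatibility with older data sets.
#' @return Numeric vector.
#' @export
#' @examples
#' ic50_to_target(c(1, 500, 15000))   # 1, ~0.354, 0
#' target_to_ic50(0)                  # 15000
ic50_to_target <- function(affinity_nM, base = 15000) {
  stopifnot(base > 1, all(affinity_nM > 0))
  pmin(pmax(1 - log(affinity_nM) / log(base), 0), 1)
}

#' @rdname ic50_to_target
#' @export
target_to_ic50 <- function(target, base = 15000) {
  stopifnot(base > 1)
  base^(1 - target)
}

valid_peptide <- function(x) {
  grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"), x)
}

#' Read quantitative peptide-binding data
#'
#' Reads a tab-separated file with columns `peptide`, `allele`,
#' `affinity_nM` and computes the transformed regression target for each
#' record.  Records are rejected (and counted) when the peptide is shorter
#' than 9 residues, contains characters outside the 20-residue alphabet,
#' or the affinity is missing or non-positive.
#'
#' @param path Path to the TSV file (header required).
#' @param base Transform base passed to [ic50_to_target()].
#' @return A data.frame with columns peptide, allele, affinity_nM, target,
#'   carrying attributes `n_rejected` and `rejected_rows` (input row
#'   numbers).
#' @export
read_binding_data <- function(path, base = 15000) {
  if (!file.exists(path)) stop("binding-data file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   comment.char = "", stringsAsFactors = FALSE)
  need <- c("peptide", "allele", "affinity_nM")
  if (!all(need %in% names(df)))
    stop("binding-data file must have columns ", paste(need, collapse = ", "))
  df <- df[need]
  df$peptide <- toupper(df$peptide)
  df$affinity_nM <- suppressWarnings(as.numeric(df$affinity_nM))
  bad <- !valid_peptide(df$peptide) | nchar(df$peptide) < CORE_LEN |
    is.na(df$affinity_nM) | df$affinity_nM <= 0
  if (any(bad))
    message(sum(bad), " record(s) rejected at rows: ",
            paste(head(which(bad), 20L), collapse = ", "))
  if (all(bad)) stop("all ", nrow(df), " records rejected")
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out$target <- ic50_to_target(out$affinity_nM, base)
  attr(out, "n_rejected") <- sum(bad)
  attr(out, "rejected_rows") <- which(bad)
  attr(out, "base") <- base
  out
}

#' Read an allele pseudo-sequence table
#'
#' Two whitespace-separated columns: allele name, pseudo sequence.  All
#' pseudo sequences must share one length; a duplicated allele name keeps
#' the last entry with a warning.
#'
#' @param path Path to the table.
#' @return Named character vector mapping allele name to pseudo sequence.
#' @export
read_pseudosequences <- function(path) {
  if (!file.exists(path)) stop("pseudo-sequence file not found: ", path)
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("allele", "pseudo"),
                   colClasses = "character")
  if (nrow(df) == 0L) stop("empty pseudo-sequence file: ", path)
  df$pseudo <- toupper(df$pseudo)
  len <- nchar(df$pseudo)
  if (length(unique(len)) > 1L) {
    ref <- len[1L]  # first entry sets the expected length
    stop("inconsistent pseudo-sequence lengths: allele ",
         df$allele[which(len != ref)[1]], " has length ",
         len[len != ref][1], ", expected ", ref)
  }
  ok <- grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), AA_WILDCARD,
                     "]+$"), df$pseudo)
  if (!all(ok))
    stop("illegal residues in pseudo sequence of allele ",
         df$allele[!ok][1])
  if (anyDuplicated(df$allele)) {
    warning("duplicated allele name(s): ",
            paste(unique(df$allele[duplicated(df$allele)]), collapse = ", "),
            " (last entry wins)")
    df <- df[!duplicated(df$allele, fromLast = TRUE), , drop = FALSE]
  }
  setNames(df$pseudo, df$allele)
}

#' Read protein sequences from FASTA
#'
#' Headers are truncated at the first whitespace; sequences are
#' uppercased.  Duplicate identifiers are an error.  Sequences containing
#' the wildcard "X" are accepted and flagged in the `has_wildcard`
#' attribute (such positions encode as zero vectors downstream).
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector of protein sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- setNames(toupper(as.character(ss)), ids)
  attr(seqs, "has_wildcard") <- ids[grepl(AA_WILDCARD, seqs, fixed = TRUE)]
  seqs
}

#' Write and re-read prediction tables
#'
#' Tab-separated with columns peptide, allele, score, predicted_nM,
#' core_offset (0-based), core_sequence.  Numeric columns are written at a
#' fixed decimal precision so that write-then-read round-trips exactly.
#'
#' @param results Data.frame as returned by [predict_binding()].
#' @param path Output path.
#' @param digits Decimal places for score and predicted_nM.
#' @return `write_predictions()` returns `path` invisibly;
#'   `read_predictions()` the data.frame.
#' @export
write_predictions <- function(results, path, digits = 6L) {
  cols <- c("peptide", "allele", "score", "predicted_nM", "core_offset",
            "core_seq")
  stopifnot(all(cols %in% names(results)))
  out <- results[cols]
  out$score <- round(out$score, digits)
  out$predicted_nM <- round(out$predicted_nM, digits)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# mhc2align predictions; core_offset is 0-based",
               paste(cols, collapse = "\t")), con)
  if (nrow(out))
    write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE,
             colClasses = c("character", "character", "numeric", "numeric",
                            "integer", "character"))
}
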