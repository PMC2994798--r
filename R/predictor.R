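#' Predict binding of peptides to an MHC class II allele
#'
#' Scores each (peptide, allele) pair with every network in the ensemble:
#' a network reports its best-scoring 9-mer core and the score at that
#' core; the ensemble score is the arithmetic mean of the per-network
#' scores (on the transformed \[0, 1\] scale, converted to nM afterwards)
#' and the reported core is the majority vote over per-network core
#' offsets, ties broken by higher mean score then smaller offset.  Any
#' allele with a pseudo sequence can be queried, including alleles absent
#' from training — the pan-specific use case.
#'
#' @param ensemble An `mhc2_ensemble` (or `mhc2_cv`, whose folds are
#'   pooled automatically).
#' @param peptides Character vector of peptides (each length >= 9).
#' @param alleles Allele name(s): one per peptide, recycled if scalar.
#' @return Data.frame with one row per pair: peptide, allele, score
#'   (mean transformed affinity in \[0, 1\]), predicted_nM, core_offset
#'   (0-based), core_seq.
#' @export
predict_binding <- function(ensemble, peptides, alleles) {
  if (inherits(ensemble, "mhc2_cv")) ensemble <- pooled_ensemble(ensemble)
  stopifnot(inherits(ensemble, "mhc2_ensemble"), length(peptides) >= 0L)
  if (length(peptides) == 0L)
    return(data.frame(peptide = character(), allele = character(),
                      score = numeric(), predicted_nM = numeric(),
                      core_offset = integer(), core_seq = character(),
                      stringsAsFactors = FALSE))
  alleles <- rep_len(alleles, length(peptides))
  unknown <- setdiff(unique(alleles), names(ensemble$pseudo))
  if (length(unknown)) {
    near <- names(ensemble$pseudo)[order(adist(unknown[1L],
                                               names(ensemble$pseudo)))]
    stop("no pseudo sequence for allele ", unknown[1L],
         "; nearest known alleles: ",
         paste(head(near, 3L), collapse = ", "))
  }
  if (any(nchar(peptides) < CORE_LEN))
    stop("peptide(s) shorter than the 9-residue core")
  cfg <- ensemble$config
  out <- data.frame(peptide = peptides, allele = alleles,
                    score = NA_real_, predicted_nM = NA_real_,
                    core_offset = NA_integer_, core_seq = NA_character_,
                    stringsAsFactors = FALSE)
  kinds <- unique(vapply(ensemble$networks, `[[`, "", "scheme_kind"))
  schemes <- lapply(setNames(kinds, kinds), scheme_from_config, cfg = cfg)
  for (al in unique(alleles)) {
    idx <- which(alleles == al)
    rec <- data.frame(peptide = peptides[idx], allele = al,
                      stringsAsFactors = FALSE)
    cands <- lapply(schemes, function(s)
      precompute_candidates(rec, ensemble$pseudo, s, cfg))
    ev <- ensemble_vote(ensemble$networks, cands, seq_len(nrow(rec)), cfg)
    out$score[idx] <- ev$score
    out$core_offset[idx] <- ev$offset
  }
  out$predicted_nM <- target_to_ic50(out$score, cfg$base)
  out$core_seq <- substring(out$peptide, out$core_offset + 1L,
                            out$core_offset + CORE_LEN)
  out
}

#' @rdname predict_binding
#' @param pairs Data.frame with columns peptide and allele.
#' @export
predict_batch <- function(ensemble, pairs) {
  stopifnot(all(c("peptide", "allele") %in% names(pairs)))
  predict_binding(ensemble, pairs$peptide, pairs$allele)
}

#' @rdname predict_binding
#' @param object An `mhc2_ensemble`.
#' @param newdata Data.frame with columns peptide and allele.
#' @param ... Ignored.
#' @export
predict.mhc2_ensemble <- function(object, newdata, ...) {
  predict_batch(object, newdata)
}
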