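#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic: the probability
#' that a randomly drawn positive scores above a randomly drawn negative,
#' with ties counted one half.  1 is perfect ranking, 0.5 random.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Logical (or 0/1) class labels.
#' @return AUC in \[0, 1\], or `NA` with a warning when only one class is
#'   present (undefined; callers exclude such cases from averages).
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  np <- sum(labels)
  nn <- sum(!labels)
  if (np == 0L || nn == 0L) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores)  # midranks implement the half-tie convention
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' Pearson correlation coefficient
#'
#' @param pred,meas Numeric vectors of equal length (n >= 2).
#' @return PCC in \[-1, 1\], or `NA` with a warning when either input has
#'   zero variance.
#' @export
pcc <- function(pred, meas) {
  stopifnot(length(pred) == length(meas), length(pred) >= 2L)
  if (stats::sd(pred) == 0 || stats::sd(meas) == 0) {
    warning("PCC undefined: zero variance")
    return(NA_real_)
  }
  cor(pred, meas)
}

#' Per-allele evaluation of predictions
#'
#' Joins predictions to measured records by (peptide, allele), classifies
#' binders at `threshold_nM` (IC50 at or below the threshold, default
#' 500 nM) and reports AUC and PCC per allele plus unweighted
#' (macro) averages across alleles.  PCC compares the prediction score to
#' the transformed measured affinity.  Alleles with a single class are
#' flagged (`NA` AUC) and excluded from the averaged AUC.
#'
#' @param predictions Data.frame with peptide, allele, score (as from
#'   [predict_binding()] or the `cv_predictions` of [train_ensemble()]).
#' @param records Data.frame with peptide, allele, affinity_nM, target.
#' @param threshold_nM Binder threshold in nM.
#' @return List with `per_allele` (data.frame: allele, n, n_binders, auc,
#'   pcc) and `average` (named vector of macro-averaged auc and pcc).
#' @export
evaluate_per_allele <- function(predictions, records, threshold_nM = 500) {
  key <- function(d) paste(d$peptide, d$allele, sep = "\r")
  m <- match(key(records), key(predictions))
  if (anyNA(m)) stop(sum(is.na(m)), " record(s) without a prediction")
  records$score <- predictions$score[m]
  rows <- lapply(split(records, records$allele), function(d) {
    lab <- d$affinity_nM <= threshold_nM
    a <- if (any(lab) && !all(lab)) auc(d$score, lab) else {
      warning("allele ", d$allele[1L], ": single class, AUC excluded")
      NA_real_
    }
    p <- if (nrow(d) >= 2L && stats::sd(d$target) > 0 &&
             stats::sd(d$score) > 0) pcc(d$score, d$target) else NA_real_
    data.frame(allele = d$allele[1L], n = nrow(d), n_binders = sum(lab),
               auc = a, pcc = p, stringsAsFactors = FALSE)
  })
  per_allele <- do.call(rbind, rows)
  rownames(per_allele) <- NULL
  list(per_allele = per_allele,
       average = c(auc = mean(per_allele$auc, na.rm = TRUE),
                   pcc = mean(per_allele$pcc, na.rm = TRUE)))
}
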