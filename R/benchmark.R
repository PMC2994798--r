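#' Leave-one-allele-out benchmark
#'
#' Removes every record of the target allele from training, trains a full
#' ensemble (`length(schemes) * n_seeds` networks) on the remaining
#' alleles, and evaluates on the held-out allele's records.  Only the
#' target's pseudo sequence is available at prediction time, so this
#' measures pan-specific extrapolation to an uncharacterized molecule.
#'
#' @param records Data.frame with peptide, allele, affinity_nM, target.
#' @param allele Target allele name.
#' @param allele_table Named pseudo-sequence vector.
#' @param cfg A [train_config()] (its `n_folds` is not used here: a single
#'   training on all non-target records).
#' @param threshold_nM Binder threshold for the AUC.
#' @param verbose Print progress.
#' @return List with `auc`, `pcc`, `n`, `n_binders`, and the per-record
#'   `predictions` data.frame.
#' @export
loo_allele <- function(records, allele, allele_table, cfg = train_config(),
                       threshold_nM = 500, verbose = FALSE) {
  test <- records[records$allele == allele, , drop = FALSE]
  if (nrow(test) == 0L) stop("no records for allele ", allele)
  train <- records[records$allele != allele, , drop = FALSE]
  if (nrow(train) == 0L) stop("no training records left")
  ens <- train_flat_ensemble(train, allele_table, cfg, verbose = verbose)
  pred <- predict_binding(ens, test$peptide, test$allele)
  res <- eval_result(pred$score, test, threshold_nM, predictions = pred)
  res$n_train <- nrow(train)
  res$train_alleles <- unique(train$allele)
  res$ensemble <- ens
  res
}

#' Leave-one-peptide-out benchmark for one allele
#'
#' Evaluates the target allele while removing, for every evaluation
#' peptide, all measurements of that peptide sequence against any allele
#' from training (peptides are often measured on several molecules, which
#' otherwise inflates leave-one-allele-out performance).  When the target
#' allele has more than `max_full` data points this runs as an inner
#' 3-fold cross-validation over its peptides (partitioned by shared-9-mer
#' linkage); otherwise a single round excludes all of them at once.
#'
#' @inheritParams loo_allele
#' @param inner_folds Inner folds used above the size cutoff.
#' @param max_full Data-point cutoff (default 200) above which the inner
#'   cross-validation is used.
#' @return As [loo_allele()], with an extra `n_rounds` element.
#' @export
loo_peptide <- function(records, allele, allele_table, cfg = train_config(),
                        threshold_nM = 500, inner_folds = 3L,
                        max_full = 200L, verbose = FALSE) {
  test_all <- records[records$allele == allele, , drop = FALSE]
  if (nrow(test_all) == 0L) stop("no records for allele ", allele)
  part <- if (nrow(test_all) > max_full)
    partition_data(test_all, inner_folds, seed = cfg$master_seed)
  else rep.int(1L, nrow(test_all))
  pred <- test_all[c("peptide", "allele")]
  pred$score <- NA_real_
  rounds <- list()
  for (p in unique(part)) {
    eval_rows <- which(part == p)
    excluded <- unique(test_all$peptide[eval_rows])
    train <- records[!(records$peptide %in% excluded), , drop = FALSE]
    if (nrow(train) == 0L) stop("no training records left")
    ens <- train_flat_ensemble(train, allele_table, cfg, verbose = verbose)
    pr <- predict_binding(ens, test_all$peptide[eval_rows], allele)
    pred$score[eval_rows] <- pr$score
    rounds[[length(rounds) + 1L]] <-
      list(eval_rows = eval_rows, excluded_peptides = excluded,
           n_train = nrow(train),
           train_peptides = unique(train$peptide))
  }
  res <- eval_result(pred$score, test_all, threshold_nM, predictions = pred)
  res$n_rounds <- length(unique(part))
  res$rounds <- rounds
  res
}

# One ensemble trained on everything (no outer folds); fold id 0 in the
# seed spread keeps these networks distinct from cross-validation ones.
train_flat_ensemble <- function(train, allele_table, cfg, verbose = FALSE) {
  schemes <- lapply(cfg$schemes, scheme_from_config, cfg = cfg)
  names(schemes) <- cfg$schemes
  nets <- list()
  for (si in seq_along(cfg$schemes)) {
    cands <- precompute_candidates(train, allele_table, schemes[[si]], cfg)
    for (k in seq_len(cfg$n_seeds)) {
      nets[[length(nets) + 1L]] <-
        train_one(train, allele_table, schemes[[si]],
                  network_seed(cfg$master_seed, 0L, si, k), cfg,
                  cands = cands)
      if (verbose) message("  trained ", cfg$schemes[si], " seed ", k)
    }
  }
  new_ensemble(nets, cfg, allele_table)
}

eval_result <- function(scores, records, threshold_nM, predictions = NULL) {
  lab <- records$affinity_nM <= threshold_nM
  list(auc = if (any(lab) && !all(lab)) auc(scores, lab) else NA_real_,
       pcc = pcc(scores, records$target),
       n = nrow(records), n_binders = sum(lab),
       predictions = predictions)
}

#' Source-protein overlapping-window ligand benchmark
#'
#' For every (protein, ligand, allele) triple the source protein is split
#' into all overlapping windows of the ligand's length; every window whose
#' sequence is identical to the annotated ligand is a positive (repeated
#' occurrences count) and all other windows are negatives — a stringent
#' rule, since suboptimal windows sharing the binding core are counted as
#' negatives.  Performance is the AUC per ligand, aggregated per ligand
#' (mean over all), per allele (mean of within-allele means) and per
#' ligand length.
#'
#' @param proteins Named character vector of protein sequences (e.g. from
#'   [read_fasta()]).
#' @param ligands Data.frame with columns protein_id, ligand, allele.
#' @param scorer An `mhc2_ensemble`/`mhc2_cv`, or a function
#'   `function(peptides, allele)` returning one score per peptide (higher
#'   = stronger predicted binding).
#' @param length_filter Inclusive \[min, max\] ligand-length window;
#'   ligands outside it are excluded and counted (`NULL` disables).
#' @return List with `per_ligand` (protein_id, ligand, allele, length,
#'   n_windows, n_pos, auc), `mean_per_ligand`, `per_allele`,
#'   `mean_per_allele`, `per_length`, `n_length_excluded` and `skipped`
#'   (ligands absent from their protein).
#' @export
ligand_benchmark <- function(proteins, ligands, scorer,
                             length_filter = c(9L, 24L)) {
  stopifnot(all(c("protein_id", "ligand", "allele") %in% names(ligands)))
  score_fun <- if (is.function(scorer)) scorer else
    function(peptides, allele) predict_binding(scorer, peptides, allele)$score
  len <- nchar(ligands$ligand)
  n_excluded <- 0L
  if (!is.null(length_filter)) {
    keep <- len >= length_filter[1L] & len <= length_filter[2L]
    n_excluded <- sum(!keep)
    if (n_excluded)
      message(n_excluded, " ligand(s) outside length window [",
              length_filter[1L], ", ", length_filter[2L], "] excluded")
    ligands <- ligands[keep, , drop = FALSE]
  }
  rows <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(ligands))) {
    pid <- ligands$protein_id[i]
    lig <- ligands$ligand[i]
    if (!pid %in% names(proteins)) {
      message("protein ", pid, " not found; ligand skipped")
      skipped <- c(skipped, lig)
      next
    }
    prot <- proteins[[pid]]
    l <- nchar(lig)
    L <- nchar(prot)
    if (L < l || !grepl(lig, prot, fixed = TRUE)) {
      message("ligand ", lig, " not a substring of protein ", pid,
              "; skipped")
      skipped <- c(skipped, lig)
      next
    }
    windows <- substring(prot, seq_len(L - l + 1L), l:L)
    pos <- windows == lig
    sc <- score_fun(windows, ligands$allele[i])
    rows[[length(rows) + 1L]] <-
      data.frame(protein_id = pid, ligand = lig,
                 allele = ligands$allele[i], length = l,
                 n_windows = length(windows), n_pos = sum(pos),
                 auc = auc(sc, pos), stringsAsFactors = FALSE)
  }
  per_ligand <- do.call(rbind, rows)
  if (is.null(per_ligand)) stop("no scorable ligands")
  by_allele <- vapply(split(per_ligand$auc, per_ligand$allele), mean,
                      numeric(1))
  by_len <- vapply(split(per_ligand$auc, per_ligand$length), mean,
                   numeric(1))
  list(per_ligand = per_ligand,
       mean_per_ligand = mean(per_ligand$auc),
       per_allele = data.frame(allele = names(by_allele),
                               auc = unname(by_allele),
                               stringsAsFactors = FALSE),
       mean_per_allele = mean(by_allele),
       per_length = data.frame(length = as.integer(names(by_len)),
                               auc = unname(by_len)),
       n_length_excluded = n_excluded, skipped = skipped)
}
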