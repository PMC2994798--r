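#' Training configuration
#'
#' Collects every tunable of ensemble training.  Defaults are the
#' published operating point: 500 training cycles, 5-fold cross-validation,
#' 40 hidden neurons and 2 encoding schemes x 10 random restarts, i.e. 20
#' networks per training/test configuration.
#'
#' @param n_cycles Training cycles; each cycle visits every record once,
#'   re-identifying its core before the weight update.
#' @param n_seeds Random restarts per encoding scheme.
#' @param schemes Character vector of encoding-scheme kinds.
#' @param n_hidden Hidden units.
#' @param n_folds Cross-validation folds.
#' @param learning_rate Online gradient-descent step size.
#' @param base Affinity-transform base in nM.
#' @param master_seed Seed from which all network seeds and the fold
#'   partition derive.
#' @param w0 Half-width of the uniform weight initialisation.
#' @param pfr_cap,len_half,len_slope,pfr_half,pfr_slope Encoding
#'   parameters, see [encode_example()].
#' @param sparse_hi,sparse_lo,blosum_scale Residue-encoding parameters,
#'   see [encoding_scheme()].
#' @return An object of class `mhc2_config`.
#' @export
train_config <- function(n_cycles = 500L, n_seeds = 10L,
                         schemes = c("sparse", "blosum"), n_hidden = 40L,
                         n_folds = 5L, learning_rate = 0.05, base = 15000,
                         master_seed = 1L, w0 = 0.1, pfr_cap = 3L,
                         len_half = 15, len_slope = 2, pfr_half = 2,
                         pfr_slope = 1, sparse_hi = 0.9, sparse_lo = 0.05,
                         blosum_scale = 5) {
  stopifnot(n_cycles >= 0L, n_folds >= 2L, n_seeds >= 1L,
            length(schemes) >= 1L, all(schemes %in% c("sparse", "blosum")),
            learning_rate >= 0, base > 1)
  structure(as.list(environment()), class = "mhc2_config")
}

#' @export
print.mhc2_config <- function(x, ...) {
  cat("<mhc2_config>", x$n_cycles, "cycles,", x$n_folds, "folds,",
      length(x$schemes), "scheme(s) x", x$n_seeds, "seed(s),",
      x$n_hidden, "hidden, lr", x$learning_rate, ", base", x$base, "nM\n")
  invisible(x)
}

scheme_from_config <- function(kind, cfg) {
  encoding_scheme(kind, sparse_hi = cfg$sparse_hi, sparse_lo = cfg$sparse_lo,
                  blosum_scale = cfg$blosum_scale)
}

# Seed of network k (1..n_seeds) of scheme s (1..) in fold f: a documented
# deterministic spread of the master seed, kept well below 2^31.
network_seed <- function(master_seed, fold, scheme_idx, k) {
  as.integer(master_seed + 100000L * fold + 10000L * scheme_idx + k)
}

# Stack the candidate-core encodings of all records into one matrix
# (records own contiguous column ranges; start is 0-based for the C++
# side).  This is the memory/speed trade the trainer lives on: encodings
# are computed once and sliced per fold.
precompute_candidates <- function(records, allele_table, scheme, cfg) {
  missing <- setdiff(unique(records$allele), names(allele_table))
  if (length(missing))
    stop("allele(s) without pseudo sequence: ", paste(missing, collapse = ", "))
  noff <- nchar(records$peptide) - CORE_LEN + 1L
  ni <- input_length(nchar(allele_table[[1]]))
  X <- base::matrix(0, ni, sum(noff))
  pos <- 0L
  for (i in seq_len(nrow(records))) {
    X[, pos + seq_len(noff[i])] <-
      encode_candidates(records$peptide[i], allele_table[[records$allele[i]]],
                        scheme, pfr_cap = cfg$pfr_cap, len_half = cfg$len_half,
                        len_slope = cfg$len_slope, pfr_half = cfg$pfr_half,
                        pfr_slope = cfg$pfr_slope)
    pos <- pos + noff[i]
  }
  list(X = X, start = c(0L, cumsum(noff))[seq_along(noff)], noff = noff)
}

#' Identify the best-scoring binding core of a peptide
#'
#' Evaluates every 9-mer window of the peptide under one network and
#' returns the highest-scoring offset; ties go to the smallest offset.
#'
#' @param net An `mhc2_network`.
#' @param peptide Peptide string (length >= 9).
#' @param pseudo Pseudo sequence of the allele.
#' @param scheme An [encoding_scheme()] matching the network.
#' @param cfg An [train_config()] supplying encoding parameters.
#' @return List with `offset` (0-based) and `score`.
#' @export
find_best_core <- function(net, peptide, pseudo, scheme,
                           cfg = train_config()) {
  X <- encode_candidates(peptide, pseudo, scheme, pfr_cap = cfg$pfr_cap,
                         len_half = cfg$len_half, len_slope = cfg$len_slope,
                         pfr_half = cfg$pfr_half, pfr_slope = cfg$pfr_slope)
  res <- cpp_best_core(t(net$w1), net$b1, net$w2, net$b2, X, 0L, ncol(X))
  list(offset = res$offset[1L], score = res$score[1L])
}

#' Train one network by concurrent core alignment
#'
#' Runs the two-step procedure for `cfg$n_cycles` cycles: records are
#' visited in a fresh random order each cycle; each visit first
#' re-identifies the record's best-scoring 9-mer core under the current
#' weights, then applies one backpropagation step at that core against the
#' record's transformed-affinity target.  Fully deterministic given
#' (records, seed, cfg).
#'
#' @param records Data.frame with columns peptide, allele, target (e.g.
#'   from [read_binding_data()] or [generate_records()]).
#' @param allele_table Named pseudo-sequence vector covering every allele
#'   in `records`.
#' @param scheme Scheme kind ("sparse"/"blosum") or an
#'   [encoding_scheme()].
#' @param seed Integer seed controlling initial weights and visit orders.
#' @param cfg A [train_config()].
#' @param cands Optional precomputed candidate encodings (internal reuse).
#' @param trace_every Record the mean squared error at the currently
#'   assigned cores every this many cycles (0 = never); stored as
#'   `net$mse_trace`.
#' @return A trained `mhc2_network`.
#' @export
train_one <- function(records, allele_table, scheme = "sparse", seed = 1L,
                      cfg = train_config(), cands = NULL, trace_every = 0L) {
  if (is.character(scheme)) scheme <- scheme_from_config(scheme, cfg)
  if (is.null(cands))
    cands <- precompute_candidates(records, allele_table, scheme, cfg)
  n <- nrow(records)
  net <- init_network(nrow(cands$X), cfg$n_hidden, seed, w0 = cfg$w0,
                      scheme_kind = scheme$kind)
  if (cfg$n_cycles == 0L) return(net)
  # visit orders are pre-drawn on a seed offset from the weight seed so the
  # two streams never alias
  order0 <- withr::with_seed(seed + 500009L, {
    vapply(seq_len(cfg$n_cycles), function(i) sample.int(n), integer(n))
  }) - 1L
  fit <- cpp_train_nnalign(t(net$w1), net$b1, net$w2, net$b2, cands$X,
                           cands$start, cands$noff, records$target,
                           base::matrix(as.integer(order0), n, cfg$n_cycles),
                           cfg$learning_rate, as.integer(trace_every))
  net$w1 <- t(fit$W1t)
  net$b1 <- as.numeric(fit$b1)
  net$w2 <- as.numeric(fit$w2)
  net$b2 <- as.numeric(fit$b2)
  net$mse_trace <- as.numeric(fit$mse_trace)
  net
}

# -- data partitioning --------------------------------------------------

# Union-find with path halving; cluster peptides that share any identical
# motif_len-mer (single linkage), an overlap-minimising stand-in for the
# common-motif partitioning used with the published data sets.
shared_kmer_clusters <- function(peptides, motif_len = 9L) {
  n <- length(peptides)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  kmers <- lapply(peptides, function(p) {
    L <- nchar(p)
    unique(substring(p, seq_len(L - motif_len + 1L),
                     motif_len:L))
  })
  idx <- rep.int(seq_len(n), lengths(kmers))
  for (grp in split(idx, unlist(kmers))) {
    if (length(grp) > 1L) {
      r <- find(grp[1L])
      for (j in grp[-1L]) {
        rj <- find(j)
        if (rj != r) parent[rj] <- r
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Overlap-aware cross-validation partition
#'
#' Clusters peptides by single linkage on shared 9-mers (two peptides that
#' share any identical 9-mer always land in the same fold, as do their
#' transitive neighbours) and deals the clusters, largest first, onto the
#' currently smallest fold.  Deterministic given `seed`, which only breaks
#' ordering ties between equal-sized clusters.
#'
#' @param records Data.frame with a `peptide` column (one row per record;
#'   duplicated peptide sequences always co-locate).
#' @param n_folds Number of folds.
#' @param motif_len Shared-motif length defining linkage (default 9).
#' @param seed Integer seed.
#' @return Integer vector of fold labels (1..n_folds) per record.
#' @export
partition_data <- function(records, n_folds = 5L, motif_len = 9L, seed = 1L) {
  peptides <- unique(records$peptide)
  comp <- shared_kmer_clusters(peptides, motif_len)
  clusters <- split(peptides, comp)
  if (n_folds > length(clusters))
    stop(n_folds, " folds requested but only ", length(clusters),
         " linkage clusters exist")
  counts <- table(records$peptide)
  sizes <- vapply(clusters, function(p) sum(counts[p]), numeric(1))
  ord <- withr::with_seed(seed, {
    o <- sample.int(length(sizes))          # random tie order
    o[order(sizes[o], decreasing = TRUE)]   # then largest first (stable)
  })
  load <- numeric(n_folds)
  pep_fold <- integer(0)
  pep_names <- character(0)
  for (ci in ord) {
    f <- which.min(load)
    load[f] <- load[f] + sizes[ci]
    pep_fold <- c(pep_fold, rep.int(f, length(clusters[[ci]])))
    pep_names <- c(pep_names, clusters[[ci]])
  }
  unname(setNames(pep_fold, pep_names)[records$peptide])
}

# -- ensembles ----------------------------------------------------------

new_ensemble <- function(networks, cfg, allele_table, fold = NA_integer_) {
  structure(list(networks = networks, config = cfg,
                 pseudo = allele_table, fold = fold),
            class = "mhc2_ensemble")
}

#' @export
print.mhc2_ensemble <- function(x, ...) {
  cat("<mhc2_ensemble>", length(x$networks), "network(s),",
      length(x$pseudo), "allele pseudo sequence(s)\n")
  invisible(x)
}

#' Train the full cross-validated ensemble
#'
#' Partitions the records with [partition_data()], then for every fold
#' trains `length(schemes) * n_seeds` networks on the remaining folds and
#' predicts the held-out fold with that fold's ensemble, so the
#' cross-validated predictions cover every record exactly once.
#'
#' @param records Data.frame with columns peptide, allele, affinity_nM,
#'   target.
#' @param allele_table Named pseudo-sequence vector.
#' @param cfg A [train_config()].
#' @param verbose Print per-fold progress.
#' @return An object of class `mhc2_cv`: list with `ensembles` (one
#'   `mhc2_ensemble` per fold), `cv_predictions` (one row per record:
#'   score, predicted_nM, core_offset, core_seq, fold), and `fold`
#'   (the partition labels).
#' @export
train_ensemble <- function(records, allele_table, cfg = train_config(),
                           verbose = FALSE) {
  folds <- partition_data(records, cfg$n_folds, seed = cfg$master_seed)
  schemes <- lapply(cfg$schemes, scheme_from_config, cfg = cfg)
  names(schemes) <- cfg$schemes
  cands <- lapply(schemes, function(s)
    precompute_candidates(records, allele_table, s, cfg))
  pred <- records[c("peptide", "allele", "affinity_nM", "target")]
  pred$score <- NA_real_
  pred$core_offset <- NA_integer_
  pred$fold <- folds
  ensembles <- vector("list", cfg$n_folds)
  for (f in seq_len(cfg$n_folds)) {
    train_idx <- which(folds != f)
    test_idx <- which(folds == f)
    nets <- list()
    for (si in seq_along(cfg$schemes)) {
      sub <- slice_candidates(cands[[si]], train_idx)
      for (k in seq_len(cfg$n_seeds)) {
        seed <- network_seed(cfg$master_seed, f, si, k)
        nets[[length(nets) + 1L]] <-
          train_one(records[train_idx, , drop = FALSE], allele_table,
                    schemes[[si]], seed, cfg, cands = sub)
      }
    }
    ensembles[[f]] <- new_ensemble(nets, cfg, allele_table, fold = f)
    if (length(test_idx)) {
      ev <- ensemble_vote(nets, cands, test_idx, cfg)
      pred$score[test_idx] <- ev$score
      pred$core_offset[test_idx] <- ev$offset
    }
    if (verbose)
      message("fold ", f, ": trained ", length(nets), " network(s) on ",
              length(train_idx), " records")
  }
  pred$predicted_nM <- target_to_ic50(pred$score, cfg$base)
  pred$core_seq <- substring(pred$peptide, pred$core_offset + 1L,
                             pred$core_offset + CORE_LEN)
  structure(list(ensembles = ensembles, cv_predictions = pred,
                 fold = folds, config = cfg, pseudo = allele_table),
            class = "mhc2_cv")
}

#' @export
print.mhc2_cv <- function(x, ...) {
  cat("<mhc2_cv>", length(x$ensembles), "fold ensembles,",
      nrow(x$cv_predictions), "cross-validated predictions\n")
  invisible(x)
}

# Extract the candidate columns of a record subset.
slice_candidates <- function(cands, idx) {
  cols <- unlist(lapply(idx, function(i)
    cands$start[i] + seq_len(cands$noff[i])), use.names = FALSE)
  noff <- cands$noff[idx]
  list(X = cands$X[, cols, drop = FALSE],
       start = c(0L, cumsum(noff))[seq_along(noff)], noff = noff)
}

# Per-network best cores/scores for a record subset, averaged and
# majority-voted across the ensemble.  Networks are matched to the
# candidate set of their own encoding scheme.
ensemble_vote <- function(nets, cands_by_scheme, idx, cfg) {
  offs <- scores <- NULL
  for (net in nets) {
    sub <- slice_candidates(cands_by_scheme[[net$scheme_kind]], idx)
    res <- cpp_best_core(t(net$w1), net$b1, net$w2, net$b2, sub$X,
                         sub$start, sub$noff)
    offs <- cbind(offs, res$offset)
    scores <- cbind(scores, res$score)
  }
  vote <- majority_core(offs, scores)
  list(score = rowMeans(scores), offset = vote)
}

# Majority vote over per-network core offsets; ties broken by the higher
# mean score among the tied offsets, then by the smallest offset.
majority_core <- function(offsets, scores) {
  vapply(seq_len(nrow(offsets)), function(i) {
    o <- offsets[i, ]
    tab <- table(o)
    top <- as.integer(names(tab)[tab == max(tab)])
    if (length(top) > 1L) {
      ms <- vapply(top, function(k) mean(scores[i, o == k]), numeric(1))
      top <- top[ms == max(ms)]
    }
    min(top)
  }, integer(1))
}

#' Pool all folds' networks into one release ensemble
#'
#' @param cv An `mhc2_cv` from [train_ensemble()].
#' @return An `mhc2_ensemble` holding every fold's networks (e.g.
#'   5 x 20 = 100 at the default configuration), for predicting external
#'   peptides.
#' @export
pooled_ensemble <- function(cv) {
  new_ensemble(do.call(c, lapply(cv$ensembles, `[[`, "networks")),
               cv$config, cv$pseudo)
}
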