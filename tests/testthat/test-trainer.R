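test_that("find_best_core equals an exhaustive brute-force scan", {
  fit <- tiny_net()
  sc <- encoding_scheme("sparse")
  pseudo <- tiny_pseudo()[[1]]
  withr::with_seed(31, {
    for (rep in 1:8) {
      pep <- random_peptide(sample(9:20, 1))
      bc <- find_best_core(fit$net, pep, pseudo, sc, fit$cfg)
      # oracle: loop over every offset, encode and forward independently
      scores <- vapply(0:(nchar(pep) - 9), function(o)
        forward(fit$net, encode_example(pep, o, pseudo, sc)), numeric(1))
      expect_length(scores, nchar(pep) - 8L)
      expect_equal(bc$offset, which.max(scores) - 1L)
      expect_equal(bc$score, max(scores))
    }
  })
  # a 9-mer has a single candidate core
  expect_equal(find_best_core(fit$net, "AAAAAAAAA", pseudo, sc,
                              fit$cfg)$offset, 0L)
})

test_that("train_one is deterministic, learns, and respects n_cycles = 0", {
  cfg <- train_config(n_cycles = 30L, n_seeds = 1L, schemes = "sparse")
  rec <- tiny_records(80L)
  tab <- tiny_pseudo()
  n1 <- train_one(rec, tab, "sparse", seed = 3L, cfg = cfg)
  n2 <- train_one(rec, tab, "sparse", seed = 3L, cfg = cfg)
  expect_identical(n1$w1, n2$w1)
  expect_identical(n1$b2, n2$b2)
  cfg0 <- train_config(n_cycles = 0L, n_seeds = 1L, schemes = "sparse")
  n0 <- train_one(rec, tab, "sparse", seed = 3L, cfg = cfg0)
  expect_equal(n0$w1, init_network(646L, 40L, 3L, scheme_kind = "sparse")$w1)
  # single-allele planted motif: train-set PCC > 0.8 after full training
  cfg_full <- train_config(n_cycles = 120L, n_seeds = 1L, schemes = "sparse")
  rec300 <- generate_records(tiny_alleles()[[1]], 300L, seed = 77L)
  net <- train_one(rec300, tab, "sparse", seed = 5L, cfg = cfg_full,
                   trace_every = 50L)
  sc <- encoding_scheme("sparse")
  pr <- vapply(seq_len(nrow(rec300)), function(i)
    find_best_core(net, rec300$peptide[i], tab[[1]], sc, cfg_full)$score,
    numeric(1))
  expect_gt(pcc(pr, rec300$target), 0.8)
  # training loss measured every 50 cycles is non-increasing in >= 90% of
  # intervals on clean synthetic data
  expect_gte(mean(diff(net$mse_trace) <= 0), 0.9)
})

test_that("partition_data keeps shared-9-mer peptides together and balances", {
  # two peptides sharing a 9-mer always co-locate
  shared <- c("AAAAAAAAACDE", "KLMAAAAAAAAA")  # common 9-mer of A's
  rec <- data.frame(peptide = c(shared, replicate(30, random_peptide(12))))
  f <- partition_data(rec, n_folds = 3L, seed = 1L)
  expect_equal(f[1], f[2])
  # all-unique random peptides balance within 1
  withr::with_seed(8, {
    rec_u <- data.frame(peptide = replicate(40, random_peptide(9)))
  })
  fu <- partition_data(rec_u, n_folds = 4L, seed = 2L)
  expect_lte(diff(range(table(fu))), 1)
  # brute-force connected-components oracle on 50 peptides built to share
  withr::with_seed(9, {
    base9 <- replicate(10, random_peptide(9))
    peps <- unique(unlist(lapply(base9, function(b)
      c(b, paste0(random_peptide(3), b), paste0(b, random_peptide(4))))))
  })
  comp <- mhc2align:::shared_kmer_clusters(peps, 9L)
  n <- length(peps)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ki <- substring(peps[i], 1:(nchar(peps[i]) - 8), 9:nchar(peps[i]))
    kj <- substring(peps[j], 1:(nchar(peps[j]) - 8), 9:nchar(peps[j]))
    adj[i, j] <- length(intersect(ki, kj)) > 0
  }
  reach <- adj
  for (k in seq_len(n)) reach <- reach | (reach %*% (reach * 1) > 0)
  oracle <- apply(reach, 1, function(r) min(which(r)))
  expect_equal(match(comp, unique(comp)), match(oracle, unique(oracle)))
  # more folds than clusters -> error
  expect_error(partition_data(data.frame(peptide = "AAAAAAAAA"), 2L),
               "clusters")
})

test_that("train_ensemble covers every record once with the right counts", {
  cfg <- train_config(n_cycles = 10L, n_seeds = 2L,
                      schemes = c("sparse", "blosum"), n_folds = 3L,
                      master_seed = 4L)
  rec <- do.call(rbind, lapply(1:2, function(i)
    generate_records(tiny_alleles()[[i]], 45L, seed = 50L + i)))
  cv <- train_ensemble(rec, tiny_pseudo(), cfg)
  # len(schemes) * n_seeds networks per fold
  expect_length(cv$ensembles, 3L)
  for (e in cv$ensembles) expect_length(e$networks, 4L)
  expect_length(pooled_ensemble(cv)$networks, 12L)
  # every record predicted exactly once, in its own fold
  expect_false(anyNA(cv$cv_predictions$score))
  expect_equal(cv$cv_predictions$fold, cv$fold)
  expect_equal(sort(unique(cv$fold)), 1:3)
  # core_seq consistency
  expect_equal(cv$cv_predictions$core_seq,
               substring(rec$peptide, cv$cv_predictions$core_offset + 1,
                         cv$cv_predictions$core_offset + 9))
  # smoke learnability: CV PCC exceeds 0 even at this tiny scale
  expect_gt(pcc(cv$cv_predictions$score, rec$target), 0)
})

test_that("removing one allele's records never changes another's encoding", {
  cfg <- train_config()
  sc <- encoding_scheme("sparse")
  rec <- do.call(rbind, lapply(1:3, function(i)
    generate_records(tiny_alleles()[[i]], 5L, seed = 60L + i)))
  full <- mhc2align:::precompute_candidates(rec, tiny_pseudo(), sc, cfg)
  keep <- which(rec$allele != "SYN-02")
  dropped <- mhc2align:::precompute_candidates(rec[keep, ], tiny_pseudo(),
                                               sc, cfg)
  sub <- mhc2align:::slice_candidates(full, keep)
  expect_identical(dropped$X, sub$X)
})
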