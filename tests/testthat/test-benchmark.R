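# cheap config: exclusion logic, not accuracy, is under test here
fast_cfg <- train_config(n_cycles = 5L, n_seeds = 1L, schemes = "sparse",
                         master_seed = 3L)

bench_records <- function() {
  memo("benchrec", do.call(rbind, lapply(1:3, function(i)
    generate_records(tiny_alleles()[[i]], 40L, seed = 20L + i))))
}

test_that("loo_allele excludes the target allele and extrapolates via pseudo", {
  rec <- bench_records()
  tab <- tiny_pseudo()
  res <- loo_allele(rec, "SYN-02", tab, fast_cfg)
  expect_equal(res$n, 40L)
  expect_equal(res$n_train, 80L)
  expect_false("SYN-02" %in% res$train_alleles)
  expect_error(loo_allele(rec, "SYN-99", tab, fast_cfg), "no records")
  # swap test: predictions depend on the target only through its pseudo
  # sequence, so querying a pseudo identical to SYN-01's reproduces
  # SYN-01's predictions
  tab2 <- tab
  tab2["TWIN"] <- tab[["SYN-01"]]
  res2 <- loo_allele(rec, "SYN-02", tab2, fast_cfg)
  peps <- rec$peptide[rec$allele == "SYN-02"][1:5]
  expect_identical(predict_binding(res2$ensemble, peps, "TWIN")$score,
                   predict_binding(res2$ensemble, peps, "SYN-01")$score)
})

test_that("loo_peptide removes every measurement of each evaluation peptide", {
  rec <- bench_records()
  tab <- tiny_pseudo()
  # plant one peptide measured on all 3 alleles
  shared <- rec$peptide[1]
  rec$peptide[c(41L, 81L)] <- shared
  res <- loo_peptide(rec, "SYN-01", tab, fast_cfg)
  expect_equal(res$n_rounds, 1L)  # 40 records <= 200 -> single round
  expect_equal(res$rounds[[1]]$n_train,
               sum(!rec$peptide %in% rec$peptide[rec$allele == "SYN-01"]))
  # the shared peptide is gone from training entirely (all 3 measurements)
  expect_false(shared %in% res$rounds[[1]]$train_peptides)
  # union of evaluation partitions covers the allele's record set
  expect_equal(sort(unlist(lapply(res$rounds, `[[`, "eval_rows"))),
               seq_len(res$n))
  expect_false(anyNA(res$predictions$score))
})

test_that("loo_peptide switches to 3 inner folds above 200 data points", {
  tab <- tiny_pseudo()
  big <- generate_records(tiny_alleles()[[1]], 210L, seed = 33L)
  other <- generate_records(tiny_alleles()[[2]], 40L, seed = 34L)
  rec <- rbind(big, other)
  res <- loo_peptide(rec, "SYN-01", tab, fast_cfg)
  expect_equal(res$n_rounds, 3L)
  expect_equal(sort(unlist(lapply(res$rounds, `[[`, "eval_rows"))),
               seq_len(210L))
  # each round's evaluation peptides are absent from that round's training
  for (rd in res$rounds)
    expect_length(intersect(rd$excluded_peptides, rd$train_peptides), 0L)
  # at 150 records a single full-exclusion round remains
  res150 <- loo_peptide(rec[c(1:150, 211:250), ], "SYN-01", tab, fast_cfg)
  expect_equal(res150$n_rounds, 1L)
})

test_that("ligand benchmark windows, identity positives and filters", {
  # hand-built protein: ligand of length 10 occurring twice in length 30
  lig <- "ACDEFGHIKL"
  prot <- paste0(lig, "MNPQRSTVW", "Y", lig)
  proteins <- c(p1 = prot)
  ligands <- data.frame(protein_id = "p1", ligand = lig, allele = "AL")
  # perfect scorer: 1 at the ligand sequence, 0 elsewhere
  perfect <- function(peptides, allele) as.numeric(peptides == lig)
  res <- ligand_benchmark(proteins, ligands, perfect)
  expect_equal(res$per_ligand$n_windows, nchar(prot) - nchar(lig) + 1L)
  expect_equal(res$per_ligand$n_pos, 2L)  # both occurrences are positives
  expect_equal(res$per_ligand$auc, 1)
  expect_equal(res$mean_per_ligand, 1)
  # length filter: 8-mers and 25-mers are excluded and counted
  ligands2 <- rbind(ligands,
                    data.frame(protein_id = "p1", ligand = substr(prot, 1, 8),
                               allele = "AL"),
                    data.frame(protein_id = "p1", ligand = strrep("A", 25),
                               allele = "AL"))
  suppressMessages(res2 <- ligand_benchmark(proteins, ligands2, perfect))
  expect_equal(res2$n_length_excluded, 2L)
  expect_equal(nrow(res2$per_ligand), 1L)
  # ligand absent from its protein is skipped with a log, not an error
  ligands3 <- rbind(ligands, data.frame(protein_id = "p1",
                                        ligand = "WWWWWWWWWW",
                                        allele = "AL"))
  suppressMessages(res3 <- ligand_benchmark(proteins, ligands3, perfect))
  expect_equal(res3$skipped, "WWWWWWWWWW")
  expect_equal(nrow(res3$per_ligand), 1L)
})

test_that("ligand benchmark aggregates per allele then across alleles", {
  lig1 <- "ACDEFGHIKLMNP"
  lig2 <- "KLMNPQRSTVWYA"
  withr::with_seed(17, {
    proteins <- c(pA = paste0(random_peptide(20), lig1, random_peptide(20)),
                  pB = paste0(lig2, random_peptide(25)))
  })
  ligands <- data.frame(protein_id = c("pA", "pA", "pB"),
                        ligand = c(lig1, lig1, lig2),
                        allele = c("AL1", "AL1", "AL2"))
  # scorer perfect for lig1 only; random-but-fixed for AL2
  scorer <- function(peptides, allele) {
    if (allele == "AL1") as.numeric(peptides == lig1)
    else seq_along(peptides) %% 7 / 7
  }
  res <- ligand_benchmark(proteins, ligands, scorer)
  a2 <- res$per_ligand$auc[res$per_ligand$allele == "AL2"]
  expect_equal(res$mean_per_ligand, mean(c(1, 1, a2)))
  expect_equal(res$mean_per_allele, mean(c(1, a2)))  # within-allele first
  expect_equal(res$per_length$auc[res$per_length$length == 13],
               mean(c(1, 1, a2)))
})
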