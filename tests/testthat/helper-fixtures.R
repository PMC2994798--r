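# Shared fixtures: everything is generated in code at test time.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

tiny_alleles <- function(n = 3L, seed = 42L) {
  memo(paste0("al", n, "-", seed), generate_alleles(n, seed = seed))
}

tiny_pseudo <- function(n = 3L, seed = 42L) {
  synthetic_pseudo_table(tiny_alleles(n, seed))
}

tiny_records <- function(n = 60L, allele_idx = 1L, seed = 7L, ...) {
  generate_records(tiny_alleles()[[allele_idx]], n, seed = seed, ...)
}

# A small but learnable single-allele training set and a quickly trained
# network, shared across test files.
tiny_net <- function() {
  memo("tinynet", {
    cfg <- train_config(n_cycles = 30L, n_seeds = 1L, schemes = "sparse",
                        master_seed = 1L)
    rec <- tiny_records(80L)
    list(net = train_one(rec, tiny_pseudo(), "sparse", seed = 3L, cfg = cfg),
         rec = rec, cfg = cfg)
  })
}

# Two-network ensemble over both encoding schemes for predictor tests.
tiny_ensemble <- function() {
  memo("tinyens", {
    cfg <- train_config(n_cycles = 20L, n_seeds = 1L,
                        schemes = c("sparse", "blosum"), master_seed = 2L)
    rec <- tiny_records(60L)
    nets <- list(train_one(rec, tiny_pseudo(), "sparse", 11L, cfg),
                 train_one(rec, tiny_pseudo(), "blosum", 12L, cfg))
    mhc2align:::new_ensemble(nets, cfg, tiny_pseudo())
  })
}

random_peptide <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

write_tsv_fixture <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
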