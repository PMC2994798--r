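test_that("affinity transform matches its definition and round-trips", {
  # anchor values: score 0 at the transform base, 1 at 1 nM
  expect_equal(ic50_to_target(15000), 0)
  expect_equal(ic50_to_target(1), 1)
  # 500 nM: frozen from 1 - log(500)/log(15000) evaluated at 30 digits
  expect_equal(ic50_to_target(500), 0.35370904587312, tolerance = 1e-12)
  # alternative base
  expect_equal(ic50_to_target(50000, base = 50000), 0)
  # above-base affinities clamp at 0 instead of going negative
  expect_equal(ic50_to_target(1e6), 0)
  # strictly decreasing on [1, base]
  aff <- sort(exp(runif(50, 0, log(15000))))
  expect_true(all(diff(ic50_to_target(aff)) <= 0))
  # inverse round-trip within 1e-9 relative error
  t0 <- runif(100)
  expect_equal(ic50_to_target(target_to_ic50(t0)), t0, tolerance = 1e-9)
})

test_that("read_binding_data validates, counts rejections and preserves order", {
  df <- data.frame(
    peptide = c("PKYVKQNTLKLAT", "AAAAAAAAA", "SHORT", "BADCHARZZZZZZ",
                "CCCCCCCCCCCC", "DDDDDDDDDD"),
    allele = "DRB1*0101",
    affinity_nM = c(15000, 1, 50, 50, -3, 500))
  path <- write_tsv_fixture(df, withr::local_tempfile(fileext = ".tsv"))
  suppressMessages(rec <- read_binding_data(path))
  # SHORT (<9), BADCHAR.. (Z), and the negative affinity are rejected
  expect_equal(attr(rec, "n_rejected"), 3L)
  expect_equal(attr(rec, "rejected_rows"), c(3L, 4L, 5L))
  expect_equal(rec$peptide,
               c("PKYVKQNTLKLAT", "AAAAAAAAA", "DDDDDDDDDD"))
  expect_equal(rec$target, c(0, 1, ic50_to_target(500)))
  # idempotent
  suppressMessages(rec2 <- read_binding_data(path))
  expect_identical(rec$peptide, rec2$peptide)
  # all rows rejected -> error
  bad <- write_tsv_fixture(df[3:5, ], withr::local_tempfile(fileext = ".tsv"))
  suppressMessages(expect_error(read_binding_data(bad), "all .* rejected"))
  expect_error(read_binding_data("no/such/file.tsv"), "not found")
})

test_that("read_pseudosequences enforces one length and handles duplicates", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("AL-01 AAAAAAAAAAAAAAAAAAAAA",
               "AL-02 CCCCCCCCCCCCCCCCCCCCC"), p)
  tab <- read_pseudosequences(p)
  expect_length(tab, 2L)
  expect_equal(unname(tab["AL-02"]), strrep("C", 21))

  writeLines(c("AL-01 AAAAAAAAAAAAAAAAAAAAA",
               "AL-02 CCCCCCCCCCCCCCCCCCCC"), p)  # 20-mer among 21-mers
  expect_error(read_pseudosequences(p), "AL-02")

  writeLines(c("AL-01 AAAAAAAAA", "AL-01 CCCCCCCCC"), p)
  expect_warning(tab <- read_pseudosequences(p), "duplicated")
  expect_equal(unname(tab["AL-01"]), strrep("C", 9))

  writeLines(character(0), p)
  expect_error(read_pseudosequences(p), "empty")
})

test_that("read_fasta truncates headers, uppercases and flags wildcards", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">prot1 some description", "acdefghik", ">prot2",
               "MKTAYXAKQ"), p)
  seqs <- read_fasta(p)
  expect_named(seqs, c("prot1", "prot2"))
  expect_equal(unname(seqs["prot1"]), "ACDEFGHIK")
  expect_equal(attr(seqs, "has_wildcard"), "prot2")
  writeLines(c(">dup", "AAA", ">dup", "CCC"), p)
  expect_error(read_fasta(p), "duplicate")
})

test_that("prediction tables round-trip through write/read", {
  ens <- tiny_ensemble()
  preds <- predict_binding(ens, c("PKYVKQNTLKLATAG", "AAAAAAAAA"), "SYN-01")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(preds, path)
  back <- read_predictions(path)
  expect_equal(back$peptide, preds$peptide)
  expect_equal(back$core_offset, preds$core_offset)
  expect_equal(back$score, round(preds$score, 6))
  # empty input -> header-only file that reads back as zero rows
  write_predictions(preds[0, ], path)
  expect_equal(nrow(read_predictions(path)), 0L)
})
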