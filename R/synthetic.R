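#' Generate synthetic alleles with planted binding motifs
#'
#' Simulates a family of MHC class II alleles for offline testing.  A root
#' allele gets a random 21-mer pseudo sequence and a 9 x 20 position score
#' matrix (PSSM) with stronger weight at the canonical anchor positions
#' (1, 4, 6, 9); each further allele derives from a randomly chosen
#' existing allele by mutating pseudo positions at `mutation_rate` and, for
#' every mutated position, perturbing one random PSSM row.  Coupling the
#' two mutation processes makes pseudo-sequence distance and motif
#' (PSSM) distance correlate across the family — the property pan-specific
#' prediction relies on.
#'
#' @param n Number of alleles.
#' @param seed Integer seed; the generator is fully deterministic.
#' @param mutation_rate Per-position pseudo mutation probability along
#'   each tree edge.
#' @param pseudo_len Pseudo-sequence length (default 21).
#' @param anchor_sd,other_sd Score spread of anchor (1, 4, 6, 9) vs
#'   non-anchor PSSM rows.
#' @param perturb_sd Spread of the PSSM row perturbation applied per
#'   pseudo mutation.
#' @return List of class `mhc2_synth_alleles`; each element has `name`,
#'   `pseudo`, `pssm` (9 x 20, rows centered), `lineage` (parent name or
#'   `NA` for the root).
#' @export
generate_alleles <- function(n, seed = 1L, mutation_rate = 0.15,
                             pseudo_len = 21L, anchor_sd = 1.5,
                             other_sd = 0.4, perturb_sd = 0.5) {
  stopifnot(n >= 1L, mutation_rate >= 0, mutation_rate <= 1)
  anchors <- c(1L, 4L, 6L, 9L)
  withr::with_seed(seed, {
    root_pssm <- t(vapply(seq_len(CORE_LEN), function(i)
      rnorm(20L, 0, if (i %in% anchors) anchor_sd else other_sd),
      numeric(20L)))
    colnames(root_pssm) <- AA_ALPHABET
    root_pssm <- root_pssm - rowMeans(root_pssm)
    out <- list(list(name = "SYN-01",
                     pseudo = paste(sample(AA_ALPHABET, pseudo_len,
                                           replace = TRUE), collapse = ""),
                     pssm = root_pssm, lineage = NA_character_))
    for (i in seq_len(n - 1L) + 1L) {
      parent <- out[[sample.int(length(out), 1L)]]
      ps <- strsplit(parent$pseudo, "")[[1]]
      mut <- which(runif(pseudo_len) < mutation_rate)
      pssm <- parent$pssm
      for (m in mut) {
        ps[m] <- sample(setdiff(AA_ALPHABET, ps[m]), 1L)
        row <- sample.int(CORE_LEN, 1L)
        pssm[row, ] <- pssm[row, ] + rnorm(20L, 0, perturb_sd)
        pssm[row, ] <- pssm[row, ] - mean(pssm[row, ])
      }
      out[[i]] <- list(name = sprintf("SYN-%02d", i),
                       pseudo = paste(ps, collapse = ""), pssm = pssm,
                       lineage = parent$name)
    }
    names(out) <- vapply(out, `[[`, "", "name")
    structure(out, class = "mhc2_synth_alleles")
  })
}

#' @export
print.mhc2_synth_alleles <- function(x, ...) {
  cat("<mhc2_synth_alleles>", length(x), "allele(s), pseudo length",
      nchar(x[[1]]$pseudo), "\n")
  invisible(x)
}

#' Pseudo-sequence table of a synthetic allele family
#'
#' @param alleles An `mhc2_synth_alleles` object.
#' @return Named character vector usable wherever
#'   [read_pseudosequences()] output is.
#' @export
synthetic_pseudo_table <- function(alleles) {
  setNames(vapply(alleles, `[[`, "", "pseudo"),
           vapply(alleles, `[[`, "", "name"))
}

#' Frobenius distance between two allele PSSMs
#'
#' @param a,b 9 x 20 position score matrices.
#' @return Non-negative distance; used to check that motif distance tracks
#'   pseudo-sequence distance across a synthetic family.
#' @export
pssm_distance <- function(a, b) sqrt(sum((a - b)^2))

#' Score a peptide under a PSSM and locate its best core
#'
#' Independent oracle used throughout the tests: sums PSSM entries over
#' each 9-mer window and returns the first-best offset.
#'
#' @param pssm 9 x 20 matrix with residue column names.
#' @param peptide Peptide string (length >= 9).
#' @return List with `offset` (0-based best core) and `score`, plus
#'   `all_scores` for every window.
#' @export
pssm_score_peptide <- function(pssm, peptide) {
  chars <- strsplit(peptide, "")[[1]]
  L <- length(chars)
  stopifnot(L >= CORE_LEN)
  s <- vapply(0:(L - CORE_LEN), function(o)
    sum(pssm[cbind(seq_len(CORE_LEN), match(chars[o + seq_len(CORE_LEN)],
                                            colnames(pssm)))]),
    numeric(1))
  k <- which.max(s)
  list(offset = k - 1L, score = s[k], all_scores = s)
}

#' Generate synthetic binding records for one allele
#'
#' Peptides are drawn with uniform residues and uniform lengths; the true
#' core is the best-scoring window under the allele's PSSM; the latent
#' target is a logistic squash of the core score (standardised against the
#' PSSM's own score distribution so roughly half the peptides fall on the
#' binder side) plus Gaussian noise on the \[0, 1\] target scale, clamped;
#' IC50 follows as `base^(1 - target)`.
#'
#' @param allele One element of [generate_alleles()] output.
#' @param n_peptides Number of records.
#' @param length_range Inclusive peptide-length range (default 9-21).
#' @param noise_sd Gaussian noise on the target scale (default 0.05).
#' @param seed Integer seed.
#' @param base Affinity-transform base in nM.
#' @return Data.frame with peptide, allele, affinity_nM, target and
#'   true_core_offset (0-based).
#' @export
generate_records <- function(allele, n_peptides, length_range = c(9L, 21L),
                             noise_sd = 0.05, seed = 1L, base = 15000) {
  pssm <- allele$pssm
  # standardise against the window-score distribution implied by the PSSM
  mu <- sum(rowMeans(pssm))
  sdev <- sqrt(sum(apply(pssm, 1L, function(r) mean(r^2) - mean(r)^2)))
  center <- mu + 1.2 * sdev   # near the expected best-window score
  scale <- 0.4 * sdev
  withr::with_seed(seed, {
    len_pool <- seq(length_range[1L], length_range[2L])
    lens <- len_pool[sample.int(length(len_pool), n_peptides,
                                replace = TRUE)]
    peptides <- vapply(lens, function(L)
      paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = ""), "")
    sc <- lapply(peptides, pssm_score_peptide, pssm = pssm)
    latent <- plogis((vapply(sc, `[[`, numeric(1), "score") - center) /
                       scale)
    target <- pmin(pmax(latent + rnorm(n_peptides, 0, noise_sd), 0), 1)
    data.frame(peptide = peptides, allele = allele$name,
               affinity_nM = target_to_ic50(target, base), target = target,
               true_core_offset = vapply(sc, `[[`, integer(1), "offset"),
               stringsAsFactors = FALSE)
  })
}

#' Synthetic ligand-benchmark fixture
#'
#' Random source proteins each carrying one implanted high-affinity ligand
#' for the given allele: the ligand's core is the PSSM's per-position
#' argmax residue string, padded with random flanks to `ligand_len`.
#'
#' @param allele One element of [generate_alleles()] output.
#' @param protein_len Protein length.
#' @param n_proteins Number of proteins (one ligand each).
#' @param ligand_len Ligand length (>= 9).
#' @param seed Integer seed.
#' @return List with `proteins` (named character vector) and `ligands`
#'   (data.frame protein_id, ligand, allele).
#' @export
generate_ligand_fixture <- function(allele, protein_len = 150L,
                                    n_proteins = 10L, ligand_len = 15L,
                                    seed = 1L) {
  stopifnot(ligand_len >= CORE_LEN, protein_len >= ligand_len)
  if (n_proteins == 0L)
    return(list(proteins = character(0),
                ligands = data.frame(protein_id = character(),
                                     ligand = character(),
                                     allele = character(),
                                     stringsAsFactors = FALSE)))
  core <- paste(colnames(allele$pssm)[apply(allele$pssm, 1L, which.max)],
                collapse = "")
  withr::with_seed(seed, {
    proteins <- character(n_proteins)
    ligands <- character(n_proteins)
    for (i in seq_len(n_proteins)) {
      n_flank <- ligand_len - CORE_LEN
      n_left <- sample.int(n_flank + 1L, 1L) - 1L
      lig <- paste0(paste(sample(AA_ALPHABET, n_left, replace = TRUE),
                          collapse = ""),
                    core,
                    paste(sample(AA_ALPHABET, n_flank - n_left,
                                 replace = TRUE), collapse = ""))
      prot <- sample(AA_ALPHABET, protein_len, replace = TRUE)
      at <- sample.int(protein_len - ligand_len + 1L, 1L)
      prot[at:(at + ligand_len - 1L)] <- strsplit(lig, "")[[1]]
      proteins[i] <- paste(prot, collapse = "")
      ligands[i] <- lig
    }
    names(proteins) <- sprintf("synprot-%03d", seq_len(n_proteins))
    list(proteins = proteins,
         ligands = data.frame(protein_id = names(proteins),
                              ligand = ligands, allele = allele$name,
                              stringsAsFactors = FALSE))
  })
}

#' Write a complete synthetic data set to disk
#'
#' Emits the same plain-text formats the rest of the pipeline reads:
#' `binding.tsv`, `pseudo.txt`, `proteins.fasta`, `ligands.tsv`.
#'
#' @param dir Output directory (created if needed).
#' @param n_alleles,n_peptides,seed,noise_sd,base Generator settings; one
#'   record set per allele and one ligand fixture for the first allele.
#' @return Invisibly, the list of written paths.
#' @export
write_synthetic_dataset <- function(dir, n_alleles = 6L, n_peptides = 400L,
                                    seed = 1L, noise_sd = 0.05,
                                    base = 15000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  alleles <- generate_alleles(n_alleles, seed = seed)
  records <- do.call(rbind, lapply(seq_along(alleles), function(i)
    generate_records(alleles[[i]], n_peptides, noise_sd = noise_sd,
                     seed = seed + i, base = base)))
  fix <- generate_ligand_fixture(alleles[[1L]], seed = seed + 1000L)
  paths <- file.path(dir, c("binding.tsv", "pseudo.txt", "proteins.fasta",
                            "ligands.tsv"))
  write.table(records[c("peptide", "allele", "affinity_nM")], paths[1L],
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste(names(synthetic_pseudo_table(alleles)),
                   synthetic_pseudo_table(alleles)), paths[2L])
  writeLines(as.vector(rbind(paste0(">", names(fix$proteins)),
                             fix$proteins)), paths[3L])
  write.table(fix$ligands, paths[4L], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
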