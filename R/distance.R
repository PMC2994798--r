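#' BLOSUM50 similarity between two pseudo sequences
#'
#' Position-wise sum of substitution scores over the pre-aligned,
#' equal-length pseudo sequences (no gaps).
#'
#' @param a,b Pseudo-sequence strings of equal length.
#' @param matrix Substitution matrix; defaults to the packaged BLOSUM50.
#' @return Numeric similarity score.
#' @export
pseudo_similarity <- function(a, b, matrix = blosum50()) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  if (length(ca) != length(cb))
    stop("pseudo sequences differ in length (", length(ca), " vs ",
         length(cb), ")")
  bad <- setdiff(unique(c(ca, cb)), rownames(matrix))
  if (length(bad)) stop("residue(s) not in matrix: ",
                        paste(bad, collapse = ", "))
  sum(matrix[cbind(ca, cb)])
}

#' Pseudo-sequence distance between two alleles
#'
#' d(A, B) = 1 - s(A, B) / sqrt(s(A, A) * s(B, B)) with s the BLOSUM50
#' similarity of the pseudo sequences.  Zero for identical sequences,
#' symmetric; values above 1 are possible for very dissimilar sequences
#' (negative cross-scores) and are reported as-is.
#'
#' @inheritParams pseudo_similarity
#' @return Non-negative distance.
#' @export
nn_distance <- function(a, b, matrix = blosum50()) {
  saa <- pseudo_similarity(a, a, matrix)
  sbb <- pseudo_similarity(b, b, matrix)
  if (saa <= 0 || sbb <= 0)
    stop("non-positive self-similarity; cannot normalize")
  1 - pseudo_similarity(a, b, matrix) / sqrt(saa * sbb)
}

#' Nearest training allele of a query allele
#'
#' The nearest-neighbor distance of an allele is its minimal
#' pseudo-sequence distance to any allele of the training set; small
#' values predict good pan-specific extrapolation.
#'
#' @param query Query allele name.
#' @param allele_table Named pseudo-sequence vector including the query.
#' @param training Character vector of training allele names (the query
#'   itself is excluded if present).
#' @param matrix Substitution matrix.
#' @return List with `allele` (nearest neighbor, ties broken
#'   lexicographically) and `distance`.
#' @export
nearest_neighbor <- function(query, allele_table,
                             training = names(allele_table),
                             matrix = blosum50()) {
  if (!query %in% names(allele_table))
    stop("no pseudo sequence for query allele ", query)
  training <- setdiff(intersect(training, names(allele_table)), query)
  if (!length(training)) stop("empty training set")
  d <- vapply(training, function(t)
    nn_distance(allele_table[[query]], allele_table[[t]], matrix),
    numeric(1))
  best <- sort(names(d)[d == min(d)])[1L]
  list(allele = best, distance = unname(d[best]))
}

#' All-pairs pseudo-sequence distance matrix
#'
#' @param allele_table Named pseudo-sequence vector.
#' @param matrix Substitution matrix.
#' @return Symmetric matrix of [nn_distance()] values with zero diagonal.
#' @export
allele_distance_matrix <- function(allele_table, matrix = blosum50()) {
  n <- length(allele_table)
  self <- vapply(allele_table, function(p)
    pseudo_similarity(p, p, matrix), numeric(1))
  out <- base::matrix(0, n, n, dimnames = list(names(allele_table),
                                               names(allele_table)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    s <- pseudo_similarity(allele_table[[i]], allele_table[[j]], matrix)
    out[i, j] <- out[j, i] <- 1 - s / sqrt(self[i] * self[j])
  }
  out
}
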