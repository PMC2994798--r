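.blosum_cache <- new.env(parent = emptyenv())

#' BLOSUM50 substitution matrix
#'
#' Returns the BLOSUM50 amino-acid substitution matrix (half-bit scores)
#' shipped with the package in NCBI text format.  Used both for the
#' "blosum" residue encoding scheme and for pseudo-sequence allele
#' distances.
#'
#' @param path Optional path to an alternative matrix file in NCBI format
#'   (a comment/header line starting the column letters, then one row per
#'   residue).  Defaults to the packaged BLOSUM50.
#' @return A symmetric numeric matrix with residue single-letter row and
#'   column names.
#' @export
#' @examples
#' m <- blosum50()
#' m["A", "A"]  # 5
blosum50 <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.blosum_cache$default)) return(.blosum_cache$default)
    path <- system.file("extdata", "BLOSUM50.txt", package = "mhc2align")
    default <- TRUE
  } else default <- FALSE
  m <- read_score_matrix(path)
  if (default) .blosum_cache$default <- m
  m
}

read_score_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  body <- strsplit(trimws(lines[-1]), "\\s+")
  rows <- vapply(body, `[`, "", 1L)
  vals <- t(vapply(body, function(x) as.numeric(x[-1L]), numeric(length(cols))))
  dimnames(vals) <- list(rows, cols)
  if (!isTRUE(all.equal(vals[cols, cols], t(vals[cols, cols]))))
    stop("substitution matrix is not symmetric: ", path)
  vals
}
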