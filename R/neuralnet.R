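#' Initialize a feed-forward network
#'
#' One hidden layer of logistic units and a single logistic output.
#' Weights and biases are drawn uniformly from \[-w0, w0\] using a
#' deterministic generator: the same (dimensions, seed) always yields the
#' identical network.
#'
#' @param input_len Number of inputs (646 at the default encodings).
#' @param n_hidden Hidden units (default 40).
#' @param seed Integer seed for the weight draw.
#' @param w0 Half-width of the uniform initialisation interval.
#' @param scheme_kind Optional encoding-scheme id ("sparse"/"blosum")
#'   stored with the network so serialized models are self-describing.
#' @return An object of class `mhc2_network` with fields `w1`
#'   (input x hidden), `b1`, `w2` (hidden), `b2`, `seed`, `n_hidden`,
#'   `input_len`, `scheme_kind`.
#' @export
init_network <- function(input_len, n_hidden = 40L, seed = 1L, w0 = 0.1,
                         scheme_kind = NA_character_) {
  stopifnot(input_len >= 1L, n_hidden >= 1L)
  pars <- withr::with_seed(seed, {
    list(w1 = base::matrix(runif(input_len * n_hidden, -w0, w0),
                           input_len, n_hidden),
         b1 = runif(n_hidden, -w0, w0),
         w2 = runif(n_hidden, -w0, w0),
         b2 = runif(1L, -w0, w0))
  })
  structure(c(pars, list(seed = as.integer(seed),
                         n_hidden = as.integer(n_hidden),
                         input_len = as.integer(input_len),
                         scheme_kind = scheme_kind)),
            class = "mhc2_network")
}

#' @export
print.mhc2_network <- function(x, ...) {
  cat("<mhc2_network>", x$input_len, "->", x$n_hidden,
      "-> 1 (logistic), seed", x$seed, "scheme",
      x$scheme_kind, "\n")
  invisible(x)
}

#' Network forward pass
#'
#' `forward()` evaluates sigma(w2 . sigma(w1' x + b1) + b2) for one input
#' vector or each column of a matrix; the output is always strictly
#' inside (0, 1).
#'
#' @param net An `mhc2_network`.
#' @param x Input vector of length `net$input_len`, or a matrix with one
#'   example per column.
#' @return Numeric vector of outputs.
#' @export
forward <- function(net, x) {
  if (is.null(dim(x))) x <- base::matrix(x, ncol = 1L)
  stopifnot(nrow(x) == net$input_len)
  cpp_forward_batch(t(net$w1), net$b1, net$w2, net$b2, x)
}

#' One online gradient-descent step
#'
#' Updates all weights by one backpropagation step on the squared error
#' `0.5 * (forward(net, x) - target)^2`.
#'
#' @param net An `mhc2_network`.
#' @param x Input vector.
#' @param target Regression target in \[0, 1\].
#' @param learning_rate Step size.
#' @return The updated network.
#' @export
sgd_update <- function(net, x, target, learning_rate = 0.05) {
  stopifnot(length(x) == net$input_len, target >= 0, target <= 1)
  h <- plogis(drop(crossprod(net$w1, x)) + net$b1)
  o <- plogis(sum(net$w2 * h) + net$b2)
  go <- (o - target) * o * (1 - o)
  gh <- go * net$w2 * h * (1 - h)
  if (!all(is.finite(gh))) stop("non-finite gradient: step size too large")
  net$w2 <- net$w2 - learning_rate * go * h
  net$b2 <- net$b2 - learning_rate * go
  net$w1 <- net$w1 - learning_rate * outer(x, gh)
  net$b1 <- net$b1 - learning_rate * gh
  net
}

#' Serialize a network to a flat text file
#'
#' Self-describing plain-text format: a header with dimensions, seed and
#' scheme id, then each parameter block written with 17 significant
#' digits, which round-trips IEEE doubles exactly.
#'
#' @param net An `mhc2_network`.
#' @param path File path.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   the network.
#' @export
write_network <- function(net, path) {
  fmt <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  writeLines(c("mhc2align-network 1",
               paste("input_len", net$input_len),
               paste("n_hidden", net$n_hidden),
               paste("seed", net$seed),
               paste("scheme", net$scheme_kind),
               paste("b2", fmt(net$b2)),
               paste("b1", fmt(net$b1)),
               paste("w2", fmt(net$w2)),
               paste("w1", fmt(net$w1))), path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[[1]], "mhc2align-network 1"))
    stop("not an mhc2align network file: ", path)
  kv <- strsplit(lines[-1], " ")
  names(kv) <- vapply(kv, `[`, "", 1L)
  num <- function(key) as.numeric(kv[[key]][-1L])
  input_len <- as.integer(num("input_len"))
  n_hidden <- as.integer(num("n_hidden"))
  structure(list(w1 = base::matrix(num("w1"), input_len, n_hidden),
                 b1 = num("b1"), w2 = num("w2"), b2 = num("b2"),
                 seed = as.integer(num("seed")),
                 n_hidden = n_hidden, input_len = input_len,
                 scheme_kind = kv[["scheme"]][2L]),
            class = "mhc2_network")
}
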