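# shared internal helpers

# round half away from zero to `digits` decimals (round() is banker's)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# uniform random DNA string of length n
random_dna <- function(n) {
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE)])
}

# all permutations of 1:n as an n! x n matrix (small n only)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix((seq_len(n))[-i][p], nrow(p)))
  }))
}

# validate a labelled symmetric distance matrix with zero diagonal
validate_distance_matrix <- function(d) {
  if (!is.matrix(d) || !is.numeric(d)) stop("distance matrix must be a numeric matrix")
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  labels <- rownames(d)
  if (is.null(labels) || is.null(colnames(d)) || !identical(labels, colnames(d)))
    stop("distance matrix must carry identical row and column labels")
  if (anyDuplicated(labels)) stop("duplicate labels in distance matrix")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix must be symmetric")
  invisible(d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
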