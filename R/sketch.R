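#' MinHash sketching and Mash distance estimation
#'
#' A sketch is the bottom-s set of hash values over the distinct canonical
#' k-mers of a nucleotide sequence (canonical = lexicographic minimum of a
#' k-mer and its reverse complement). Jaccard similarity between two
#' sequences is estimated from the merged bottom-s sketch and transformed
#' into a Mash distance, an estimate of per-base divergence.
#'
#' Hashing is a fixed splitmix64 mix of the 2-bit-packed canonical k-mer
#' XORed with a mixed seed, truncated to its top 53 bits so every hash is
#' exactly representable as an R double. This makes sketches bit-identical
#' across platforms with no external dependency.
#'
#' @name sketching
NULL

#' Sketching parameters
#'
#' @param k k-mer length in nucleotides, between 1 and 31. Default 16.
#' @param s sketch size: number of minimum hashes retained. `Inf` keeps
#'   every distinct canonical k-mer hash (exact Jaccard). Defaults follow
#'   the pipeline's conventions: 1000 for plasmid-scale sequences; use
#'   2000 for chromosomes.
#' @param hash_seed integer seed mixed into the hash function.
#' @return A `sketch_params` list.
#' @export
sketch_params <- function(k = 16L, s = 1000L, hash_seed = 42L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 31L) stop("k must be in [1, 31]")
  if (!is.infinite(s)) {
    s <- as.integer(s)
    if (is.na(s) || s < 1L) stop("s must be >= 1")
  }
  structure(list(k = k, s = s, hash_seed = as.integer(hash_seed)),
            class = "sketch_params")
}

#' Sketch a nucleotide sequence
#'
#' Enumerates distinct canonical k-mers (k-mers containing `N` are skipped
#' entirely), hashes them, and retains the `s` smallest hash values in
#' ascending order.
#'
#' @param seq A nucleotide string over `ACGTN` (case-insensitive), at
#'   least `k` long, or a length-1 [Biostrings::DNAStringSet] /
#'   [Biostrings::DNAString].
#' @param params A [sketch_params()] object.
#' @param name Optional sequence identifier stored in the sketch.
#' @return A `minhash_sketch`: list with `name`, `params`, `hashes`
#'   (strictly increasing numeric vector, length `min(s, n_kmers)`) and
#'   `n_kmers` (distinct canonical k-mers hashed).
#' @export
sketch_sequence <- function(seq, params = sketch_params(), name = NA_character_) {
  if (!inherits(params, "sketch_params")) stop("params must be sketch_params()")
  seq <- as.character(seq)
  if (length(seq) != 1L) stop("seq must be a single sequence")
  if (nchar(seq) < params$k) stop("sequence shorter than k")
  s_arg <- if (is.infinite(params$s)) -1L else params$s
  res <- sketch_hashes_cpp(seq, params$k, params$hash_seed, s_arg)
  structure(list(name = name, params = params,
                 hashes = res$hashes, n_kmers = res$n_kmers),
            class = "minhash_sketch")
}

#' Sketch every record of a FASTA file
#'
#' @param path FASTA file (multi-record; each record sketched separately).
#' @param params A [sketch_params()] object.
#' @return Named list of `minhash_sketch` objects, one per record.
#' @export
sketch_fasta <- function(path, params = sketch_params()) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) stop("duplicate record IDs in FASTA: ", path)
  out <- lapply(seq_along(seqs), function(i)
    sketch_sequence(as.character(seqs[[i]]), params, name = ids[i]))
  names(out) <- ids
  out
}

#' Mash distance between two sketches
#'
#' The Jaccard index is estimated as `|X intersect A intersect B| / |X|`
#' where `X` is the bottom-s of the union of the two hash sets, and
#' transformed as `d = -(1/k) * log(2j / (1 + j))`. `j = 0` maps to the
#' conventional cap `d = 1`; `j = 1` gives `d = 0`.
#'
#' @param a,b `minhash_sketch` objects with identical parameters.
#' @return Mash distance in `[0, 1]`.
#' @export
mash_distance <- function(a, b) {
  if (!inherits(a, "minhash_sketch") || !inherits(b, "minhash_sketch"))
    stop("inputs must be minhash_sketch objects")
  for (f in c("k", "s", "hash_seed")) {
    if (!identical(as.numeric(a$params[[f]]), as.numeric(b$params[[f]])))
      stop("sketch parameter mismatch: ", f)
  }
  k <- a$params$k
  s <- a$params$s
  u <- sort(unique(c(a$hashes, b$hashes)))
  if (!is.infinite(s) && length(u) > s) u <- u[seq_len(s)]
  if (length(u) == 0L) return(0)           # two empty sketches: identical
  j <- sum(u %in% a$hashes & u %in% b$hashes) / length(u)
  if (j <= 0) return(1)
  d <- -(1 / k) * log(2 * j / (1 + j))
  min(max(d, 0), 1)
}

#' All-by-all Mash distance matrix
#'
#' @param sketches List of `minhash_sketch` objects (at least 2) sharing
#'   parameters; names are taken from the sketch `name` fields.
#' @return Symmetric numeric matrix with zero diagonal and sequence IDs
#'   as dimnames.
#' @export
distance_matrix <- function(sketches) {
  if (length(sketches) < 2L) stop("need at least 2 sketches")
  labels <- vapply(sketches, function(s) s$name, character(1))
  if (anyDuplicated(labels)) stop("duplicate sketch labels")
  n <- length(sketches)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (jj in seq((i + 1L), n)) {
      dij <- mash_distance(sketches[[i]], sketches[[jj]])
      d[i, jj] <- dij
      d[jj, i] <- dij
    }
  }
  validate_distance_matrix(d)
  d
}

#' Exact Mash-formula distance from full canonical k-mer sets
#'
#' Convenience wrapper: sketches both sequences with `s = Inf` so the
#' Jaccard index is computed over the complete distinct canonical k-mer
#' sets, then applies the same distance transform. Useful as the
#' sampling-error-free reference for sketch-based estimates.
#'
#' @param seq_a,seq_b Nucleotide strings.
#' @param k k-mer length.
#' @param hash_seed Hash seed (any value; the exact Jaccard does not
#'   depend on it).
#' @return Distance in `[0, 1]`.
#' @export
mash_distance_exact <- function(seq_a, seq_b, k = 16L, hash_seed = 42L) {
  p <- sketch_params(k = k, s = Inf, hash_seed = hash_seed)
  mash_distance(sketch_sequence(seq_a, p, "a"), sketch_sequence(seq_b, p, "b"))
}
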