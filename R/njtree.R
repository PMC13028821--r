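#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining (Q-matrix agglomeration, via [ape::nj()]) on
#' a labelled symmetric distance matrix, e.g. all-by-all Mash distances.
#' Negative branch lengths, which NJ can produce on non-additive input,
#' are clamped to zero. The result is returned as a Newick string
#' terminated with `";"`.
#'
#' @param dm Symmetric numeric matrix with identical row/column labels,
#'   zero diagonal, and at least 3 labels.
#' @return Newick string with branch lengths.
#' @export
nj_tree <- function(dm) {
  validate_distance_matrix(dm)
  if (nrow(dm) < 3L) stop("neighbor joining needs at least 3 labels")
  tr <- ape::nj(stats::as.dist(dm))
  tr$edge.length <- pmax(tr$edge.length, 0)
  ape::write.tree(tr)
}
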