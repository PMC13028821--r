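#' Pangenome composition and cross-module linkage
#'
#' Gene clusters are partitioned from a genome-by-cluster membership
#' table into core (present in every genome), singleton (present in
#' exactly one) and accessory (the remainder). Cross-module associations
#' among composition metrics, plasmid cluster counts, mobilome burden
#' and richness PC scores are evaluated with tie-corrected Spearman
#' correlations under Benjamini-Hochberg false-discovery control.
#'
#' @name pangenome
NULL

#' Read a gene-cluster membership table
#'
#' Long TSV with columns `cluster_id`, `genome`, and optionally
#' `present` (0/1; rows with `present == 0` are dropped, absent column
#' means every row is a presence).
#'
#' @param path TSV path.
#' @return Binary incidence matrix, clusters x genomes.
#' @export
read_membership <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  req <- c("cluster_id", "genome")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("membership table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if ("present" %in% names(df)) df <- df[df$present != 0, , drop = FALSE]
  clusters <- sort(unique(df$cluster_id))
  genomes <- sort(unique(df$genome))
  m <- matrix(0L, length(clusters), length(genomes),
              dimnames = list(clusters, genomes))
  m[cbind(match(df$cluster_id, clusters), match(df$genome, genomes))] <- 1L
  m
}

#' Core / accessory / singleton composition metrics
#'
#' Core clusters are present in all genomes (strict intersection),
#' singletons in exactly one; everything else is accessory. Per-genome
#' counts are restricted to the clusters that genome carries, and
#' fractions are counts over the genome's total.
#'
#' @param m Binary incidence matrix, clusters (rows) x genomes
#'   (columns); at least 2 genomes, every cluster present somewhere.
#' @return Data frame with one row per genome: `genome`,
#'   `total_clusters`, `core_clusters`, `accessory_clusters`,
#'   `singleton_clusters`, `accessory_fraction`, `singleton_fraction`.
#'   The per-cluster class vector is attached as attribute
#'   `cluster_class`.
#' @export
composition_metrics <- function(m) {
  if (!is.matrix(m)) stop("membership must be a matrix (clusters x genomes)")
  if (ncol(m) < 2L) stop("core is undefined for a single-genome table")
  m <- (m > 0) + 0L
  if (any(rowSums(m) == 0))
    stop("membership table has cluster(s) present in no genome")
  prev <- rowSums(m)
  n_genomes <- ncol(m)
  class <- ifelse(prev == n_genomes, "core",
                  ifelse(prev == 1L, "singleton", "accessory"))
  per_class_count <- function(g, cl) sum(m[class == cl, g] > 0)
  out <- data.frame(
    genome = colnames(m),
    total_clusters = colSums(m),
    core_clusters = vapply(seq_len(n_genomes), per_class_count, integer(1),
                           cl = "core"),
    accessory_clusters = vapply(seq_len(n_genomes), per_class_count,
                                integer(1), cl = "accessory"),
    singleton_clusters = vapply(seq_len(n_genomes), per_class_count,
                                integer(1), cl = "singleton"),
    stringsAsFactors = FALSE
  )
  stopifnot(all(out$total_clusters ==
                out$core_clusters + out$accessory_clusters + out$singleton_clusters))
  out$accessory_fraction <- out$accessory_clusters / out$total_clusters
  out$singleton_fraction <- out$singleton_clusters / out$total_clusters
  rownames(out) <- NULL
  attr(out, "cluster_class") <- setNames(class, rownames(m))
  out
}

#' Spearman rank correlation with exact small-sample p value
#'
#' Rho is the Pearson correlation of mid-ranks (average ranks for ties).
#' The two-sided p value is exact by full permutation enumeration for
#' `n <= 9` and uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` otherwise.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, finite, each with
#'   nonzero variance.
#' @return List: `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite")
  if (sd(x) == 0 || sd(y) == 0)
    stop("rho undefined for a zero-variance vector")
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 9L) {
    perms <- all_permutations(n)
    sx <- as.vector(scale(rx))
    sy <- as.vector(scale(ry))
    # rho under permutation pi: sum(sx[pi] * sy) / (n - 1)
    rho_perm <- as.vector(matrix(sx[perms], nrow(perms)) %*% sy) / (n - 1)
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    r2 <- min(rho^2, 1)
    if (r2 >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - r2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
  }
  list(rho = rho, p = p, n = n)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Maps p values to q values with the step-up rule
#' `q(i) = min over j >= i of (m * p(j) / j)` on the ascending sort,
#' capped at 1 and mapped back to input order (delegates to
#' [stats::p.adjust()]).
#'
#' @param pvalues Numeric vector of p values in `[0, 1]`.
#' @return q values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p values must be in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Cross-module Spearman linkage analysis
#'
#' Computes tie-corrected Spearman correlations for every unordered pair
#' of numeric feature columns, with pairwise deletion of incomplete
#' rows, and applies Benjamini-Hochberg adjustment across the full pair
#' family. Subset analyses (e.g. plasmid-bearing genomes only) should be
#' run as separate calls so each family is corrected on its own. Pairs
#' with fewer than 3 complete observations or a zero-variance member are
#' dropped with a warning.
#'
#' @param features Data frame of per-genome variables; a `genome`
#'   column, if present, is used for row labels and otherwise ignored.
#' @return A data frame (`correlation_table`): `var1`, `var2`, `rho`,
#'   `p`, `q`, `n`.
#' @export
linkage_analysis <- function(features) {
  if ("genome" %in% names(features)) {
    rownames(features) <- features$genome
    features$genome <- NULL
  }
  num <- vapply(features, is.numeric, logical(1))
  features <- features[, num, drop = FALSE]
  if (ncol(features) < 2L) stop("need at least 2 numeric variables")
  prs <- combn(names(features), 2)
  rows <- lapply(seq_len(ncol(prs)), function(i) {
    v1 <- prs[1, i]; v2 <- prs[2, i]
    x <- features[[v1]]; y <- features[[v2]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      warning("dropping pair ", v1, " ~ ", v2,
              ": fewer than 3 complete rows or zero variance")
      return(NULL)
    }
    r <- spearman_cor(x[ok], y[ok])
    data.frame(var1 = v1, var2 = v2, rho = r$rho, p = r$p, n = r$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no valid variable pairs")
  out$q <- bh_adjust(out$p)
  out <- out[, c("var1", "var2", "rho", "p", "q", "n")]
  class(out) <- c("correlation_table", "data.frame")
  out
}
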