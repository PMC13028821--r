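#' Insertion-sequence and prophage burden summaries
#'
#' Mobilome burden is summarized per genome from element annotation
#' tables: element count and cumulative element length (from 1-based
#' inclusive coordinates, so fragmented inputs remain summarizable).
#'
#' @name mobilome
NULL

validate_annotations <- function(annotations) {
  req <- c("genome", "element_type", "contig", "start", "end")
  missing <- setdiff(req, names(annotations))
  if (length(missing))
    stop("annotation table is missing required column(s): ",
         paste(missing, collapse = ", "))
  bad <- annotations$end < annotations$start
  if (any(bad))
    stop("negative-length annotation row(s): ",
         paste(which(bad), collapse = ", "))
  invisible(annotations)
}

#' Read an element annotation TSV
#'
#' Columns: `genome`, `element_type` (`IS` or `prophage_region`),
#' `contig`, `start`, `end`, and optionally `family`.
#'
#' @param path TSV path.
#' @return Validated annotation data frame.
#' @export
read_elements <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  validate_annotations(df)
  df
}

burden_summary <- function(annotations, type, genomes = NULL) {
  validate_annotations(annotations)
  rows <- annotations[annotations$element_type == type, , drop = FALSE]
  if (is.null(genomes)) genomes <- sort(unique(rows$genome))
  if (inherits(genomes, "genome_manifest")) genomes <- genomes$accession
  lens <- lapply(genomes, function(g) {
    r <- rows[rows$genome == g, , drop = FALSE]
    as.integer(r$end - r$start + 1L)
  })
  out <- data.frame(genome = genomes,
                    count = lengths(lens),
                    total_length_bp = vapply(lens, function(x) sum(as.numeric(x)),
                                             numeric(1)),
                    stringsAsFactors = FALSE)
  out$lengths <- I(lens)
  rownames(out) <- NULL
  out
}

#' Per-genome insertion-sequence burden
#'
#' Two primary metrics per genome: total IS element count and cumulative
#' IS sequence length. Genomes listed in `genomes` (or a manifest) but
#' absent from the annotations get a zero summary.
#'
#' @param annotations Element annotation data frame (rows with
#'   `element_type == "IS"` are used).
#' @param genomes Optional character vector of genome accessions, or a
#'   `genome_manifest`, fixing the output genome set.
#' @return Data frame: `genome`, `count`, `total_length_bp`, and a
#'   list-column `lengths` of the individual element lengths.
#' @export
is_burden <- function(annotations, genomes = NULL) {
  burden_summary(annotations, "IS", genomes)
}

#' Per-genome prophage-region burden
#'
#' Region count and total predicted prophage region length per genome;
#' same contract as [is_burden()] on `element_type == "prophage_region"`
#' rows.
#'
#' @inheritParams is_burden
#' @return Data frame as in [is_burden()].
#' @export
prophage_burden <- function(annotations, genomes = NULL) {
  burden_summary(annotations, "prophage_region", genomes)
}

#' Element length distribution with short/medium/long bins
#'
#' Median and quartiles use the type-7 (linear interpolation) convention.
#' Bin edges are closed on the left: short `[0, break1)`, medium
#' `[break1, break2)`, long `[break2, Inf)`; the defaults operationalize
#' "medium" as 20-50 kb.
#'
#' @param annotations Annotation rows to summarize (at least one).
#' @param breaks Two increasing bin edges in bp (default
#'   `c(20000, 50000)`).
#' @return List: `median_bp`, `iqr` (`q1`, `q3`), `bin_counts` (named:
#'   `short`, `medium`, `long`).
#' @export
length_distribution <- function(annotations, breaks = c(20000, 50000)) {
  validate_annotations(annotations)
  if (nrow(annotations) == 0) stop("no regions to summarize")
  stopifnot(length(breaks) == 2, breaks[1] < breaks[2])
  len <- annotations$end - annotations$start + 1
  q <- quantile(len, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  bins <- cut(len, breaks = c(0, breaks, Inf), right = FALSE,
              labels = c("short", "medium", "long"))
  list(median_bp = q[2],
       iqr = c(q1 = q[1], q3 = q[3]),
       bin_counts = setNames(as.integer(table(bins)),
                             c("short", "medium", "long")))
}

#' Rank agreement of per-genome burdens between two prediction tools
#'
#' Spearman correlation (tie-corrected) of per-genome total element
#' lengths over the genomes shared by both summaries.
#'
#' @param burden_a,burden_b Burden data frames from [is_burden()] /
#'   [prophage_burden()].
#' @param metric Column compared, `"total_length_bp"` (default) or
#'   `"count"`.
#' @return List: `rho`, `p`, `n`.
#' @export
cross_tool_concordance <- function(burden_a, burden_b,
                                   metric = "total_length_bp") {
  shared <- intersect(burden_a$genome, burden_b$genome)
  if (length(shared) < 3L) stop("need at least 3 shared genomes")
  a <- burden_a[[metric]][match(shared, burden_a$genome)]
  b <- burden_b[[metric]][match(shared, burden_b$genome)]
  r <- spearman_cor(a, b)
  list(rho = r$rho, p = r$p, n = length(shared))
}
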