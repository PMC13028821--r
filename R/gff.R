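#' Read a GFF3 feature table
#'
#' Imports a GFF3 file (via rtracklayer) and flattens it into the feature
#' data frame used by the bcs-richness and mobilome modules: one row per
#' feature with columns `contig`, `type`, `start`, `end`, `strand` plus
#' any attribute columns present (`genome`, `gene`, `product`, `domain`,
#' `element_type`, `family`, ...). Multi-valued attributes (e.g.
#' `domain=GGDEF,EAL`) are collapsed into comma-separated strings;
#' [find_targets()] splits them again.
#'
#' @param path GFF3 file path.
#' @return A data frame of features. Coordinates are 1-based inclusive.
#' @export
read_features <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(gr$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  mc <- S4Vectors::mcols(gr)
  for (nm in setdiff(colnames(mc), c("type", "score", "phase"))) {
    col <- mc[[nm]]
    if (methods::is(col, "List") || is.list(col)) {
      col <- vapply(col, function(v)
        if (length(v) == 0) NA_character_ else paste(v, collapse = ","),
        character(1))
    }
    df[[nm]] <- as.character(col)
  }
  df
}

# minimal GFF3 writer for generator output: `features` needs contig, type,
# start, end, strand; every other column becomes a key=value attribute.
write_features_gff3 <- function(features, path, contig_lengths = NULL) {
  con <- file(path, open = "wb")   # binary: byte-identical across platforms
  on.exit(close(con))
  wline <- function(x) writeLines(x, con, sep = "\n")
  wline("##gff-version 3")
  if (!is.null(contig_lengths)) {
    for (nm in names(contig_lengths))
      wline(sprintf("##sequence-region %s 1 %d", nm, as.integer(contig_lengths[[nm]])))
  }
  attr_cols <- setdiff(names(features), c("contig", "type", "start", "end", "strand"))
  for (i in seq_len(nrow(features))) {
    vals <- unlist(features[i, attr_cols, drop = FALSE])
    vals <- vals[!is.na(vals) & vals != ""]
    attrs <- if (length(vals))
      paste(sprintf("%s=%s", names(vals), vals), collapse = ";") else "."
    strand <- features$strand[i]
    if (is.na(strand) || !strand %in% c("+", "-")) strand <- "."
    wline(sprintf("%s\tkomagenomics\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                  features$contig[i], features$type[i],
                  as.integer(features$start[i]), as.integer(features$end[i]),
                  strand, if (features$type[i] == "CDS") "0" else ".",
                  attrs))
  }
  invisible(path)
}
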