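#' Genome manifest handling
#'
#' The genome manifest is the frozen record of which complete assemblies
#' enter the analysis: one row per RefSeq assembly with species and strain
#' labels, assembly size, isolation source, and a flag marking clonal or
#' derivative assemblies that are excluded from mobilome comparisons.
#'
#' @name manifest
NULL

.manifest_columns <- c("accession", "species", "strain", "size_bp",
                       "source", "excluded_clonal")

new_genome_manifest <- function(df, provenance = NA_character_) {
  structure(df, class = c("genome_manifest", "data.frame"),
            provenance = provenance)
}

validate_manifest <- function(m) {
  missing <- setdiff(.manifest_columns, names(m))
  if (length(missing))
    stop("manifest is missing required column(s): ",
         paste(missing, collapse = ", "))
  dup <- m$accession[duplicated(m$accession)]
  if (length(dup))
    stop("duplicate accession(s) in manifest: ",
         paste(unique(dup), collapse = ", "))
  included <- !m$excluded_clonal
  bad <- included & (is.na(m$size_bp) | m$size_bp <= 0)
  if (any(bad))
    stop("included record(s) with missing or non-positive size_bp: ",
         paste(m$accession[bad], collapse = ", "))
  invisible(m)
}

#' Load a genome manifest from a TSV file
#'
#' Reads a tab-separated manifest with columns `accession`, `species`,
#' `strain`, `size_bp`, `source` and `excluded_clonal`. Empty fields and
#' literal `NA` are preserved as `NA`, never as empty strings.
#'
#' @param path Path to the manifest TSV.
#' @return A `genome_manifest` (a data frame with a `provenance` attribute).
#' @examples
#' path <- system.file("extdata", "komagataeibacter_manifest.tsv",
#'                     package = "komagenomics")
#' m <- load_manifest(path)
#' nrow(m)
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", ""), check.names = FALSE,
                   colClasses = "character")
  missing <- setdiff(.manifest_columns, names(df))
  if (length(missing))
    stop("manifest is missing required column(s): ",
         paste(missing, collapse = ", "))
  df$size_bp <- as.numeric(df$size_bp)
  df$excluded_clonal <- as.logical(toupper(df$excluded_clonal))
  df$excluded_clonal[is.na(df$excluded_clonal)] <- FALSE
  m <- new_genome_manifest(df[, union(.manifest_columns, names(df))],
                           provenance = path)
  validate_manifest(m)
  m
}

#' Remove excluded accessions from a manifest
#'
#' Drops the given accessions (e.g. clonal or derivative assemblies) and
#' returns the nonredundant manifest. Unknown accessions are permitted and
#' reported as a warning; the input manifest is never modified.
#'
#' @param manifest A `genome_manifest`.
#' @param exclusions Character vector of RefSeq assembly accessions
#'   (`GCF_*`) to drop.
#' @return The filtered `genome_manifest`.
#' @export
apply_exclusions <- function(manifest, exclusions) {
  validate_manifest(manifest)
  exclusions <- as.character(exclusions)
  if (length(exclusions)) {
    bad <- !grepl("^GCF_", exclusions)
    if (any(bad))
      stop("syntactically invalid exclusion accession(s): ",
           paste(exclusions[bad], collapse = ", "))
    unknown <- setdiff(exclusions, manifest$accession)
    if (length(unknown))
      warning("exclusion accession(s) not present in manifest: ",
              paste(unknown, collapse = ", "))
  }
  keep <- !(manifest$accession %in% exclusions)
  out <- manifest[keep, , drop = FALSE]
  rownames(out) <- NULL
  new_genome_manifest(out, provenance = attr(manifest, "provenance"))
}

#' Summarize a genome manifest
#'
#' Computes the dataset-level summary: number of genomes, number of
#' distinct species labels, number of species represented by a single
#' genome, and the genome-size median/min/max in Mb. The median for even
#' numbers of genomes is the arithmetic mean of the two central values;
#' Mb values are `size_bp / 1e6` rounded half-up to 2 decimals. Species
#' identity is exact string match on the `species` column.
#'
#' @param manifest A `genome_manifest` with at least one record.
#' @return A list with elements `n_genomes`, `n_species`,
#'   `n_singleton_species`, `size_median_mb`, `size_min_mb`, `size_max_mb`.
#' @export
summarize_manifest <- function(manifest) {
  validate_manifest(manifest)
  if (nrow(manifest) == 0) stop("cannot summarize empty manifest")
  if (any(is.na(manifest$size_bp)))
    stop("cannot summarize: size_bp missing for ",
         paste(manifest$accession[is.na(manifest$size_bp)], collapse = ", "))
  sizes_mb <- manifest$size_bp / 1e6
  tab <- table(manifest$species)
  out <- list(
    n_genomes = nrow(manifest),
    n_species = length(tab),
    n_singleton_species = sum(tab == 1),
    size_median_mb = round_half_up(median(sizes_mb), 2),
    size_min_mb = round_half_up(min(sizes_mb), 2),
    size_max_mb = round_half_up(max(sizes_mb), 2)
  )
  stopifnot(out$n_singleton_species <= out$n_species,
            out$n_species <= out$n_genomes)
  out
}

#' @export
print.genome_manifest <- function(x, ...) {
  cat(sprintf("genome manifest: %d records (%d excluded as clonal/derivative)\n",
              nrow(x), sum(x$excluded_clonal)))
  prov <- attr(x, "provenance")
  if (!is.na(prov %||% NA)) cat("provenance:", prov, "\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Accessions of the four clonal or derivative assemblies excluded from
#' the bundled Komagataeibacter manifest's nonredundant set.
#' @return Character vector of four RefSeq accessions.
#' @export
clonal_exclusions <- function() {
  c("GCF_011611525.1", "GCF_014725815.1", "GCF_040581375.1", "GCF_040581385.1")
}
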