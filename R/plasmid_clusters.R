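#' Plasmid homology clustering and conservation classification
#'
#' Plasmids are clustered into homology groups by single-linkage on the
#' Mash distance matrix: two plasmids are linked when their distance is at
#' or below the threshold, and clusters are the connected components of
#' the resulting graph. Within-cluster distance dispersion separates
#' clusters consistent with conserved backbones (low median distance)
#' from mosaic-like clusters unified by shared sequence modules (high
#' median distance).
#'
#' @name plasmid_clustering
NULL

#' Cluster plasmids by single-linkage at a Mash distance threshold
#'
#' Components of size 1 are retained as singleton clusters (flagged by
#' `size == 1`) but are excluded from "clustered plasmid" counts and from
#' the presence matrix. Cluster ids are dense from 1, ordered by
#' descending size, ties broken by the lexicographically smallest member
#' ID, so "Cluster 1" is always the largest group.
#'
#' @param dm Symmetric plasmid distance matrix; row labels are plasmid
#'   IDs of the form `<accession>|<plasmid_name>`.
#' @param threshold Mash distance cutoff in (0, 1); edges are `d <=
#'   threshold`. Default 0.10.
#' @return A `plasmid_cluster_set`: list with `clusters` (data frame:
#'   `plasmid`, `host`, `cluster_id`, `size`) and `threshold_used`.
#' @export
cluster_plasmids <- function(dm, threshold = 0.10) {
  validate_distance_matrix(dm)
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  adj <- dm <= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  labels <- rownames(dm)
  groups <- split(labels, comp)
  sizes <- lengths(groups)
  smallest <- vapply(groups, function(g) min(g), character(1))
  ord <- order(-sizes, smallest)
  groups <- groups[ord]
  clusters <- do.call(rbind, lapply(seq_along(groups), function(i) {
    members <- sort(groups[[i]])
    data.frame(plasmid = members,
               host = sub("\\|.*$", "", members),
               cluster_id = i,
               size = length(members),
               stringsAsFactors = FALSE)
  }))
  rownames(clusters) <- NULL
  structure(list(clusters = clusters, threshold_used = threshold),
            class = "plasmid_cluster_set")
}

#' Within-cluster Mash distance dispersion and conservation class
#'
#' For each cluster, summarizes the `n * (n - 1) / 2` within-cluster
#' pairwise distances as median, minimum and maximum, and classifies the
#' cluster with [classify_conservation()]. Size-1 clusters have zero
#' pairs and category `"singleton"`.
#'
#' @param cs A `plasmid_cluster_set` from [cluster_plasmids()].
#' @param dm The distance matrix the clusters were built from (cluster
#'   members must all be among its labels).
#' @return Data frame with one row per cluster: `cluster_id`, `size`,
#'   `n_pairs`, `median_d`, `min_d`, `max_d`, `category`.
#' @export
dispersion_stats <- function(cs, dm) {
  validate_distance_matrix(dm)
  stopifnot(inherits(cs, "plasmid_cluster_set"))
  missing <- setdiff(cs$clusters$plasmid, rownames(dm))
  if (length(missing))
    stop("cluster member(s) absent from distance matrix: ",
         paste(missing, collapse = ", "))
  ids <- sort(unique(cs$clusters$cluster_id))
  out <- do.call(rbind, lapply(ids, function(id) {
    members <- cs$clusters$plasmid[cs$clusters$cluster_id == id]
    n <- length(members)
    if (n < 2L) {
      data.frame(cluster_id = id, size = n, n_pairs = 0L,
                 median_d = NA_real_, min_d = NA_real_, max_d = NA_real_,
                 category = "singleton", stringsAsFactors = FALSE)
    } else {
      sub <- dm[members, members]
      pd <- sub[upper.tri(sub)]
      data.frame(cluster_id = id, size = n, n_pairs = length(pd),
                 median_d = median(pd), min_d = min(pd), max_d = max(pd),
                 category = classify_conservation(median(pd)),
                 stringsAsFactors = FALSE)
    }
  }))
  rownames(out) <- NULL
  out
}

#' Classify plasmid-cluster conservation from the median Mash distance
#'
#' Median below 0.02 is `highly_conserved` (consistent with a conserved
#' backbone); between 0.02 and 0.05 inclusive is `moderately_conserved`;
#' above 0.05 is `mosaic_like` (heterogeneous, module-driven
#' relationships). Vectorized.
#'
#' @param median_d Median within-cluster Mash distance(s) in `[0, 1]`.
#' @return Character vector of categories.
#' @export
classify_conservation <- function(median_d) {
  if (any(is.na(median_d)) || any(median_d < 0 | median_d > 1))
    stop("median_d must be in [0, 1]")
  ifelse(median_d < 0.02, "highly_conserved",
         ifelse(median_d <= 0.05, "moderately_conserved", "mosaic_like"))
}

#' Genome-by-cluster presence/absence matrix
#'
#' Binary matrix over all manifest genomes (rows) and multi-member
#' clusters (columns); singleton clusters are not columns. Also reports
#' the species span of each cluster: the number of distinct species
#' labels among its host genomes.
#'
#' @param cs A `plasmid_cluster_set`.
#' @param manifest A `genome_manifest` covering every host accession.
#' @return List with `m` (binary matrix, genomes x clusters), `species`
#'   (named vector, genome -> species label), and `species_span` (data
#'   frame: `cluster_id`, `species_span`).
#' @export
presence_matrix <- function(cs, manifest) {
  stopifnot(inherits(cs, "plasmid_cluster_set"))
  validate_manifest(manifest)
  orphan <- setdiff(cs$clusters$host, manifest$accession)
  if (length(orphan))
    stop("host accession(s) not in manifest: ", paste(orphan, collapse = ", "))
  species <- setNames(manifest$species, manifest$accession)
  multi <- cs$clusters[cs$clusters$size > 1, , drop = FALSE]
  ids <- sort(unique(multi$cluster_id))
  m <- matrix(0L, nrow = nrow(manifest), length(ids),
              dimnames = list(manifest$accession,
                              if (length(ids)) paste0("cluster_", ids) else NULL))
  for (i in seq_len(nrow(multi)))
    m[multi$host[i], paste0("cluster_", multi$cluster_id[i])] <- 1L
  span <- data.frame(
    cluster_id = ids,
    species_span = vapply(ids, function(id)
      length(unique(species[multi$host[multi$cluster_id == id]])), integer(1))
  )
  list(m = m, species = species, species_span = span)
}

# normalize annotation product strings: case-fold, collapse whitespace,
# strip trailing punctuation (annotation dialects differ)
normalize_product <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("\\s+", " ", x)
  sub("[[:punct:]]+$", "", x)
}

#' CDS-product Jaccard concordance within a plasmid cluster
#'
#' Orthogonal validation of a homology cluster: pairwise Jaccard overlap
#' of normalized CDS product sets between cluster members. Jaccard of two
#' empty sets is defined as 1.
#'
#' @param members Character vector of plasmid IDs in the cluster.
#' @param products Named list mapping each plasmid ID to a character
#'   vector of CDS product strings.
#' @return List with `pairs` (data frame: `a`, `b`, `jaccard`) and
#'   `median_jaccard`.
#' @export
product_concordance <- function(members, products) {
  missing <- setdiff(members, names(products))
  if (length(missing))
    stop("no product set for cluster member(s): ",
         paste(missing, collapse = ", "))
  sets <- lapply(products[members], function(p) unique(normalize_product(p)))
  if (length(members) < 2L)
    return(list(pairs = data.frame(a = character(), b = character(),
                                   jaccard = numeric()),
                median_jaccard = NA_real_))
  cmb <- combn(members, 2)
  jac <- apply(cmb, 2, function(pr) {
    a <- sets[[pr[1]]]; b <- sets[[pr[2]]]
    u <- length(union(a, b))
    if (u == 0) 1 else length(intersect(a, b)) / u
  })
  list(pairs = data.frame(a = cmb[1, ], b = cmb[2, ], jaccard = jac,
                          stringsAsFactors = FALSE),
       median_jaccard = median(jac))
}

#' Ingest a plasmid mobility prediction table
#'
#' Reads a MOB-suite-style TSV with columns `plasmid_id`,
#' `host_accession`, `predicted_mobility`, `relaxase_type` and counts
#' plasmids per genome in each mobility class. Labels are matched
#' case-insensitively; unrecognized labels are bucketed as `unknown`
#' with a warning. The `unknown` class is preserved as its own category.
#'
#' @param path TSV path.
#' @return Data frame with one row per genome: `genome`, `conjugative`,
#'   `mobilizable`, `non_mobilizable`, `unknown`, plus a `relaxase_types`
#'   column collapsing the relaxase annotations seen in that genome.
#' @export
ingest_mobility_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  req <- c("plasmid_id", "host_accession", "predicted_mobility", "relaxase_type")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("mobility table is missing required column(s): ",
         paste(missing, collapse = ", "))
  classes <- c("conjugative", "mobilizable", "non_mobilizable", "unknown")
  lab <- gsub("-", "_", tolower(trimws(df$predicted_mobility)))
  bad <- !(lab %in% classes) & !is.na(lab)
  if (any(bad)) {
    warning("unrecognized mobility label(s) bucketed as unknown: ",
            paste(unique(df$predicted_mobility[bad]), collapse = ", "))
    lab[bad] <- "unknown"
  }
  lab[is.na(lab)] <- "unknown"
  genomes <- sort(unique(df$host_accession))
  out <- data.frame(genome = genomes, stringsAsFactors = FALSE)
  for (cl in classes)
    out[[cl]] <- vapply(genomes, function(g)
      sum(df$host_accession == g & lab == cl), integer(1), USE.NAMES = FALSE)
  out$relaxase_types <- vapply(genomes, function(g) {
    r <- df$relaxase_type[df$host_accession == g]
    r <- sort(unique(r[!is.na(r)]))
    if (length(r)) paste(r, collapse = ",") else NA_character_
  }, character(1), USE.NAMES = FALSE)
  out
}
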