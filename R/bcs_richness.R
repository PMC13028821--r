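#' Cellulose-synthesis locus anchoring and richness features
#'
#' The richness module quantifies variation in cellulose-synthesis (bcs)
#' loci and their local c-di-GMP regulatory context. Per genome, target
#' genes are identified from annotation, a single anchor contig (the one
#' where bcsA and bcsZ co-localize) standardizes the neighborhood
#' comparison, GGDEF/EAL domain signals are summarized within 50 kb of
#' the anchor locus, and the per-genome feature vectors are z-scored and
#' projected by principal component analysis.
#'
#' @name bcs_richness
NULL

.bcs_targets <- c("bcsA", "bcsB", "bcsC", "bcsD", "bcsZ", "bcsQ")

#' Default target definitions for cellulose and c-di-GMP genes
#'
#' Each target is matched by curated gene-name synonyms, case-insensitive
#' product keywords, and/or domain labels carried in the annotation
#' `domain` attribute. Dual-domain proteins (e.g. `GGDEF,EAL`) hit every
#' matching target.
#'
#' @return Named list of rules (`gene`, `product_keywords`, `domains`).
#' @export
bcs_target_defs <- function() {
  list(
    bcsA = list(gene = "bcsA",
                product_keywords = c("cellulose synthase catalytic"),
                domains = character()),
    bcsB = list(gene = "bcsB",
                product_keywords = c("cellulose synthase cyclic di-gmp-binding",
                                     "cellulose synthase subunit b"),
                domains = character()),
    bcsC = list(gene = "bcsC",
                product_keywords = c("cellulose synthase operon protein c",
                                     "cellulose synthase subunit c"),
                domains = character()),
    bcsD = list(gene = "bcsD",
                product_keywords = c("cellulose synthase operon protein d"),
                domains = character()),
    bcsZ = list(gene = "bcsZ",
                product_keywords = c("endo-1,4-beta-glucanase", "endoglucanase"),
                domains = character()),
    bcsQ = list(gene = "bcsQ",
                product_keywords = c("cellulose biosynthesis protein bcsq"),
                domains = character()),
    GGDEF = list(gene = character(),
                 product_keywords = character(),
                 domains = "GGDEF"),
    EAL = list(gene = character(),
               product_keywords = character(),
               domains = "EAL")
  )
}

#' Find cellulose/c-di-GMP target genes in a feature table
#'
#' Scans CDS rows of a feature table (see [read_features()]) against
#' target definitions. A CDS can hit several targets (dual GGDEF+EAL
#' proteins are counted once under each).
#'
#' @param features Feature data frame with columns `contig`, `type`,
#'   `start`, `end`, `strand` and attribute columns `genome` plus any of
#'   `gene`, `product`, `domain` (comma-separated for multiple domains).
#' @param target_defs Definitions as from [bcs_target_defs()].
#' @return Data frame of target hits: `genome`, `target`, `contig`,
#'   `start`, `end`, `strand`.
#' @export
find_targets <- function(features, target_defs = bcs_target_defs()) {
  empty <- data.frame(genome = character(), target = character(),
                      contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  if (nrow(features) == 0) return(empty)
  if (!"genome" %in% names(features))
    stop("feature table must carry a 'genome' column")
  cds <- features[features$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0) return(empty)
  gene <- tolower(cds$gene %||% rep(NA_character_, nrow(cds)))
  product <- tolower(cds$product %||% rep(NA_character_, nrow(cds)))
  domain <- cds$domain %||% rep(NA_character_, nrow(cds))
  domain_sets <- strsplit(ifelse(is.na(domain), "", domain), ",\\s*")
  hits <- lapply(names(target_defs), function(tn) {
    def <- target_defs[[tn]]
    hit <- rep(FALSE, nrow(cds))
    if (length(def$gene))
      hit <- hit | (!is.na(gene) & gene %in% tolower(def$gene))
    for (kw in def$product_keywords)
      hit <- hit | (!is.na(product) & grepl(kw, product, fixed = TRUE))
    if (length(def$domains))
      hit <- hit | vapply(domain_sets, function(ds)
        any(ds %in% def$domains), logical(1))
    if (!any(hit)) return(NULL)
    data.frame(genome = cds$genome[hit], target = tn,
               contig = cds$contig[hit],
               start = as.integer(cds$start[hit]),
               end = as.integer(cds$end[hit]),
               strand = cds$strand[hit], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out[order(out$genome, out$target, out$contig, out$start), , drop = FALSE]
}

#' Select the per-genome bcs anchor contig
#'
#' The anchor contig is the contig on which bcsA and bcsZ co-localize.
#' Genomes with no such contig are flagged as non-qualifying (not an
#' error) and are excluded from anchor-based window summaries. When more
#' than one contig qualifies, the contig carrying more distinct bcs
#' targets wins; remaining ties go to the longer contig (if lengths are
#' supplied) and then to the lexicographically smallest contig ID.
#'
#' @param hits Target hits for a single genome (from [find_targets()]).
#' @param contig_lengths Optional named vector of contig lengths used in
#'   tie-breaking.
#' @return One-row data frame: `genome`, `qualifies`, `anchor_contig`,
#'   `span_start`, `span_end`, `bcsA_copy_count`, `bcsA_dispersed`,
#'   and on-anchor presence flags `bcsB_on_anchor` ... `bcsQ_on_anchor`.
#' @export
select_anchor <- function(hits, contig_lengths = NULL) {
  genome <- unique(hits$genome)
  if (length(genome) > 1L) stop("hits must come from a single genome")
  if (length(genome) == 0L) genome <- NA_character_
  bcs <- hits[hits$target %in% .bcs_targets, , drop = FALSE]
  a_contigs <- unique(bcs$contig[bcs$target == "bcsA"])
  z_contigs <- unique(bcs$contig[bcs$target == "bcsZ"])
  candidates <- intersect(a_contigs, z_contigs)
  bcsA_n <- sum(bcs$target == "bcsA")
  dispersed <- length(a_contigs) > 1L
  flags <- setNames(rep(FALSE, 5), paste0(c("bcsB", "bcsC", "bcsD", "bcsZ", "bcsQ"),
                                          "_on_anchor"))
  base <- data.frame(genome = genome, qualifies = FALSE,
                     anchor_contig = NA_character_,
                     span_start = NA_integer_, span_end = NA_integer_,
                     bcsA_copy_count = bcsA_n, bcsA_dispersed = dispersed,
                     stringsAsFactors = FALSE)
  if (length(candidates) == 0L) return(cbind(base, as.list(flags)))
  if (length(candidates) > 1L) {
    n_targets <- vapply(candidates, function(ct)
      length(unique(bcs$target[bcs$contig == ct])), integer(1))
    len <- if (is.null(contig_lengths)) rep(0, length(candidates))
           else unname(contig_lengths[candidates])
    len[is.na(len)] <- 0
    ord <- order(-n_targets, -len, candidates)
    candidates <- candidates[ord]
  }
  anchor <- candidates[1L]
  on_anchor <- bcs[bcs$contig == anchor, , drop = FALSE]
  base$qualifies <- TRUE
  base$anchor_contig <- anchor
  base$span_start <- min(on_anchor$start)
  base$span_end <- max(on_anchor$end)
  for (t in c("bcsB", "bcsC", "bcsD", "bcsZ", "bcsQ"))
    flags[paste0(t, "_on_anchor")] <- t %in% on_anchor$target
  cbind(base, as.list(flags))
}

#' Summarize GGDEF/EAL signals within 50 kb of the anchor locus
#'
#' A domain gene counts when its CDS interval intersects (closed
#' intervals) the window `[span_start - window_bp, span_end + window_bp]`
#' clipped to the contig, on the anchor contig only. The anchor locus is
#' the full span of anchor-contig bcs hits.
#'
#' @param hits Target hits for the genome (must include GGDEF/EAL rows).
#' @param anchor Anchor selection row from [select_anchor()]; must
#'   qualify.
#' @param window_bp Window half-width in bp on each side of the span
#'   (default 50000).
#' @param contig_lengths Optional named contig lengths for clipping the
#'   window's right edge.
#' @return List: `ggdef_present`, `eal_present`, `ggdef_count`,
#'   `eal_count`.
#' @export
window_signals <- function(hits, anchor, window_bp = 50000,
                           contig_lengths = NULL) {
  if (!isTRUE(anchor$qualifies))
    stop("window_signals called on a non-qualifying anchor")
  win_start <- max(1, anchor$span_start - window_bp)
  win_end <- anchor$span_end + window_bp
  if (!is.null(contig_lengths) && anchor$anchor_contig %in% names(contig_lengths))
    win_end <- min(win_end, contig_lengths[[anchor$anchor_contig]])
  count_in <- function(target) {
    h <- hits[hits$target == target & hits$contig == anchor$anchor_contig, ,
              drop = FALSE]
    sum(h$start <= win_end & h$end >= win_start)
  }
  gg <- count_in("GGDEF")
  ea <- count_in("EAL")
  list(ggdef_present = gg > 0, eal_present = ea > 0,
       ggdef_count = gg, eal_count = ea)
}

# amino-acid 5-mer set of a protein sequence; sequences shorter than the
# word size contribute themselves as a single token
aa_kmer_set <- function(seq, k = 5L) {
  n <- nchar(seq)
  if (n < k) return(seq)
  unique(substring(seq, seq_len(n - k + 1L), k:n))
}

#' Per-genome similarity to the medoid target sequence
#'
#' For each target carried by at least two genomes, pairwise distance
#' between protein sequences is 1 minus the Jaccard of amino-acid 5-mer
#' sets; the medoid is the sequence minimizing the summed distance to all
#' others (ties broken by lexicographic genome ID), and the feature is
#' 1 minus the distance to the medoid. Genomes lacking the target get 0.
#'
#' @param protein_seqs Nested named list: target -> genome -> protein
#'   sequence string.
#' @param genomes Optional character vector fixing the output genome set
#'   (defaults to the union over targets).
#' @return Numeric matrix, genomes x targets, values in `[0, 1]`.
#' @export
medoid_similarity <- function(protein_seqs, genomes = NULL) {
  if (is.null(genomes))
    genomes <- sort(unique(unlist(lapply(protein_seqs, names))))
  out <- matrix(0, length(genomes), length(protein_seqs),
                dimnames = list(genomes, names(protein_seqs)))
  for (target in names(protein_seqs)) {
    seqs <- protein_seqs[[target]]
    carriers <- intersect(genomes, names(seqs))
    if (length(carriers) < 2L) next
    sets <- lapply(seqs[carriers], aa_kmer_set)
    n <- length(carriers)
    d <- matrix(0, n, n, dimnames = list(carriers, carriers))
    for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
      u <- length(union(sets[[i]], sets[[j]]))
      jac <- if (u == 0) 1 else length(intersect(sets[[i]], sets[[j]])) / u
      d[i, j] <- d[j, i] <- 1 - jac
    }
    sums <- rowSums(d)
    medoid <- carriers[order(sums, carriers)][1L]
    out[carriers, target] <- 1 - d[, medoid]
  }
  out
}

#' Assemble and z-score the richness feature matrix
#'
#' Combines anchor architecture features (bcsA copy count and dispersal,
#' on-anchor presence flags), 50-kb window GGDEF/EAL signals (0-imputed
#' for non-qualifying genomes, which are flagged), and per-target medoid
#' similarities into one numeric matrix, then centers and scales each
#' column. Constant columns are dropped before PCA and recorded in the
#' scaling record.
#'
#' @param anchors Data frame of per-genome anchor selections (rbind of
#'   [select_anchor()] rows).
#' @param windows Data frame with columns `genome`, `ggdef_present`,
#'   `eal_present`, `ggdef_count`, `eal_count` for qualifying genomes.
#' @param similarities Optional medoid-similarity matrix from
#'   [medoid_similarity()] (rows matched to genomes; missing rows are 0).
#' @return A `richness_matrix`: list with `x` (scaled matrix), `raw`,
#'   `center`, `scale`, `dropped` (constant feature names), and
#'   `non_qualifying` (genome IDs without an anchor).
#' @export
build_feature_matrix <- function(anchors, windows, similarities = NULL) {
  if (nrow(anchors) < 2L) stop("need at least 2 genomes")
  genomes <- anchors$genome
  flag_cols <- paste0(c("bcsB", "bcsC", "bcsD", "bcsZ", "bcsQ"), "_on_anchor")
  raw <- data.frame(row.names = genomes)
  raw$bcsA_copy_count <- anchors$bcsA_copy_count
  raw$bcsA_dispersed <- as.numeric(anchors$bcsA_dispersed)
  for (fc in flag_cols) raw[[fc]] <- as.numeric(anchors[[fc]])
  for (wc in c("ggdef_present", "eal_present", "ggdef_count", "eal_count")) {
    v <- setNames(rep(0, length(genomes)), genomes)
    if (nrow(windows)) {
      known <- intersect(windows$genome, genomes)
      v[known] <- as.numeric(windows[[wc]][match(known, windows$genome)])
    }
    raw[[wc]] <- v
  }
  if (!is.null(similarities)) {
    for (target in colnames(similarities)) {
      v <- setNames(rep(0, length(genomes)), genomes)
      known <- intersect(rownames(similarities), genomes)
      v[known] <- similarities[known, target]
      raw[[paste0("sim_", target)]] <- v
    }
  }
  raw <- as.matrix(raw)
  if (anyNA(raw)) stop("feature matrix contains NA after imputation")
  sds <- apply(raw, 2, sd)
  keep <- sds > 0
  x <- scale(raw[, keep, drop = FALSE])
  structure(list(x = x[, , drop = FALSE], raw = raw,
                 center = attr(x, "scaled:center"),
                 scale = attr(x, "scaled:scale"),
                 dropped = colnames(raw)[!keep],
                 non_qualifying = genomes[!anchors$qualifies]),
            class = "richness_matrix")
}

#' Principal component projection of the richness matrix
#'
#' Eigen-decomposition of the covariance of the scaled feature matrix.
#' Components are ordered by eigenvalue; the sign of each component is
#' fixed so that its largest-magnitude loading is positive.
#' `variance_explained` fractions are relative to the total variance, so
#' they are non-increasing and sum to at most 1.
#'
#' @param m A `richness_matrix` from [build_feature_matrix()].
#' @param n_components Number of components to retain (default 2).
#' @return A list with `scores` (genomes x components), `loadings`
#'   (features x components) and `variance_explained`.
#' @export
pca_project <- function(m, n_components = 2L) {
  stopifnot(inherits(m, "richness_matrix"))
  x <- m$x
  if (nrow(x) < 2L) stop("need at least 2 genomes")
  if (ncol(x) < 1L) stop("no variance to project")
  p <- prcomp(x, center = FALSE, scale. = FALSE)
  nc <- min(n_components, ncol(p$rotation))
  scores <- p$x[, seq_len(nc), drop = FALSE]
  loadings <- p$rotation[, seq_len(nc), drop = FALSE]
  for (j in seq_len(nc)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ve <- (p$sdev^2 / sum(p$sdev^2))[seq_len(nc)]
  list(scores = scores, loadings = loadings, variance_explained = ve)
}
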