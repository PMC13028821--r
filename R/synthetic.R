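#' Seeded synthetic genome sets with ground truth
#'
#' The generator emits a complete, deterministic test bed for the
#' pipeline: multi-replicon assemblies (chromosome plus plasmids),
#' plasmid families with shared backbones or shared modules, multicopy
#' bcsA architectures with or without nearby GGDEF/EAL genes, planted IS
#' elements and prophage-length regions, a manifest, a pangenome
#' membership table, and a machine-readable truth record for every
#' planted element. Identical configuration and seed give byte-identical
#' output files.
#'
#' @name synthetic_data
NULL

#' Configuration for a synthetic genome set
#'
#' Defaults emulate the shape of the curated Komagataeibacter dataset:
#' 18 genomes of chromosome length 3.76 Mb across 10 species labels
#' (3 singleton species); a mosaic plasmid family of 7 members
#' (module_fraction 0.3) and a conserved backbone family of 6 (per-base
#' mutation rate 0.005) echoing the two dominant homology clusters, plus
#' four small backbone families and 5 unclustered singleton plasmids
#' spread over 13 plasmid-bearing genomes; per-genome IS counts drawn in
#' [50, 181] with element lengths in [700, 2500]; 1-4 prophage regions
#' per genome with lengths in [10080, 70900]; and a bcs architecture
#' table with 17 qualifying anchors (14 with GGDEF and EAL within the
#' 50-kb window), one non-qualifying genome, and 3 genomes with
#' dispersed bcsA copies.
#'
#' @param n_genomes Number of genomes.
#' @param chromosome_length_bp Chromosome length in bp.
#' @param species Character vector of species labels, one per genome.
#' @param plasmid_families List of family specs: `mode` ("backbone" or
#'   "mosaic"), `n_members`, `length_bp`, `mutation_rate` (backbone),
#'   `module_fraction` (mosaic).
#' @param n_singleton_plasmids Unrelated plasmids planted as singletons.
#' @param singleton_plasmid_length_range Length range for those.
#' @param n_plasmid_genomes How many genomes carry plasmids.
#' @param bcs Data frame with one row per genome: `anchor` (logical),
#'   `bcsA_copies`, `dispersed`, `ggdef_in_window`, `eal_in_window`.
#' @param is_elements List: `count_range`, `length_range`.
#' @param prophage List: `count_range`, `length_range`.
#' @param membership List: `n_core`, `n_accessory`, `accessory_prob`,
#'   `singleton_range`.
#' @param seed Integer seed driving every random draw.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_genomes = 18L,
                         chromosome_length_bp = 3760000L,
                         species = NULL,
                         plasmid_families = NULL,
                         n_singleton_plasmids = 5L,
                         singleton_plasmid_length_range = c(8000L, 30000L),
                         n_plasmid_genomes = 13L,
                         bcs = NULL,
                         is_elements = list(count_range = c(50L, 181L),
                                            length_range = c(700L, 2500L)),
                         prophage = list(count_range = c(1L, 4L),
                                         length_range = c(10080L, 70900L)),
                         membership = list(n_core = 300L, n_accessory = 700L,
                                           accessory_prob = 0.5,
                                           singleton_range = c(20L, 326L)),
                         seed = 1L) {
  if (is.null(species)) {
    stopifnot(n_genomes == 18L)
    species <- c("sp01", rep("sp02", 3), rep("sp03", 2), rep("sp04", 2),
                 rep("sp05", 2), rep("sp06", 2), rep("sp07", 2),
                 rep("sp08", 2), "sp09", "sp10")
  }
  if (is.null(plasmid_families)) {
    plasmid_families <- list(
      list(mode = "mosaic", n_members = 7L, length_bp = 40000L,
           module_fraction = 0.3),
      list(mode = "backbone", n_members = 6L, length_bp = 40000L,
           mutation_rate = 0.005),
      list(mode = "backbone", n_members = 3L, length_bp = 25000L,
           mutation_rate = 0.005),
      list(mode = "backbone", n_members = 3L, length_bp = 20000L,
           mutation_rate = 0.005),
      list(mode = "backbone", n_members = 2L, length_bp = 15000L,
           mutation_rate = 0.005),
      list(mode = "backbone", n_members = 2L, length_bp = 12000L,
           mutation_rate = 0.005)
    )
  }
  if (is.null(bcs)) {
    stopifnot(n_genomes == 18L)
    bcs <- data.frame(
      anchor = c(rep(TRUE, 17), FALSE),
      bcsA_copies = c(rep(2L, 14), 3L, 3L, 2L, 3L),
      dispersed = c(rep(FALSE, 14), TRUE, TRUE, FALSE, TRUE),
      ggdef_in_window = c(rep(TRUE, 14), rep(FALSE, 4)),
      eal_in_window = c(rep(TRUE, 14), rep(FALSE, 4))
    )
  }
  cfg <- list(n_genomes = as.integer(n_genomes),
              chromosome_length_bp = as.integer(chromosome_length_bp),
              species = species,
              plasmid_families = plasmid_families,
              n_singleton_plasmids = as.integer(n_singleton_plasmids),
              singleton_plasmid_length_range = as.integer(singleton_plasmid_length_range),
              n_plasmid_genomes = as.integer(n_plasmid_genomes),
              bcs = bcs, is_elements = is_elements, prophage = prophage,
              membership = membership, seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_genomes >= 1L,
            length(cfg$species) == cfg$n_genomes,
            nrow(cfg$bcs) == cfg$n_genomes,
            cfg$chromosome_length_bp > 0,
            cfg$n_plasmid_genomes <= cfg$n_genomes)
  for (fam in cfg$plasmid_families) {
    stopifnot(fam$mode %in% c("backbone", "mosaic"),
              fam$n_members >= 1L, fam$length_bp > 0)
    if (fam$mode == "backbone")
      stopifnot(fam$mutation_rate >= 0, fam$mutation_rate <= 1)
    if (fam$mode == "mosaic")
      stopifnot(fam$module_fraction > 0, fam$module_fraction < 1)
    if (fam$n_members > cfg$n_plasmid_genomes)
      stop("plasmid family larger than the number of plasmid-bearing genomes")
  }
  # feasibility: planted elements plus the reserved bcs region must fit
  worst <- cfg$is_elements$count_range[2] * cfg$is_elements$length_range[2] +
    cfg$prophage$count_range[2] * cfg$prophage$length_range[2] +
    2 * (cfg$is_elements$count_range[2] + cfg$prophage$count_range[2])
  reserved <- 140000 + 30000
  if (worst + reserved > cfg$chromosome_length_bp)
    stop("infeasible config: planted elements exceed chromosome length")
  invisible(cfg)
}

#' Substitute bases of a backbone sequence at a fixed per-base rate
#'
#' Each position is substituted independently with probability `rate`,
#' to a uniformly chosen different base. No indels, so exact k-mer
#' Jaccard oracles on backbone pairs stay simple.
#'
#' @param backbone Nucleotide string.
#' @param rate Per-base substitution probability in `[0, 0.5]`.
#' @param seed Optional integer seed for a self-contained draw.
#' @return List: `seq` (mutated sequence), `n_substitutions` (realized
#'   count).
#' @export
mutate_backbone <- function(backbone, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 0.5)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  }
  n <- nchar(backbone)
  idx <- which(runif(n) < rate)
  if (length(idx) == 0L)
    return(list(seq = backbone, n_substitutions = 0L))
  ch <- strsplit(backbone, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  code <- match(ch[idx], bases)
  shift <- sample.int(3L, length(idx), replace = TRUE)
  ch[idx] <- bases[((code - 1L + shift) %% 4L) + 1L]
  list(seq = paste(ch, collapse = ""), n_substitutions = length(idx))
}

#' Plant a mosaic plasmid family around a shared module
#'
#' Each member carries the shared module at a random position, embedded
#' in independent random filler so the module occupies `module_fraction`
#' of the member's length. Such families have high within-family Mash
#' distances despite guaranteed partial homology, emulating
#' module-driven plasmid relationships.
#'
#' @param module Shared nucleotide module.
#' @param n_members Number of member plasmids.
#' @param module_fraction Fraction of each member occupied by the
#'   module, in (0, 1).
#' @param seed Optional integer seed.
#' @return Character vector of member sequences.
#' @export
plant_mosaic_family <- function(module, n_members, module_fraction,
                                seed = NULL) {
  stopifnot(module_fraction > 0, module_fraction < 1, n_members >= 1)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  }
  mod_len <- nchar(module)
  member_len <- as.integer(round(mod_len / module_fraction))
  filler_len <- member_len - mod_len
  vapply(seq_len(n_members), function(i) {
    if (filler_len == 0L) return(module)
    filler <- random_dna(filler_len)
    pos <- sample.int(filler_len + 1L, 1L) - 1L  # module after `pos` filler bases
    paste0(substr(filler, 1, pos), module,
           substr(filler, pos + 1L, filler_len))
  }, character(1))
}

# place `lengths` as non-overlapping intervals (gaps >= 1) inside
# [lo, hi]; returns data.frame(start, end)
place_intervals <- function(lengths, lo, hi) {
  n <- length(lengths)
  if (n == 0L) return(data.frame(start = integer(), end = integer()))
  slack <- (hi - lo + 1) - sum(lengths)
  if (slack < n) stop("infeasible placement: elements exceed region length")
  offsets <- sort(sample.int(slack, n))
  starts <- lo - 1L + offsets + c(0, cumsum(lengths[-n]))
  data.frame(start = as.integer(starts),
             end = as.integer(starts + lengths - 1L))
}

.bcs_gene_lengths <- c(bcsQ = 753L, bcsA = 2202L, bcsB = 2406L,
                       bcsC = 3900L, bcsD = 468L, bcsZ = 1104L)
.bcs_products <- c(
  bcsA = "cellulose synthase catalytic subunit [UDP-forming]",
  bcsB = "cellulose synthase cyclic di-GMP-binding regulatory subunit",
  bcsC = "cellulose synthase operon protein C",
  bcsD = "cellulose synthase operon protein D",
  bcsZ = "endo-1,4-beta-glucanase",
  bcsQ = "cellulose biosynthesis protein BcsQ")

#' Plant a bcs locus and its c-di-GMP neighborhood
#'
#' Emits annotation rows for one genome's cellulose-synthesis locus:
#' either a qualifying architecture (bcsA and bcsZ co-localized on the
#' first contig, bcsQ included) or a non-qualifying one (bcsZ moved to
#' the second contig), optional dispersed bcsA copies on the second
#' contig, and GGDEF/EAL genes placed inside the 50-kb anchor window or
#' well outside it (62-80 kb away) according to the spec flags.
#'
#' @param genome Genome accession planted into the rows.
#' @param contigs Named integer vector of contig lengths; the first is
#'   the chromosome (anchor candidate), the second hosts displaced
#'   genes when needed.
#' @param spec List/row: `anchor`, `bcsA_copies`, `dispersed`,
#'   `ggdef_in_window`, `eal_in_window`.
#' @param locus_start Chromosome coordinate where the operon starts.
#' @return List: `features` (annotation rows), `truth` (planted values:
#'   anchor contig, qualifies, copy counts, window flags, span).
#' @export
plant_bcs_locus <- function(genome, contigs, spec, locus_start = 1500000L) {
  chr <- names(contigs)[1]
  needs_second <- !isTRUE(spec$anchor) || isTRUE(spec$dispersed)
  # a non-qualifying genome with dispersed bcsA needs a third contig, so
  # the displaced bcsZ and the extra bcsA copies cannot co-localize
  needs_third <- !isTRUE(spec$anchor) && isTRUE(spec$dispersed)
  if (needs_second && length(contigs) < 2L)
    stop("infeasible placement: spec needs a second contig")
  if (needs_third && length(contigs) < 3L)
    stop("infeasible placement: spec needs a third contig")
  second <- if (length(contigs) >= 2L) names(contigs)[2] else NA_character_
  extra_contig <- if (needs_third) names(contigs)[3] else second
  row <- function(contig, target, start, gene_len, domain = NA_character_,
                  product = NA_character_, gene = NA_character_) {
    end <- start + gene_len - 1L
    if (end > contigs[[contig]])
      stop("infeasible placement: gene exceeds contig length")
    data.frame(contig = contig, type = "CDS", start = as.integer(start),
               end = as.integer(end), strand = "+", genome = genome,
               gene = gene, product = product, domain = domain,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  pos <- as.integer(locus_start)
  operon <- if (isTRUE(spec$anchor)) names(.bcs_gene_lengths)
            else setdiff(names(.bcs_gene_lengths), c("bcsZ", "bcsQ"))
  for (g in operon) {
    rows[[length(rows) + 1L]] <-
      row(chr, g, pos, .bcs_gene_lengths[[g]], gene = g,
          product = .bcs_products[[g]])
    pos <- pos + .bcs_gene_lengths[[g]] + 80L
  }
  if (!isTRUE(spec$anchor)) {
    # bcsZ and bcsQ displaced to the second contig: no co-localization
    rows[[length(rows) + 1L]] <- row(second, "bcsZ", 3000L,
                                     .bcs_gene_lengths[["bcsZ"]],
                                     gene = "bcsZ",
                                     product = .bcs_products[["bcsZ"]])
    rows[[length(rows) + 1L]] <- row(second, "bcsQ", 6000L,
                                     .bcs_gene_lengths[["bcsQ"]],
                                     gene = "bcsQ",
                                     product = .bcs_products[["bcsQ"]])
  }
  extra <- max(0L, as.integer(spec$bcsA_copies) - 1L)
  if (extra > 0L) {
    if (isTRUE(spec$dispersed)) {
      for (i in seq_len(extra))
        rows[[length(rows) + 1L]] <-
          row(extra_contig, "bcsA", 12000L + (i - 1L) * 3000L,
              .bcs_gene_lengths[["bcsA"]], gene = "bcsA",
              product = .bcs_products[["bcsA"]])
    } else {
      for (i in seq_len(extra)) {
        rows[[length(rows) + 1L]] <-
          row(chr, "bcsA", pos, .bcs_gene_lengths[["bcsA"]], gene = "bcsA",
              product = .bcs_products[["bcsA"]])
        pos <- pos + .bcs_gene_lengths[["bcsA"]] + 500L
      }
    }
  }
  feats <- do.call(rbind, rows)
  on_chr <- feats[feats$contig == chr, , drop = FALSE]
  span <- c(min(on_chr$start), max(on_chr$end))
  qualifies <- isTRUE(spec$anchor)
  # c-di-GMP neighborhood genes, relative to the planted span
  dom_row <- function(domain, product, offset) {
    start <- span[2] + as.integer(offset)
    row(chr, domain, start, 1497L, domain = domain, product = product)
  }
  gg_off <- if (isTRUE(spec$ggdef_in_window)) 10000L else 62000L
  ea_off <- if (isTRUE(spec$eal_in_window)) 14000L else 75000L
  feats <- rbind(feats,
                 dom_row("GGDEF", "diguanylate cyclase", gg_off),
                 dom_row("EAL", "c-di-GMP phosphodiesterase", ea_off))
  truth <- list(
    anchor_contig = if (qualifies) chr else NA_character_,
    qualifies = qualifies,
    bcsA_copy_count = as.integer(spec$bcsA_copies),
    bcsA_dispersed = isTRUE(spec$dispersed),
    bcsQ_on_anchor = qualifies,
    ggdef_in_window = qualifies && isTRUE(spec$ggdef_in_window),
    eal_in_window = qualifies && isTRUE(spec$eal_in_window),
    span_start = span[1], span_end = span[2]
  )
  list(features = feats, truth = truth)
}

# random protein string over the 20 standard amino acids
random_protein <- function(n) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

mutate_protein <- function(seq, rate = 0.02) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- which(runif(length(ch)) < rate)
  if (length(idx))
    ch[idx] <- sample(aa, length(idx), replace = TRUE)
  paste(ch, collapse = "")
}

#' Generate a synthetic genome set with ground truth
#'
#' Builds the full artifact in memory first (so an infeasible
#' configuration errors before any file is written), then writes, under
#' `outdir`: `genomes/<accession>.fna` (chromosome plus any extra
#' contig and hosted plasmids), `plasmids.fna` (catalog, record IDs
#' `<accession>|<plasmid>`), `features.gff3`, `elements.tsv` (IS and
#' prophage annotations), `manifest.tsv`, `membership.tsv`,
#' `proteins.faa` (per-target protein sequences, IDs
#' `<accession>|<target>`), and `truth.json`.
#'
#' @param config A [synth_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths) and
#'   `truth` (the truth record, also serialized as JSON).
#' @export
generate_genome_set <- function(config, outdir) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  n <- config$n_genomes
  acc <- sprintf("GCF_9%05d.1", seq_len(n))
  chr_id <- paste0(acc, "|chr")
  L <- config$chromosome_length_bp

  ## ---- plasmid families ----
  plasmid_seqs <- list()       # plasmid id -> sequence
  plasmid_host <- character()  # plasmid id -> genome accession
  plasmid_counter <- integer(n)
  families_truth <- list()
  npg <- config$n_plasmid_genomes
  expected_cat <- function(fam) {
    if (fam$n_members == 1L) return("singleton")
    if (fam$mode == "mosaic") return("mosaic_like")
    d <- 2 * fam$mutation_rate   # expected pairwise divergence
    if (d < 0.02) "highly_conserved"
    else if (d <= 0.05) "moderately_conserved" else "mosaic_like"
  }
  add_plasmid <- function(g, seq) {
    plasmid_counter[g] <<- plasmid_counter[g] + 1L
    id <- sprintf("%s|p%02d", acc[g], plasmid_counter[g])
    plasmid_seqs[[id]] <<- seq
    plasmid_host[id] <<- acc[g]
    id
  }
  for (f in seq_along(config$plasmid_families)) {
    fam <- config$plasmid_families[[f]]
    seqs <- if (fam$mode == "backbone") {
      ancestor <- random_dna(fam$length_bp)
      vapply(seq_len(fam$n_members), function(i)
        mutate_backbone(ancestor, fam$mutation_rate)$seq, character(1))
    } else {
      module <- random_dna(as.integer(round(fam$length_bp * fam$module_fraction)))
      plant_mosaic_family(module, fam$n_members, fam$module_fraction)
    }
    hosts <- ((f - 1L) * 2L + seq_len(fam$n_members) - 1L) %% npg + 1L
    ids <- vapply(seq_len(fam$n_members), function(i)
      add_plasmid(hosts[i], seqs[i]), character(1))
    families_truth[[sprintf("family_%d", f)]] <- list(
      mode = fam$mode, members = ids,
      expected_category = expected_cat(fam))
  }
  if (config$n_singleton_plasmids > 0L) {
    hosts <- sample.int(npg, config$n_singleton_plasmids, replace = TRUE)
    for (i in seq_len(config$n_singleton_plasmids)) {
      len <- sample(seq(config$singleton_plasmid_length_range[1],
                        config$singleton_plasmid_length_range[2]), 1L)
      id <- add_plasmid(hosts[i], random_dna(len))
      families_truth[[id]] <- list(mode = "singleton", members = id,
                                   expected_category = "singleton")
    }
  }

  ## ---- per-genome chromosome, bcs locus, mobilome ----
  locus_start <- as.integer(min(1500000L, max(200000L, L %/% 2)))
  reserve_lo <- locus_start - 30000L
  reserve_hi <- locus_start + 110000L
  if (reserve_lo < 1L || reserve_hi > L)
    stop("infeasible config: chromosome too short for the bcs neighborhood")
  genome_seqs <- vector("list", n)     # per genome: named contig sequences
  feature_rows <- list()
  element_rows <- list()
  genome_truth <- vector("list", n)
  names(genome_truth) <- acc
  base_proteins <- setNames(
    lapply(seq_along(c(.bcs_targets, "GGDEF", "EAL")), function(i)
      random_protein(350L)),
    c(.bcs_targets, "GGDEF", "EAL"))
  protein_records <- list()

  for (g in seq_len(n)) {
    spec <- config$bcs[g, , drop = FALSE]
    contigs <- setNames(L, chr_id[g])
    needs_second <- !isTRUE(spec$anchor) || isTRUE(spec$dispersed)
    needs_third <- !isTRUE(spec$anchor) && isTRUE(spec$dispersed)
    extra_seqs <- list()
    if (needs_second) {
      contigs <- c(contigs, setNames(60000L, paste0(acc[g], "|ctg2")))
      extra_seqs[[paste0(acc[g], "|ctg2")]] <- random_dna(60000L)
    }
    if (needs_third) {
      contigs <- c(contigs, setNames(60000L, paste0(acc[g], "|ctg3")))
      extra_seqs[[paste0(acc[g], "|ctg3")]] <- random_dna(60000L)
    }
    locus <- plant_bcs_locus(acc[g], contigs, as.list(spec), locus_start)
    feature_rows[[g]] <- locus$features

    # IS and prophage placement outside the reserved bcs neighborhood
    is_count <- sample(seq(config$is_elements$count_range[1],
                           config$is_elements$count_range[2]), 1L)
    is_len <- sample(seq(config$is_elements$length_range[1],
                         config$is_elements$length_range[2]),
                     is_count, replace = TRUE)
    ph_count <- sample(seq(config$prophage$count_range[1],
                           config$prophage$count_range[2]), 1L)
    ph_len <- sample(seq(config$prophage$length_range[1],
                         config$prophage$length_range[2]),
                     ph_count, replace = TRUE)
    lens <- c(is_len, ph_len)
    types <- c(rep("IS", is_count), rep("prophage_region", ph_count))
    fams <- c(sample(c("IS110", "IS3", "IS5", "IS21", "IS256", "ISL3"),
                     is_count, replace = TRUE),
              rep(NA_character_, ph_count))
    # split between the two free arms proportionally to their capacity
    cap1 <- reserve_lo - 1L
    cap2 <- L - reserve_hi
    in_arm1 <- runif(length(lens)) < cap1 / (cap1 + cap2)
    placed <- rbind(
      if (any(in_arm1)) cbind(place_intervals(lens[in_arm1], 1L, cap1),
                              i = which(in_arm1)),
      if (any(!in_arm1)) cbind(place_intervals(lens[!in_arm1],
                                               reserve_hi + 1L, L),
                               i = which(!in_arm1)))
    placed <- placed[order(placed$i), , drop = FALSE]
    element_rows[[g]] <- data.frame(
      genome = acc[g], element_type = types, contig = chr_id[g],
      start = placed$start, end = placed$end, family = fams,
      stringsAsFactors = FALSE)

    chrom <- random_dna(L)
    genome_seqs[[g]] <- c(setNames(list(chrom), chr_id[g]), extra_seqs)

    # per-target protein sequences (slightly diverged from a shared base)
    targets_here <- unique(locus$features$gene[!is.na(locus$features$gene)])
    targets_here <- c(targets_here, "GGDEF", "EAL")
    for (t in targets_here)
      protein_records[[sprintf("%s|%s", acc[g], t)]] <-
        mutate_protein(base_proteins[[t]])

    genome_truth[[g]] <- c(locus$truth, list(
      is_count = is_count,
      is_total_bp = sum(is_len),
      prophage_count = ph_count,
      prophage_lengths = ph_len,
      plasmids = names(plasmid_host)[plasmid_host == acc[g]]))
  }

  ## ---- pangenome membership ----
  mem <- config$membership
  rows <- list()
  core_ids <- sprintf("GC_C%04d", seq_len(mem$n_core))
  for (id in core_ids)
    rows[[length(rows) + 1L]] <- data.frame(cluster_id = id, genome = acc,
                                            present = 1L)
  for (a in seq_len(mem$n_accessory)) {
    pres <- runif(n) < mem$accessory_prob
    if (!any(pres)) pres[sample.int(n, 1L)] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      cluster_id = sprintf("GC_A%04d", a), genome = acc[pres], present = 1L)
  }
  singleton_counts <- sample(seq(mem$singleton_range[1],
                                 mem$singleton_range[2]), n, replace = TRUE)
  for (g in seq_len(n)) {
    if (singleton_counts[g] == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      cluster_id = sprintf("GC_S%02d_%04d", g, seq_len(singleton_counts[g])),
      genome = acc[g], present = 1L)
    genome_truth[[g]]$singleton_clusters <- singleton_counts[g]
  }
  membership_df <- do.call(rbind, rows)

  ## ---- manifest ----
  plasmid_len_by_genome <- vapply(acc, function(a) {
    ids <- names(plasmid_host)[plasmid_host == a]
    sum(nchar(unlist(plasmid_seqs[ids]))) + 0
  }, numeric(1))
  size_bp <- vapply(seq_len(n), function(g)
    sum(nchar(unlist(genome_seqs[[g]]))) + plasmid_len_by_genome[g], numeric(1))
  manifest_df <- data.frame(
    accession = acc, species = config$species,
    strain = sprintf("SYN%02d", seq_len(n)),
    size_bp = as.integer(size_bp),
    source = "synthetic", excluded_clonal = FALSE,
    stringsAsFactors = FALSE)

  truth <- list(seed = config$seed,
                n_genomes = n,
                genomes = genome_truth,
                plasmid_families = families_truth)

  ## ---- write everything ----
  dir.create(file.path(outdir, "genomes"), recursive = TRUE,
             showWarnings = FALSE)
  paths <- list(
    plasmids = file.path(outdir, "plasmids.fna"),
    features = file.path(outdir, "features.gff3"),
    elements = file.path(outdir, "elements.tsv"),
    manifest = file.path(outdir, "manifest.tsv"),
    membership = file.path(outdir, "membership.tsv"),
    proteins = file.path(outdir, "proteins.faa"),
    truth = file.path(outdir, "truth.json"))
  for (g in seq_len(n)) {
    ids <- names(plasmid_host)[plasmid_host == acc[g]]
    recs <- c(genome_seqs[[g]], plasmid_seqs[ids])
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(unlist(recs)),
      file.path(outdir, "genomes", paste0(acc[g], ".fna")))
  }
  if (length(plasmid_seqs))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(unlist(plasmid_seqs)),
                                paths$plasmids)
  else
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(), paths$plasmids)
  all_features <- do.call(rbind, feature_rows)
  contig_lengths <- c(setNames(rep(L, n), chr_id),
                      unlist(lapply(seq_len(n), function(g) {
                        s <- genome_seqs[[g]][-1]
                        if (length(s)) vapply(s, nchar, numeric(1)) else NULL
                      })))
  write_features_gff3(all_features, paths$features, contig_lengths)
  write_tsv <- function(df, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA", eol = "\n")
  }
  write_tsv(do.call(rbind, element_rows), paths$elements)
  write_tsv(manifest_df, paths$manifest)
  write_tsv(membership_df, paths$membership)
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(unlist(protein_records)), paths$proteins)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(paths = c(paths, genomes_dir = file.path(outdir, "genomes")),
                 truth = truth, manifest = manifest_df))
}

#' Synthetic per-genome feature table for linkage power studies
#'
#' Independent standard-normal columns, optionally with one planted
#' monotone dependency: a pair (`dep_x`, `dep_y`) drawn from a bivariate
#' normal with the given correlation.
#'
#' @param n_genomes Number of rows.
#' @param n_null_vars Number of independent columns.
#' @param planted_rho Optional correlation for the planted pair.
#' @param seed Optional integer seed.
#' @return Data frame with a `genome` column plus numeric variables.
#' @export
synth_feature_table <- function(n_genomes = 18L, n_null_vars = 6L,
                                planted_rho = NULL, seed = NULL) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
  }
  out <- data.frame(genome = sprintf("g%02d", seq_len(n_genomes)))
  for (v in seq_len(n_null_vars))
    out[[sprintf("v%02d", v)]] <- rnorm(n_genomes)
  if (!is.null(planted_rho)) {
    stopifnot(abs(planted_rho) <= 1)
    x <- rnorm(n_genomes)
    out$dep_x <- x
    out$dep_y <- planted_rho * x +
      sqrt(1 - planted_rho^2) * rnorm(n_genomes)
  }
  out
}
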