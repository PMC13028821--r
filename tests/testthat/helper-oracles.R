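# Shared fixtures and independent oracles used across test files.

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(seq) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# distinct canonical k-mers of a sequence, as strings (brute force)
canonical_kmer_set <- function(seq, k) {
  n <- nchar(seq)
  kmers <- substring(seq, seq_len(n - k + 1), k:n)
  rc <- vapply(kmers, revcomp, character(1), USE.NAMES = FALSE)
  unique(pmin(kmers, rc))
}

# exact Mash-formula distance from brute-force canonical k-mer string sets
exact_mash_oracle <- function(a, b, k) {
  sa <- canonical_kmer_set(a, k)
  sb <- canonical_kmer_set(b, k)
  j <- length(intersect(sa, sb)) / length(union(sa, sb))
  if (j == 0) return(1)
  min(max(-(1 / k) * log(2 * j / (1 + j)), 0), 1)
}

# brute-force connected components of the graph with edges d <= threshold;
# returns a canonical partition (sorted list of sorted member vectors)
brute_components <- function(dm, threshold) {
  labels <- rownames(dm)
  n <- length(labels)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && dm[i, j] <= threshold && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  parts <- unname(lapply(split(labels, comp), sort))
  parts[order(vapply(parts, `[`, character(1), 1))]
}

# canonical partition of a plasmid_cluster_set for comparison
cluster_partition <- function(cs) {
  parts <- lapply(split(cs$clusters$plasmid, cs$clusters$cluster_id), sort)
  unname(parts[order(vapply(parts, `[`, character(1), 1))])
}

# brute-force BH step-up from the min-over-suffix definition:
# for ascending rank i, q_(i) = min over j >= i of m * p_(j) / j, capped at 1
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  qs <- vapply(seq_len(m), function(i)
    min(1, min(m * ps[i:m] / (i:m))), numeric(1))
  q <- numeric(m)
  q[ord] <- qs
  q
}

# type-7 quantile by explicit sort-and-interpolate
quantile7_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# small synthetic configuration that keeps generator tests fast
small_synth_config <- function(seed = 1L) {
  synth_config(
    n_genomes = 4L,
    chromosome_length_bp = 600000L,
    species = c("spA", "spA", "spB", "spC"),
    plasmid_families = list(
      list(mode = "backbone", n_members = 2L, length_bp = 20000L,
           mutation_rate = 0.005),
      list(mode = "mosaic", n_members = 2L, length_bp = 20000L,
           module_fraction = 0.3)),
    n_singleton_plasmids = 1L,
    n_plasmid_genomes = 4L,
    bcs = data.frame(anchor = c(TRUE, TRUE, TRUE, FALSE),
                     bcsA_copies = c(2L, 1L, 3L, 2L),
                     dispersed = c(FALSE, FALSE, TRUE, TRUE),
                     ggdef_in_window = c(TRUE, FALSE, TRUE, FALSE),
                     eal_in_window = c(TRUE, FALSE, FALSE, FALSE)),
    is_elements = list(count_range = c(5L, 10L),
                       length_range = c(700L, 1500L)),
    prophage = list(count_range = c(1L, 2L),
                    length_range = c(10080L, 20000L)),
    membership = list(n_core = 20L, n_accessory = 30L,
                      accessory_prob = 0.5, singleton_range = c(2L, 5L)),
    seed = seed)
}
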