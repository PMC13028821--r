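make_dm <- function(labels, fill = 1) {
  m <- matrix(fill, length(labels), length(labels),
              dimnames = list(labels, labels))
  diag(m) <- 0
  m
}

test_that("single-linkage components follow the threshold graph", {
  labels <- paste0("g", 1:3, "|p1")
  m <- make_dm(labels, 0.5)
  # all pairs above threshold: only singletons
  cs <- cluster_plasmids(m, 0.1)
  expect_true(all(cs$clusters$size == 1))
  # transitive linking through b
  m2 <- make_dm(c("x|a", "x|b", "x|c"), 0.30)
  m2["x|a", "x|b"] <- m2["x|b", "x|a"] <- 0.05
  m2["x|b", "x|c"] <- m2["x|c", "x|b"] <- 0.05
  cs2 <- cluster_plasmids(m2, 0.1)
  expect_equal(sort(cs2$clusters$plasmid[cs2$clusters$cluster_id == 1]),
               c("x|a", "x|b", "x|c"))
})

test_that("clustering equals brute-force components on random instances", {
  set.seed(404)
  for (rep in 1:200) {
    n <- sample(3:9, 1)
    labels <- paste0("g", seq_len(n), "|p")
    m <- make_dm(labels)
    vals <- runif(n * (n - 1) / 2)
    m[upper.tri(m)] <- vals
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    thr <- runif(1, 0.05, 0.6)
    cs <- cluster_plasmids(m, thr)
    expect_identical(cluster_partition(cs), brute_components(m, thr))
  }
})

test_that("clustering is order-invariant and monotone in the threshold", {
  set.seed(77)
  labels <- paste0("h", 1:8, "|p")
  m <- make_dm(labels)
  vals <- runif(28, 0, 0.4)
  m[upper.tri(m)] <- vals
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  perm <- sample(8)
  cs <- cluster_plasmids(m, 0.15)
  cs_perm <- cluster_plasmids(m[perm, perm], 0.15)
  expect_identical(cluster_partition(cs), cluster_partition(cs_perm))
  n_comp <- vapply(c(0.05, 0.1, 0.2, 0.3, 0.5),
                   function(t) max(cluster_plasmids(m, t)$clusters$cluster_id),
                   numeric(1))
  expect_true(all(diff(n_comp) <= 0))
})

test_that("planted families of 7 and 6 are the only multi-member clusters", {
  set.seed(1234)
  p <- sketch_params(k = 16, s = 1000, hash_seed = 11)
  anc <- random_dna_str(40000)
  backbone <- vapply(1:6, function(i) mutate_backbone(anc, 0.005)$seq,
                     character(1))
  module <- random_dna_str(12000)
  mosaic <- plant_mosaic_family(module, 7, 0.3)
  unrelated <- vapply(1:5, function(i) random_dna_str(20000), character(1))
  seqs <- c(mosaic, backbone, unrelated)
  ids <- c(sprintf("gm%02d|p1", 1:7), sprintf("gb%02d|p1", 1:6),
           sprintf("gu%02d|p1", 1:5))
  sks <- lapply(seq_along(seqs), function(i)
    sketch_sequence(seqs[i], p, ids[i]))
  cs <- cluster_plasmids(distance_matrix(sks), 0.10)
  sizes <- sort(unique(cs$clusters[, c("cluster_id", "size")])$size,
                decreasing = TRUE)
  expect_equal(sizes[1:2], c(7, 6))
  expect_true(all(sizes[-(1:2)] == 1))
  # cluster 1 is the larger family and contains exactly the mosaic members
  expect_setequal(cs$clusters$plasmid[cs$clusters$cluster_id == 1],
                  sprintf("gm%02d|p1", 1:7))
})

test_that("dispersion stats summarize within-cluster pairs", {
  labels <- c("a|p", "b|p", "c|p")
  m <- make_dm(labels)
  m["a|p", "b|p"] <- m["b|p", "a|p"] <- 0.01
  m["a|p", "c|p"] <- m["c|p", "a|p"] <- 0.02
  m["b|p", "c|p"] <- m["c|p", "b|p"] <- 0.06
  cs <- cluster_plasmids(m, 0.5)
  d <- dispersion_stats(cs, m)
  expect_equal(d$n_pairs, 3L)
  expect_equal(d$median_d, 0.02)
  expect_equal(d$min_d, 0.01)
  expect_equal(d$max_d, 0.06)
  # size-2 cluster has a single pair; size-7 has 21
  m2 <- make_dm(c("a|p", "b|p"), 0.004)
  cs2 <- cluster_plasmids(m2, 0.5)
  d2 <- dispersion_stats(cs2, m2)
  expect_equal(d2$n_pairs, 1L)
  expect_equal(c(d2$median_d, d2$min_d, d2$max_d), rep(0.004, 3))
  m7 <- make_dm(paste0(letters[1:7], "|p"), 0.01)
  expect_equal(dispersion_stats(cluster_plasmids(m7, 0.5), m7)$n_pairs, 21L)
})

test_that("conservation classes split at 0.02 and 0.05 as stated", {
  expect_equal(classify_conservation(0.001), "highly_conserved")
  expect_equal(classify_conservation(0.0199), "highly_conserved")
  expect_equal(classify_conservation(0.02), "moderately_conserved")
  expect_equal(classify_conservation(0.05), "moderately_conserved")
  expect_equal(classify_conservation(0.052), "mosaic_like")
  expect_error(classify_conservation(1.2), "\\[0, 1\\]")
})

test_that("presence matrix counts clusters per genome and spans species", {
  man <- structure(data.frame(
    accession = paste0("GCF_", 1:6), species = c("s1", "s2", "s3", "s4", "s5", "s6"),
    strain = paste0("st", 1:6), size_bp = rep(1e6, 6),
    source = NA_character_, excluded_clonal = FALSE),
    class = c("genome_manifest", "data.frame"))
  labels <- c(paste0("GCF_", 1:6, "|p1"), "GCF_1|p2")
  m <- make_dm(labels)
  # one cluster linking a plasmid in each of the six genomes
  for (i in 1:5) {
    a <- paste0("GCF_", i, "|p1"); b <- paste0("GCF_", i + 1, "|p1")
    m[a, b] <- m[b, a] <- 0.01
  }
  cs <- cluster_plasmids(m, 0.05)
  pm <- presence_matrix(cs, man)
  expect_equal(dim(pm$m), c(6L, 1L))
  expect_equal(unname(rowSums(pm$m)), rep(1, 6))
  expect_equal(pm$species_span$species_span, 6L)
  # all hosts same species: span 1
  man2 <- man; man2$species <- "sX"
  expect_equal(presence_matrix(cs, man2)$species_span$species_span, 1L)
  # no multi-member clusters: zero columns
  cs0 <- cluster_plasmids(make_dm(labels), 0.05)
  expect_equal(ncol(presence_matrix(cs0, man)$m), 0L)
  bad <- cs
  bad$clusters$host[1] <- "GCF_99"
  expect_error(presence_matrix(bad, man), "not in manifest")
})

test_that("CDS-product concordance uses normalized Jaccard with empty-set rule", {
  prods <- list(p1 = c("Replication protein A", "mobilization  protein."),
                p2 = c("replication protein a", "Mobilization protein"),
                p3 = c("unrelated thing", "other thing"),
                p4 = c("a", "b", "c"), p5 = c("b", "c", "d"),
                e1 = character(), e2 = character())
  expect_equal(product_concordance(c("p1", "p2"), prods)$median_jaccard, 1)
  expect_equal(product_concordance(c("p1", "p3"), prods)$median_jaccard, 0)
  expect_equal(product_concordance(c("p4", "p5"), prods)$median_jaccard, 0.5)
  expect_equal(product_concordance(c("e1", "e2"), prods)$median_jaccard, 1)
  expect_error(product_concordance(c("p1", "nope"), prods), "nope")
})

test_that("mobility table ingestion normalizes labels and buckets unknowns", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("plasmid_id\thost_accession\tpredicted_mobility\trelaxase_type",
               "p1\tGCF_1\tConjugative\tMOBQ",
               "p2\tGCF_1\tconjugative\tMOBF",
               "p3\tGCF_1\tCONJUGATIVE\tMOBP",
               "p4\tGCF_1\tnon-mobilizable\tNA",
               "p5\tGCF_2\tweird-label\tNA",
               "p6\tGCF_2\tmobilizable\tMOBQ"), tmp)
  expect_warning(tab <- ingest_mobility_table(tmp), "weird-label")
  g1 <- tab[tab$genome == "GCF_1", ]
  expect_equal(g1$conjugative, 3L)
  expect_equal(g1$non_mobilizable, 1L)
  g2 <- tab[tab$genome == "GCF_2", ]
  expect_equal(g2$unknown, 1L)
  expect_equal(g2$mobilizable, 1L)
  expect_equal(g1$relaxase_types, "MOBF,MOBP,MOBQ")
  # empty table
  writeLines("plasmid_id\thost_accession\tpredicted_mobility\trelaxase_type", tmp)
  empty <- ingest_mobility_table(tmp)
  expect_equal(nrow(empty), 0L)
})
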