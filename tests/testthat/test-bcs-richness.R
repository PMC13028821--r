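hit_row <- function(genome, target, contig, start, end) {
  data.frame(genome = genome, target = target, contig = contig,
             start = as.integer(start), end = as.integer(end), strand = "+",
             stringsAsFactors = FALSE)
}

feature_row <- function(contig, start, end, gene = NA, product = NA,
                        domain = NA, genome = "G1", type = "CDS") {
  data.frame(contig = contig, type = type, start = start, end = end,
             strand = "+", genome = genome, gene = gene, product = product,
             domain = domain, stringsAsFactors = FALSE)
}

test_that("target finding matches gene names, product keywords and domains", {
  feats <- rbind(
    feature_row("c1", 100, 2300, gene = "bcsA"),
    feature_row("c1", 3000, 4100, product = "endo-1,4-beta-glucanase"),
    feature_row("c1", 5000, 6500, product = "bifunctional protein",
                domain = "GGDEF,EAL"),
    feature_row("c1", 9000, 9500, product = "hypothetical protein"),
    feature_row("c1", 9600, 9900, gene = "bcsA", type = "gene"))  # not a CDS
  hits <- find_targets(feats)
  expect_setequal(hits$target, c("bcsA", "bcsZ", "GGDEF", "EAL"))
  # dual-domain CDS yields one hit under each domain target
  dual <- hits[hits$start == 5000, ]
  expect_setequal(dual$target, c("GGDEF", "EAL"))
  expect_equal(nrow(find_targets(feats[0, ])), 0L)
})

test_that("anchor selection requires bcsA/bcsZ co-localization", {
  h <- rbind(hit_row("G1", "bcsA", "c1", 100, 2300),
             hit_row("G1", "bcsZ", "c1", 3000, 4100),
             hit_row("G1", "bcsQ", "c1", 5000, 5700))
  a <- select_anchor(h)
  expect_true(a$qualifies)
  expect_equal(a$anchor_contig, "c1")
  expect_equal(c(a$span_start, a$span_end), c(100L, 5700L))
  expect_true(a$bcsQ_on_anchor)

  h2 <- rbind(hit_row("G1", "bcsA", "c1", 100, 2300),
              hit_row("G1", "bcsZ", "c2", 3000, 4100))
  a2 <- select_anchor(h2)
  expect_false(a2$qualifies)
  expect_true(is.na(a2$anchor_contig))
  expect_true(is.na(a2$span_start))
})

test_that("anchor tie-breaks: target count, then length, then contig ID", {
  both <- function(contig, extra = NULL) {
    rows <- rbind(hit_row("G1", "bcsA", contig, 100, 2300),
                  hit_row("G1", "bcsZ", contig, 3000, 4100))
    if (!is.null(extra)) rows <- rbind(rows, extra)
    rows
  }
  # c2 carries one more distinct target
  h <- rbind(both("c1"), both("c2", hit_row("G1", "bcsD", "c2", 5000, 5400)))
  expect_equal(select_anchor(h)$anchor_contig, "c2")
  # equal targets: longer contig wins
  h2 <- rbind(both("c1"), both("c2"))
  expect_equal(select_anchor(h2, c(c1 = 10000, c2 = 50000))$anchor_contig, "c2")
  # equal targets, no lengths: lexicographic smallest
  expect_equal(select_anchor(h2)$anchor_contig, "c1")
  # order invariance
  set.seed(2)
  h_perm <- h[sample(nrow(h)), ]
  expect_equal(select_anchor(h_perm), select_anchor(h))
})

test_that("bcsA copy counting flags dispersed architectures", {
  h <- rbind(hit_row("G1", "bcsA", "c1", 100, 2300),
             hit_row("G1", "bcsA", "c1", 8000, 10200),
             hit_row("G1", "bcsA", "c2", 100, 2300),
             hit_row("G1", "bcsZ", "c1", 3000, 4100))
  a <- select_anchor(h)
  expect_equal(a$bcsA_copy_count, 3L)
  expect_true(a$bcsA_dispersed)
  expect_true(a$qualifies)
  expect_error(select_anchor(rbind(h, hit_row("G2", "bcsA", "c1", 1, 30))),
               "single genome")
})

test_that("window signals use closed-interval intersection on the anchor contig", {
  anchor <- select_anchor(rbind(hit_row("G1", "bcsA", "c1", 100000, 102300),
                                hit_row("G1", "bcsZ", "c1", 103000, 104100)))
  # span is [100000, 104100]; window is [50000, 154100]
  base <- rbind(hit_row("G1", "GGDEF", "c1", 114000, 115500))    # 10 kb away
  w <- window_signals(base, anchor)
  expect_true(w$ggdef_present)
  expect_false(w$eal_present)
  expect_equal(w$ggdef_count, 1L)
  # 60 kb away: outside
  far <- rbind(hit_row("G1", "GGDEF", "c1", 164200, 165700))
  w2 <- window_signals(far, anchor)
  expect_false(w2$ggdef_present)
  expect_false(w2$eal_present)
  # straddling the right edge by exactly 1 bp: counted
  edge <- rbind(hit_row("G1", "EAL", "c1", 154100, 155600))
  expect_true(window_signals(edge, anchor)$eal_present)
  beyond <- rbind(hit_row("G1", "EAL", "c1", 154101, 155600))
  expect_false(window_signals(beyond, anchor)$eal_present)
  # other contigs never count
  other <- rbind(hit_row("G1", "GGDEF", "c2", 114000, 115500))
  expect_false(window_signals(other, anchor)$ggdef_present)
  # monotone in window size
  counts <- vapply(c(10000, 50000, 70000), function(wb)
    window_signals(rbind(base, far), anchor, window_bp = wb)$ggdef_count,
    integer(1))
  expect_true(all(diff(counts) >= 0))
  non_qual <- select_anchor(rbind(hit_row("G1", "bcsA", "c1", 1, 10)))
  expect_error(window_signals(base, non_qual), "non-qualifying")
})

test_that("medoid similarity matches a brute-force medoid oracle", {
  set.seed(9)
  aa <- function(n) paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                 n, replace = TRUE), collapse = "")
  seqs <- list(gA = aa(120), gB = aa(120), gC = aa(120))
  # brute-force: pairwise 5-mer Jaccard distances, argmin of summed distance
  kset <- function(s) unique(substring(s, 1:(nchar(s) - 4), 5:nchar(s)))
  dmat <- outer(names(seqs), names(seqs), Vectorize(function(i, j) {
    a <- kset(seqs[[i]]); b <- kset(seqs[[j]])
    1 - length(intersect(a, b)) / length(union(a, b))
  }))
  dimnames(dmat) <- list(names(seqs), names(seqs))
  medoid <- names(seqs)[which.min(rowSums(dmat))]
  sim <- medoid_similarity(list(tgt = seqs))
  expect_equal(sim[medoid, "tgt"], 1)
  for (g in names(seqs))
    expect_equal(sim[g, "tgt"], 1 - dmat[g, medoid])
  # identical sequences: all 1; absent genome: 0
  sim2 <- medoid_similarity(list(tgt = list(gA = "MKLVV", gB = "MKLVV")),
                            genomes = c("gA", "gB", "gC"))
  expect_equal(unname(sim2[, "tgt"]), c(1, 1, 0))
})

make_anchor_df <- function(n = 4) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    q <- i < n
    h <- rbind(hit_row(paste0("g", i), "bcsA", "c1", 1000 * i, 1000 * i + 2000),
               hit_row(paste0("g", i), "bcsZ", if (q) "c1" else "c2", 5000, 6000))
    select_anchor(h)
  }))
}

test_that("feature matrix is z-scored with constant columns dropped", {
  anchors <- make_anchor_df()
  windows <- data.frame(genome = paste0("g", 1:3),
                        ggdef_present = c(TRUE, TRUE, FALSE),
                        eal_present = c(FALSE, TRUE, FALSE),
                        ggdef_count = c(1, 2, 0), eal_count = c(0, 1, 0))
  m <- build_feature_matrix(anchors, windows)
  expect_s3_class(m, "richness_matrix")
  expect_equal(m$non_qualifying, "g4")
  # scaled columns have mean 0 and sd 1
  expect_equal(unname(colMeans(m$x)), rep(0, ncol(m$x)), tolerance = 1e-12)
  expect_equal(unname(apply(m$x, 2, sd)), rep(1, ncol(m$x)))
  # bcsA_copy_count is constant here, so it must be in the dropped record
  expect_true("bcsA_copy_count" %in% m$dropped)
  expect_false("bcsA_copy_count" %in% colnames(m$x))
  # non-qualifying genome got zero-imputed window features
  expect_equal(unname(m$raw["g4", c("ggdef_count", "eal_count")]), c(0, 0))
  expect_error(build_feature_matrix(anchors[1, , drop = FALSE], windows),
               "at least 2")
})

test_that("PCA matches an independent eigendecomposition and fixes signs", {
  set.seed(123)
  raw <- matrix(rnorm(20), 5, 4,
                dimnames = list(paste0("g", 1:5), paste0("f", 1:4)))
  m <- structure(list(x = scale(raw), raw = raw, dropped = character()),
                 class = "richness_matrix")
  pr <- pca_project(m, n_components = 4)
  ev <- eigen(stats::cov(m$x))
  # scores from the oracle: X %*% eigenvectors
  oracle_scores <- m$x %*% ev$vectors
  for (j in 1:4) {
    expect_equal(abs(unname(pr$scores[, j])), abs(unname(oracle_scores[, j])),
                 tolerance = 1e-8)
  }
  expect_equal(unname(pr$variance_explained),
               ev$values / sum(ev$values), tolerance = 1e-8)
  expect_true(all(diff(pr$variance_explained) <= 1e-12))
  # sign convention: the largest-magnitude loading of each PC is positive
  for (j in 1:4) expect_gt(pr$loadings[which.max(abs(pr$loadings[, j])), j], 0)
  # row order invariance (up to the fixed sign rule)
  perm <- c(3, 1, 5, 2, 4)
  m2 <- structure(list(x = m$x[perm, ], raw = raw[perm, ],
                       dropped = character()), class = "richness_matrix")
  pr2 <- pca_project(m2, n_components = 2)
  expect_equal(pr2$scores[rownames(pr$scores), ], pr$scores[, 1:2],
               tolerance = 1e-8)
  # rank-1 case: two distinct rows
  m3 <- structure(list(x = scale(matrix(c(0, 1, 0, 2), 2, 2,
                       dimnames = list(c("a", "b"), c("u", "v"))))),
                  class = "richness_matrix")
  expect_equal(pca_project(m3, 1)$variance_explained, 1)
  # degenerate: all rows equal leaves no variance
  anchors <- make_anchor_df(3)[c(1, 1, 1), ]
  anchors$genome <- paste0("g", 1:3)
  md <- build_feature_matrix(anchors,
                             data.frame(genome = character(),
                                        ggdef_present = logical(),
                                        eal_present = logical(),
                                        ggdef_count = integer(),
                                        eal_count = integer()))
  expect_error(pca_project(md), "no variance")
})
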