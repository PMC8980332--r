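make_qc_matrix <- function() {
  # 1000 regular genes + 10 mito genes; cells crafted to sit on and around
  # the QC boundaries
  n_genes <- 1000L
  genes <- c(paste0("g", seq_len(n_genes)), paste0("mt-", 1:10))
  cells <- c("ok", "genes_900", "genes_901", "mito_20", "mito_25")
  m <- matrix(0L, length(genes), length(cells),
              dimnames = list(genes, cells))
  m[1:950, "ok"] <- 1L                       # 950 genes, no mito
  m[1:900, "genes_900"] <- 1L                # exactly 900 genes
  m[1:901, "genes_901"] <- 1L                # just above the bound
  m[1:950, "mito_20"] <- 1L                  # mito = 238/1188... adjust below
  m[1:950, "mito_25"] <- 1L
  # mito_20: mito reads exactly 20% of total -> 950 regular + x mito reads
  # with x / (950 + x) = 0.20 -> x = 237.5; use 240 regular + 60 mito
  m[, "mito_20"] <- 0L
  m[1:950, "mito_20"] <- 1L
  m["mt-1", "mito_20"] <- 237L               # 237 + 0.5 short; fix to 20%
  m[951:1000, "mito_20"] <- 0L
  # make total regular = 952 so that mito 238 is exactly 20% of 1190
  m[1:950, "mito_20"] <- 1L
  m["g1", "mito_20"] <- 3L
  m["mt-1", "mito_20"] <- 238L
  # mito_25: 25% mito
  m[1:900, "mito_25"] <- 1L
  m["mt-1", "mito_25"] <- 300L
  clusters <- setNames(rep("A", length(cells)), cells)
  list(counts = m, clusters = clusters)
}

test_that("QC removes cells at exactly 900 genes or exactly 20% mito", {
  x <- make_qc_matrix()
  # verify the constructed boundary cell really is at exactly 20%
  tot <- sum(x$counts[, "mito_20"])
  expect_equal(sum(x$counts[grepl("^mt-", rownames(x$counts)), "mito_20"]) /
                 tot, 0.20)
  qc <- qc_filter_cells(x$counts, x$clusters)
  kept <- colnames(qc$counts)
  expect_true("ok" %in% kept)
  expect_true("genes_901" %in% kept)
  expect_false("genes_900" %in% kept)   # "more than 900" is strict
  expect_false("mito_20" %in% kept)     # "less than 20%" is strict
  expect_false("mito_25" %in% kept)
  expect_equal(qc$n_removed, 3L)
  # removing every cell is an explicit error
  expect_error(qc_filter_cells(x$counts, x$clusters, min_genes = 2000L),
               "all .* cells removed")
})

test_that("normalisation matches the closed form and is depth-invariant", {
  m <- matrix(c(0L, 10L, 90L, 0L, 50L, 50L), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("c1", "c2")))
  nm <- normalize_counts(m)
  expect_equal(nm["a", "c1"], 0)
  expect_equal(nm["b", "c1"], log(1 + 10 / 100 * 1e4))
  # a count equal to the whole cell total maps to ln(1 + 10000)
  solo <- matrix(c(7L, 0L), nrow = 2, dimnames = list(c("a", "b"), "c1"))
  expect_equal(normalize_counts(solo)["a", "c1"], log(1 + 1e4))
  expect_equal(normalize_counts(solo)["a", "c1"], 9.2104, tolerance = 1e-4)
  # doubling all counts in a cell changes nothing
  expect_equal(normalize_counts(m * 2L), nm)
  zero <- matrix(c(1L, 0L), nrow = 1, dimnames = list("a", c("c1", "c2")))
  expect_warning(nz <- normalize_counts(zero), "zero-total")
  expect_equal(ncol(nz), 1L)
})

test_that("rank-sum p-values are exact: worked example and enumeration", {
  expect_equal(rank_sum_test(1:3, 4:6), 0.1)
  expect_equal(rank_sum_test(c(2, 2, 2), c(2, 2)), 1)
  set.seed(41)
  for (i in 1:20) {
    na <- sample(1:5, 1)
    nb <- sample(1:5, 1)
    withties <- i %% 2 == 0
    pool <- if (withties) sample(1:4, na + nb, replace = TRUE) + 0
            else sample(1:100, na + nb) + runif(na + nb, 0, 0.1)
    a <- pool[seq_len(na)]
    b <- pool[-seq_len(na)]
    expect_equal(rank_sum_test(a, b), oracle_ranksum(a, b),
                 tolerance = 1e-12,
                 info = sprintf("case %d: a=%s b=%s", i,
                                paste(a, collapse = ","),
                                paste(b, collapse = ",")))
  }
})

test_that("the large-sample approximation tracks the exact p at n = 20 + 20", {
  set.seed(42)
  for (i in 1:10) {
    a <- rnorm(20, sd = 2) + runif(20, 0, 1e-6)
    b <- rnorm(20, mean = sample(c(0.2, 0.4, 0.6), 1), sd = 2) +
      runif(20, 0, 1e-6)
    p_exact <- rank_sum_test(a, b, exact_max_n = 50L)
    p_approx <- stats::wilcox.test(a, b, exact = FALSE,
                                   correct = TRUE)$p.value
    expect_lt(abs(p_approx - p_exact) / p_exact, 0.10)
  }
})

test_that("planted 16-fold markers are recovered; weak and sparse genes fail", {
  planted <- paste0("gene", 1:20)
  sim <- make_expression(
    n_genes = 400L, cells_per_cluster = c(MG = 100L, rest = 300L),
    nb_mean = 2, nb_dispersion = 0.5,
    markers = data.frame(gene = planted, cluster = "MG", fold_change = 16),
    seed = 43)
  mk <- find_markers(sim$counts, sim$clusters, "MG")
  hit <- mk$gene_id[mk$passes]
  recall <- mean(planted %in% hit)
  expect_gte(recall, 0.95)
  # false-pass rate among the 380 unplanted genes stays under 5%
  false_pass <- setdiff(hit, planted)
  expect_lte(length(false_pass) / 380, 0.05)
  # a 2.5-fold gene has log2fc ~ 1.3 and misses the fold-change filter
  sim2 <- make_expression(
    n_genes = 50L, cells_per_cluster = c(MG = 100L, rest = 300L),
    markers = data.frame(gene = "gene1", cluster = "MG", fold_change = 2.5),
    seed = 44)
  mk2 <- find_markers(sim2$counts, sim2$clusters, "MG")
  g1 <- mk2[mk2$gene_id == "gene1", ]
  expect_lt(g1$log2fc, 2)
  expect_false(g1$passes)
})

test_that("genes below the expression-fraction prefilter are never tested", {
  set.seed(45)
  counts <- matrix(0L, 3, 40, dimnames = list(
    c("sparse", "dense", "mid"), paste0("c", 1:40)))
  counts["sparse", sample(40, 4)] <- 5L   # 10% of both groups
  counts["dense", ] <- rpois(40, 5)
  counts["mid", 1:20] <- 3L
  clusters <- setNames(rep(c("T", "R"), each = 20), colnames(counts))
  mk <- find_markers(counts, clusters, "T")
  expect_false("sparse" %in% mk$gene_id)
  expect_true("dense" %in% mk$gene_id)
})

test_that("label permutation yields the nominal false-positive rate", {
  set.seed(46)
  sim <- make_expression(n_genes = 800L,
                         cells_per_cluster = c(A = 60L, B = 60L),
                         nb_mean = 3, nb_dispersion = 0.4, seed = 46)
  perm <- setNames(sample(sim$clusters), names(sim$clusters))
  mk <- find_markers(sim$counts, perm, "A", min_pct = 0)
  frac <- mean(mk$p_value < 0.05)
  # binomial 99% bounds around 0.05 for the number of genes tested
  n <- nrow(mk)
  bound <- 2.576 * sqrt(0.05 * 0.95 / n)
  expect_lt(abs(frac - 0.05), bound + 0.001)
})

test_that("the TF panel is the passing markers intersected with the TF list", {
  mk <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   target_cluster = "MG", log2fc = c(4, 3, 5, 4),
                   p_value = c(1e-5, 1e-4, 1e-3, 1e-2),
                   p_adj = NA, pct_in = 1, pct_out = 0.1, is_tf = NA,
                   passes = c(TRUE, TRUE, FALSE, TRUE))
  panel <- select_tfs(mk, c("g2", "g4", "g4", "g3"))
  expect_equal(panel$gene_id, c("g2", "g4"))  # marker order kept, deduped
  expect_warning(empty <- select_tfs(mk, "zzz"), "empty TF panel")
  expect_equal(nrow(empty), 0L)
})
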