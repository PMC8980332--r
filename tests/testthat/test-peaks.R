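test_that("bedGraph and equivalent fixedStep wiggle load to the same track", {
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t100\t105\t40", "chr1\t110\t112\t7.5"), bg)
  tr <- read_coverage(bg)[["chr1"]]
  expect_equal(tr$values[101:105], rep(40, 5))
  expect_equal(tr$values[106:110], rep(0, 5))   # gap reads as zero
  expect_equal(tr$values[111:112], rep(7.5, 2))

  wig <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=chr1 start=101 step=1 span=1",
               rep("40", 5),
               "fixedStep chrom=chr1 start=111 step=1 span=1",
               rep("7.5", 2)), wig)
  tw <- read_coverage(wig)[["chr1"]]
  n <- min(length(tr$values), length(tw$values))
  expect_equal(tw$values[1:n], tr$values[1:n])

  empty <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(character(0), empty)
  expect_length(read_coverage(empty), 0L)

  bad <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t100\t110\t4", "chr1\t105\t115\t6"), bad)
  expect_error(read_coverage(bad), "overlap")
  neg <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chr1\t0\t5\t-1", neg)
  expect_error(read_coverage(neg), "negative")
})

test_that("flanking regions span neighbour-to-neighbour including the gene body", {
  genes <- gene_models(gene_id = c("gA", "gB", "gC"), chrom = "chr1",
                       strand = "+", tx_start = c(0, 500, 1000),
                       tx_end = c(100, 700, 1200))
  expect_equal(unname(flanking_region("gB", genes)), c(100, 1000))
  expect_equal(unname(flanking_region("gA", genes))[1], 0)
  expect_equal(unname(flanking_region("gC", genes, chrom_len = 5000)),
               c(700, 5000))
  expect_error(flanking_region("nope", genes), "not found")
  # overlapping neighbour clips that side's flank to zero length
  ov <- gene_models(gene_id = c("gA", "gB"), chrom = "chr1", strand = "+",
                    tx_start = c(0, 500), tx_end = c(600, 700))
  expect_warning(r <- flanking_region("gB", ov), "clip")
  expect_equal(unname(r)[1], 500)
})

test_that("tip and 20%-of-tip boundaries are recovered exactly", {
  # triangular: s[60 +/- k] = 40 - 4k; 20% of 40 = 8 -> positions 52..68
  tr <- triangle_track(120, 60, 40, 4)
  pk <- call_peaks(tr)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$start, 52)
  expect_equal(pk$end, 69)
  expect_equal(pk$tip_pos, 60)
  expect_equal(pk$tip_value, 40)
  # same shape scaled below the tip threshold yields nothing
  expect_equal(nrow(call_peaks(triangle_track(120, 60, 15, 1.5))), 0L)
  # a flat plateau keeps its extent; tip is the leftmost maximum
  v <- numeric(30); v[11:20] <- 30
  pp <- call_peaks(coverage_track(v))
  expect_equal(pp$start, 10)
  expect_equal(pp$end, 20)
  expect_equal(pp$tip_pos, 10)
  expect_error(call_peaks(tr, boundary_frac = 1.2), "boundary_frac")
})

test_that("raising tip_min or boundary_frac never adds or widens peaks", {
  set.seed(31)
  cov <- make_coverage(2000, data.frame(
    tip_pos = c(200, 700, 1200, 1700), tip_value = c(25, 40, 21, 60),
    half_width = c(12, 20, 8, 15),
    shape = c("triangular", "gaussian", "triangular", "plateau")))
  n_lo <- nrow(call_peaks(cov$track, tip_min = 20))
  n_hi <- nrow(call_peaks(cov$track, tip_min = 30))
  expect_lte(n_hi, n_lo)
  p20 <- call_peaks(cov$track, boundary_frac = 0.2)
  p50 <- call_peaks(cov$track, boundary_frac = 0.5)
  for (i in seq_len(nrow(p50))) {
    j <- which(p20$tip_pos == p50$tip_pos[i])
    expect_true(length(j) == 1 && p50$start[i] >= p20$start[j] &&
                  p50$end[i] <= p20$end[j])
  }
})

test_that("noise-free synthetic peaks are recovered exactly across many loci", {
  set.seed(32)
  shapes <- c("triangular", "gaussian", "plateau")
  hits <- 0L
  total <- 0L
  for (rep in 1:50) {
    k <- sample(1:3, 1)
    specs <- data.frame(
      tip_pos = sort(sample(seq(150, 1850, by = 50), k)) +
        sample(0:20, k, replace = TRUE),
      tip_value = sample(21:80, k, replace = TRUE),
      half_width = sample(5:15, k, replace = TRUE),
      shape = sample(shapes, k, replace = TRUE))
    # keep truth peaks far apart so shapes cannot interact
    specs <- specs[c(TRUE, diff(specs$tip_pos) > 250), , drop = FALSE]
    cov <- make_coverage(2000, specs, noise_sd = 0)
    got <- call_peaks(cov$track)
    truth <- cov$truth[!cov$truth$sub_threshold, , drop = FALSE]
    expect_equal(nrow(got), nrow(truth))
    for (i in seq_len(nrow(truth))) {
      total <- total + 1L
      inter <- min(got$end[i], truth$end[i]) - max(got$start[i], truth$start[i])
      uni <- max(got$end[i], truth$end[i]) - min(got$start[i], truth$start[i])
      if (inter / uni >= 0.9) hits <- hits + 1L
      expect_equal(got$start[i], truth$start[i])
      expect_equal(got$end[i], truth$end[i])
      expect_equal(got$tip_value[i], truth$tip_value[i])
    }
  }
  expect_equal(hits / total, 1.0)
})

test_that("exonic peaks are excluded by >= 1 bp overlap, idempotently", {
  genes <- gene_models(gene_id = "g", chrom = "chr1", strand = "+",
                       tx_start = 0, tx_end = 200,
                       exons = list(cbind(68, 120)))
  pk <- data.frame(chrom = "chr1", start = 52, end = 69, tip_pos = 60,
                   tip_value = 40)
  expect_equal(nrow(exclude_exonic(pk, genes)), 0L)      # 1-bp overlap
  genes2 <- gene_models(gene_id = "g", chrom = "chr1", strand = "+",
                        tx_start = 0, tx_end = 200,
                        exons = list(cbind(69, 120)))
  expect_equal(nrow(exclude_exonic(pk, genes2)), 1L)     # touching, kept
  # intron-contained peak is kept
  genes3 <- gene_models(gene_id = "g", chrom = "chr1", strand = "+",
                        tx_start = 0, tx_end = 200,
                        exons = list(rbind(c(0, 10), c(150, 200))))
  expect_equal(nrow(exclude_exonic(pk, genes3)), 1L)
  once <- exclude_exonic(pk, genes3)
  expect_identical(exclude_exonic(once, genes3), once)
})

test_that("nomination composes region, peak, exon and sequence steps", {
  set.seed(33)
  # three planted peaks: tips 40 and 25 pass, 15 fails the tip threshold
  cov <- make_coverage(3000, data.frame(
    tip_pos = c(600, 1500, 2400), tip_value = c(40, 25, 15),
    half_width = c(10, 10, 10), shape = "triangular"))
  genes <- gene_models(gene_id = c("up", "goi", "down"), chrom = "chr1",
                       strand = "+", tx_start = c(0, 1200, 2900),
                       tx_end = c(100, 1800, 3000),
                       exons = list(cbind(0, 100), cbind(1200, 1250),
                                    cbind(2900, 3000)))
  genome <- c(chr1 = random_dna(3000, 0.4))
  cands <- nominate_crms("goi", cov$track, genes, genome)
  expect_equal(nrow(cands), 2L)
  expect_equal(cands$crm_id, c("goi_1", "goi_2"))
  expect_equal(nchar(cands$sequence), cands$end - cands$start)
  expect_equal(cands$sequence[1],
               substr(genome[["chr1"]], cands$start[1] + 1, cands$end[1]))
  # planting the middle peak inside an exon removes it
  genes_ex <- gene_models(gene_id = c("up", "goi", "down"), chrom = "chr1",
                          strand = "+", tx_start = c(0, 1200, 2900),
                          tx_end = c(100, 1800, 3000),
                          exons = list(cbind(0, 100), cbind(1480, 1520),
                                       cbind(2900, 3000)))
  expect_equal(nrow(nominate_crms("goi", cov$track, genes_ex, NULL)), 1L)
  # no signal above threshold -> empty nomination
  flat <- coverage_track(rep(5, 3000))
  expect_equal(nrow(nominate_crms("goi", flat, genes, NULL)), 0L)
})

test_that("BED12 gene models round-trip through write and read", {
  genes <- gene_models(gene_id = c("gA", "gB"), chrom = "chr1",
                       strand = c("+", "-"), tx_start = c(100, 1000),
                       tx_end = c(600, 1500),
                       exons = list(rbind(c(100, 200), c(450, 600)),
                                    cbind(1000, 1500)))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed12(genes, f)
  back <- read_gene_models(f)
  expect_equal(back$gene_id, genes$gene_id)
  expect_equal(back$tx_start, as.integer(genes$tx_start))
  expect_equal(back$tx_end, as.integer(genes$tx_end))
  expect_equal(unname(back$exons[[1]][, 1]), c(100L, 450L))
  expect_equal(unname(back$exons[[1]][, 2]), c(200L, 600L))
})
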