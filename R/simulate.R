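#' Build a motif profile from a consensus sequence
#'
#' Synthetic PFM generator: each column holds `sharpness * N` counts on the
#' consensus base and `(1 - sharpness) * N / 3` on each other base
#' (N = 100). Sharpness 1 gives a consensus-only matrix; lower sharpness
#' lowers the information content and admits near-consensus hits.
#'
#' @param consensus DNA string over A, C, G, T.
#' @param sharpness Fraction of counts on the consensus base, in (0, 1].
#' @param motif_id,tf_name Identifiers (default derived from the
#'   consensus).
#' @param pseudocount,background Passed to the PWM construction.
#' @return A `motif_profile`.
#' @export
make_profile <- function(consensus, sharpness = 1.0, motif_id = NULL,
                         tf_name = NULL, pseudocount = 1.0,
                         background = rep(0.25, 4)) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (!all(bases %in% DNA_BASES)) {
    stop("consensus must be over A, C, G, T")
  }
  if (sharpness <= 0 || sharpness > 1) stop("sharpness must be in (0, 1]")
  if (is.null(motif_id)) motif_id <- paste0("SYN_", toupper(consensus))
  if (is.null(tf_name)) tf_name <- motif_id
  N <- 100
  pfm <- matrix((1 - sharpness) * N / 3, nrow = 4L, ncol = length(bases),
                dimnames = list(DNA_BASES, NULL))
  pfm[cbind(match(bases, DNA_BASES), seq_along(bases))] <- sharpness * N
  new_motif_profile(motif_id, tf_name, pfm, pseudocount, background)
}

#' Random DNA background at a given GC content
#'
#' @param n Length in bp.
#' @param gc GC fraction in (0, 1).
#' @return DNA string.
#' @export
random_dna <- function(n, gc = 0.5) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Plant motif sites into a random background sequence
#'
#' Draws a background at the requested GC content and overwrites it with
#' the given site sequences (reverse-complemented for minus-strand sites).
#' The returned truth table lists the exact intended hit coordinates in the
#' 0-based half-open, forward-anchored convention of the scanner.
#'
#' @param length_bp Sequence length.
#' @param sites Data.frame with columns `motif_id`, `site` (the
#'   forward-strand motif sequence as it should be read on its strand),
#'   `position` (0-based start) and `strand`; may have zero rows.
#' @param gc Background GC fraction (default 0.4, roughly mammalian
#'   non-coding).
#' @param seed Optional seed for the background draw.
#' @return List with `sequence` and `truth` (the sites with an added
#'   `end` column).
#' @export
plant_sequence <- function(length_bp, sites = NULL, gc = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seq <- random_dna(length_bp, gc)
  if (is.null(sites)) {
    sites <- data.frame(motif_id = character(0), site = character(0),
                        position = integer(0), strand = character(0),
                        stringsAsFactors = FALSE)
  }
  if (nrow(sites)) {
    for (i in seq_len(nrow(sites))) {
      s <- toupper(sites$site[i])
      if (sites$strand[i] == "-") s <- revcomp(s)
      p <- sites$position[i]
      if (p < 0 || p + nchar(s) > length_bp) {
        stop("site ", i, " falls outside the sequence")
      }
      substr(seq, p + 1L, p + nchar(s)) <- s
    }
    sites$end <- sites$position + nchar(sites$site)
  } else {
    sites$end <- integer(0)
  }
  list(sequence = seq, truth = sites)
}

#' Simulate a coverage track with known peak ground truth
#'
#' Sums analytic peak shapes onto a zero baseline, optionally adding
#' seeded Gaussian noise. The truth table carries the analytic
#' tip-threshold / 20%-of-tip boundaries, so noise-free recovery by
#' [call_peaks()] must be exact.
#'
#' @param length_bp Track length.
#' @param peak_specs Data.frame with `tip_pos` (0-based), `tip_value`,
#'   `half_width` (bp from tip to zero for triangular; s.d. in bp for
#'   gaussian; half the plateau width for plateau) and
#'   `shape` in `{"triangular", "gaussian", "plateau"}`.
#' @param noise_sd Gaussian noise s.d. (default 0); negative values are
#'   clipped at 0.
#' @param tip_min,boundary_frac Thresholds used to annotate the truth
#'   (defaults 20 and 0.2).
#' @param chrom Chromosome name.
#' @param seed Optional seed for the noise draw.
#' @return List with `track` (a `coverage_track`) and `truth` (data.frame
#'   with analytic `start`, `end`, `tip_pos`, `tip_value` and a
#'   `sub_threshold` flag).
#' @export
make_coverage <- function(length_bp, peak_specs, noise_sd = 0,
                          tip_min = 20, boundary_frac = 0.2,
                          chrom = "chr1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- numeric(length_bp)
  truth <- vector("list", nrow(peak_specs))
  pos <- seq_len(length_bp) - 1L
  for (i in seq_len(nrow(peak_specs))) {
    tp <- peak_specs$tip_pos[i]
    tv <- peak_specs$tip_value[i]
    hw <- peak_specs$half_width[i]
    shape <- peak_specs$shape[i]
    d <- abs(pos - tp)
    contrib <- switch(shape,
      triangular = pmax(0, tv * (1 - d / hw)),
      gaussian = {
        g <- tv * exp(-d^2 / (2 * hw^2))
        g[g < 1e-6] <- 0   # truncate far tails so peaks stay local
        g
      },
      plateau = ifelse(d <= hw, tv, 0),
      stop("unknown shape '", shape, "'"))
    v <- v + contrib
    # analytic boundary: outermost offset k with value >= boundary_frac * tip
    kmax <- switch(shape,
      triangular = floor(hw * (1 - boundary_frac) + 1e-9),
      gaussian = floor(hw * sqrt(-2 * log(boundary_frac)) + 1e-9),
      plateau = hw)
    truth[[i]] <- data.frame(
      start = max(0, tp - kmax), end = min(length_bp, tp + kmax + 1),
      tip_pos = if (shape == "plateau") max(0, tp - hw) else tp,
      tip_value = tv, sub_threshold = tv < tip_min,
      stringsAsFactors = FALSE)
  }
  if (noise_sd > 0) v <- pmax(0, v + rnorm(length_bp, 0, noise_sd))
  list(track = coverage_track(v, chrom = chrom),
       truth = do.call(rbind, truth))
}

#' Simulate a clustered single-cell count matrix with planted markers
#'
#' Negative-binomial counts (mean `nb_mean`, dispersion `nb_dispersion`;
#' variance `mu + dispersion * mu^2`) for every gene in every cell, with
#' planted markers whose mean is multiplied by `fold_change` in their
#' cluster. Mitochondrial genes and low-complexity cells can be injected to
#' exercise the QC filter.
#'
#' @param n_genes Number of genes (named `gene1..geneN`; planted markers
#'   keep these names).
#' @param cells_per_cluster Named integer vector, e.g.
#'   `c(MG = 100, rest = 300)`.
#' @param nb_mean Baseline NB mean per gene per cell (default 2).
#' @param nb_dispersion NB dispersion (default 0.5; `size = 1/dispersion`).
#' @param markers Data.frame with `gene`, `cluster`, `fold_change`, or
#'   `NULL`.
#' @param n_mito Number of mitochondrial genes appended (named `mt-1...`,
#'   default 0).
#' @param mito_boost Mean multiplier for mito genes in `mito_cells`
#'   (default 1).
#' @param mito_cells Indices of cells whose mito load is boosted.
#' @param seed Optional seed.
#' @return List with `counts` (genes x cells), `clusters` (named vector)
#'   and `truth` (the planted marker table).
#' @export
make_expression <- function(n_genes, cells_per_cluster, nb_mean = 2,
                            nb_dispersion = 0.5, markers = NULL,
                            n_mito = 0L, mito_boost = 1, mito_cells = integer(0),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cl_labels <- rep(names(cells_per_cluster), cells_per_cluster)
  n_cells <- length(cl_labels)
  genes <- c(paste0("gene", seq_len(n_genes)),
             if (n_mito > 0) paste0("mt-", seq_len(n_mito)))
  mu <- matrix(nb_mean, nrow = length(genes), ncol = n_cells,
               dimnames = list(genes, paste0("cell", seq_len(n_cells))))
  if (!is.null(markers) && nrow(markers)) {
    for (i in seq_len(nrow(markers))) {
      mu[markers$gene[i], cl_labels == markers$cluster[i]] <-
        nb_mean * markers$fold_change[i]
    }
  }
  if (n_mito > 0 && length(mito_cells)) {
    mu[grepl("^mt-", genes), mito_cells] <-
      mu[grepl("^mt-", genes), mito_cells] * mito_boost
  }
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion),
                   nrow = nrow(mu), dimnames = dimnames(mu))
  clusters <- setNames(cl_labels, colnames(counts))
  list(counts = counts, clusters = clusters,
       truth = if (is.null(markers)) {
         data.frame(gene = character(0), cluster = character(0),
                    fold_change = numeric(0))
       } else markers)
}

#' Write a simulation preset to disk
#'
#' Generates a self-contained input set for the pipeline in the standard
#' interchange formats (FASTA, JASPAR PFM, bedGraph, BED12, TSV) plus a
#' `truth/` directory of ground-truth tables. Presets:
#' \describe{
#'   \item{mg-demo}{A TF panel of four sharp motifs, 12 candidate CRMs with
#'     planted high-density sites and 12 motif-free decoys — the
#'     density-prescreen demonstration.}
#'   \item{peaks-demo}{A coverage track with planted triangular, gaussian,
#'     plateau and sub-threshold peaks plus BED12 gene models (one planted
#'     peak exonic).}
#'   \item{markers-demo}{An NB count matrix, 100 target vs 300 rest cells,
#'     20 planted 16-fold markers, cluster labels and a TF list.}
#'   \item{stitch-demo}{Three stage bedGraph tracks, a brain track, gene
#'     models and a genome FASTA for the stitching designer.}
#' }
#'
#' @param preset One of `"mg-demo"`, `"peaks-demo"`, `"markers-demo"`,
#'   `"stitch-demo"`.
#' @param seed Integer seed; every file is a deterministic function of it.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the files written plus the in-memory
#'   truth objects.
#' @export
simulate_preset <- function(preset = c("mg-demo", "peaks-demo",
                                       "markers-demo", "stitch-demo"),
                            seed = 1L, out_dir) {
  preset <- match.arg(preset)
  dir.create(file.path(out_dir, "truth"), recursive = TRUE,
             showWarnings = FALSE)
  # independent substreams per component so modules regenerate independently
  sub <- function(k) as.integer((seed * 101L + k) %% .Machine$integer.max)
  switch(preset,
         "mg-demo" = preset_mg_demo(sub, out_dir),
         "peaks-demo" = preset_peaks_demo(sub, out_dir),
         "markers-demo" = preset_markers_demo(sub, out_dir),
         "stitch-demo" = preset_stitch_demo(sub, out_dir))
}

## Four 10-bp sharp motifs; active candidates carry 18 planted sites per
## 500 bp (merged density 3.6 per 100 bp, at least twice either cut),
## decoys carry none.
demo_panel_consensus <- c("TGACGTCATG", "GGCCAATCAG", "CACGTGACTT",
                          "TTGCGCAAGG")

preset_mg_demo <- function(sub, out_dir) {
  profiles <- lapply(seq_along(demo_panel_consensus), function(i) {
    make_profile(demo_panel_consensus[i], sharpness = 1.0,
                 motif_id = sprintf("SYN%04d", i),
                 tf_name = paste0("TF", i))
  })
  pfm_path <- file.path(out_dir, "panel.pfm")
  write_jaspar_pfm(profiles, pfm_path)
  set.seed(sub(1L))
  n_active <- 12L
  n_decoy <- 12L
  len <- 500L
  fa <- character(0)
  truth_rows <- list()
  for (k in seq_len(n_active)) {
    n_sites <- 18L
    pos <- seq(10L, by = 25L, length.out = n_sites)
    cons <- sample(demo_panel_consensus, n_sites, replace = TRUE)
    sites <- data.frame(
      motif_id = sprintf("SYN%04d", match(cons, demo_panel_consensus)),
      site = cons, position = pos,
      strand = sample(c("+", "-"), n_sites, replace = TRUE),
      stringsAsFactors = FALSE)
    ps <- plant_sequence(len, sites, gc = 0.4)
    id <- sprintf("active_%02d", k)
    fa <- c(fa, paste0(">", id), chunk_string(ps$sequence, 70L))
    truth_rows[[length(truth_rows) + 1L]] <-
      cbind(crm_id = id, ps$truth, planted_active = TRUE)
  }
  for (k in seq_len(n_decoy)) {
    ps <- plant_sequence(len, NULL, gc = 0.4)
    id <- sprintf("decoy_%02d", k)
    fa <- c(fa, paste0(">", id), chunk_string(ps$sequence, 70L))
  }
  fasta_path <- file.path(out_dir, "candidates.fa")
  writeLines(fa, fasta_path)
  truth <- do.call(rbind, truth_rows)
  truth_path <- file.path(out_dir, "truth", "planted_sites.tsv")
  write.table(truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  active_ids <- sprintf("active_%02d", seq_len(n_active))
  decoy_ids <- sprintf("decoy_%02d", seq_len(n_decoy))
  labels_path <- file.path(out_dir, "truth", "candidate_labels.tsv")
  write.table(data.frame(crm_id = c(active_ids, decoy_ids),
                         planted_active = rep(c(TRUE, FALSE),
                                              c(n_active, n_decoy))),
              labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(pfm = pfm_path, fasta = fasta_path, truth = truth,
                 files = c(pfm_path, fasta_path, truth_path, labels_path)))
}

preset_peaks_demo <- function(sub, out_dir) {
  specs <- data.frame(
    tip_pos = c(300L, 900L, 1500L, 2100L),
    tip_value = c(40, 30, 25, 15),
    half_width = c(10L, 5L, 20L, 10L),
    shape = c("triangular", "plateau", "gaussian", "triangular"),
    stringsAsFactors = FALSE)
  cov <- make_coverage(3000L, specs, noise_sd = 0, seed = sub(2L))
  bg_path <- file.path(out_dir, "coverage.bedGraph")
  write_bedgraph(cov$track, bg_path)
  # gene models: the gaussian peak at 1500 lies inside an exon
  genes <- gene_models(
    gene_id = c("geneL", "geneQ", "geneR"), chrom = "chr1",
    strand = c("+", "+", "-"),
    tx_start = c(0L, 100L, 2800L), tx_end = c(50L, 2700L, 3000L),
    exons = list(cbind(0L, 50L),
                 rbind(c(100L, 160L), c(1450L, 1550L), c(2650L, 2700L)),
                 cbind(2800L, 3000L)))
  bed_path <- file.path(out_dir, "genes.bed")
  write_bed12(genes, bed_path)
  set.seed(sub(3L))
  genome_path <- file.path(out_dir, "genome.fa")
  writeLines(c(">chr1", chunk_string(random_dna(3000L, 0.4), 70L)),
             genome_path)
  truth_path <- file.path(out_dir, "truth", "peaks.tsv")
  write.table(cov$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(coverage = bg_path, genes = bed_path, genome = genome_path,
                 truth = cov$truth, gene_models = genes,
                 files = c(bg_path, bed_path, genome_path, truth_path)))
}

preset_markers_demo <- function(sub, out_dir) {
  n_planted <- 20L
  markers <- data.frame(gene = paste0("gene", seq_len(n_planted)),
                        cluster = "MG", fold_change = 16,
                        stringsAsFactors = FALSE)
  sim <- make_expression(n_genes = 300L,
                         cells_per_cluster = c(MG = 100L, rest = 300L),
                         nb_mean = 2, nb_dispersion = 0.5,
                         markers = markers, seed = sub(4L))
  counts_path <- file.path(out_dir, "counts.tsv")
  write.table(sim$counts, counts_path, sep = "\t", quote = FALSE,
              col.names = NA)
  cl_path <- file.path(out_dir, "clusters.tsv")
  write.table(data.frame(cell = names(sim$clusters),
                         cluster = unname(sim$clusters)),
              cl_path, sep = "\t", quote = FALSE, row.names = FALSE)
  tf_path <- file.path(out_dir, "tf_list.tsv")
  writeLines(c("gene_id", paste0("gene", seq(1L, 300L, by = 3L))), tf_path)
  truth_path <- file.path(out_dir, "truth", "planted_markers.tsv")
  write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(counts = counts_path, clusters = cl_path, tfs = tf_path,
                 truth = sim$truth, sim = sim,
                 files = c(counts_path, cl_path, tf_path, truth_path)))
}

preset_stitch_demo <- function(sub, out_dir) {
  n <- 6000L
  stage_specs <- list(
    retina_P1 = data.frame(tip_pos = c(500L, 2000L), tip_value = c(40, 35),
                           half_width = 15L, shape = "triangular"),
    retina_P7 = data.frame(tip_pos = c(520L, 3500L), tip_value = c(30, 45),
                           half_width = 15L, shape = "triangular"),
    retina_8wk = data.frame(tip_pos = 5000L, tip_value = 50,
                            half_width = 15L, shape = "triangular"))
  files <- character(0)
  for (lab in names(stage_specs)) {
    cov <- make_coverage(n, stage_specs[[lab]], noise_sd = 0)
    p <- file.path(out_dir, paste0(lab, ".bedGraph"))
    write_bedgraph(cov$track, p)
    files <- c(files, p)
  }
  # brain shares the peak near 3500 -> rejected by the specificity filter
  brain <- make_coverage(n, data.frame(tip_pos = 3510L, tip_value = 60,
                                       half_width = 20L,
                                       shape = "triangular"), noise_sd = 0)
  brain_path <- file.path(out_dir, "brain.bedGraph")
  write_bedgraph(brain$track, brain_path)
  # the peak near 2000 lies in an exon -> excluded by the exon filter
  genes <- gene_models(gene_id = c("geneA", "target", "geneB"),
                       chrom = "chr1", strand = "+",
                       tx_start = c(0L, 1000L, 5800L),
                       tx_end = c(100L, 4000L, 6000L),
                       exons = list(cbind(0L, 100L),
                                    rbind(c(1000L, 1100L), c(1950L, 2050L)),
                                    cbind(5800L, 6000L)))
  bed_path <- file.path(out_dir, "genes.bed")
  write_bed12(genes, bed_path)
  set.seed(sub(5L))
  genome_path <- file.path(out_dir, "genome.fa")
  writeLines(c(">chr1", chunk_string(random_dna(n, 0.42), 70L)), genome_path)
  invisible(list(stages = files, brain = brain_path, genes = bed_path,
                 genome = genome_path, gene_models = genes,
                 files = c(files, brain_path, bed_path, genome_path)))
}

#' Write motif profiles in the JASPAR raw PFM dialect
#'
#' @param profiles List of `motif_profile` objects.
#' @param path Output file.
#' @export
write_jaspar_pfm <- function(profiles, path) {
  lines <- unlist(lapply(profiles, function(p) {
    c(paste0(">", p$motif_id, " ", p$tf_name),
      vapply(seq_len(4L), function(r) {
        paste0(DNA_BASES[r], "  [ ",
               paste(format(p$pfm[r, ], trim = TRUE), collapse = " "), " ]")
      }, character(1)))
  }))
  writeLines(lines, path)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal signal collapse to one interval; zero runs are omitted.
#'
#' @param track A `coverage_track`.
#' @param path Output file.
#' @export
write_bedgraph <- function(track, path) {
  r <- rle(track$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nz <- r$values != 0
  lines <- sprintf("%s\t%d\t%d\t%s", track$chrom,
                   track$origin + starts[nz] - 1L, track$origin + ends[nz],
                   format(r$values[nz], trim = TRUE, scientific = FALSE))
  writeLines(lines, path)
}

#' Write gene models as BED12
#'
#' @param genes Gene-model data.frame (see [gene_models()]).
#' @param path Output file.
#' @export
write_bed12 <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    sizes <- paste0(paste(ex[, 2] - ex[, 1], collapse = ","), ",")
    offs <- paste0(paste(ex[, 1] - genes$tx_start[i], collapse = ","), ",")
    paste(genes$chrom[i], genes$tx_start[i], genes$tx_end[i],
          genes$gene_id[i], 0, genes$strand[i], genes$tx_start[i],
          genes$tx_end[i], "0,0,0", nrow(ex), sizes, offs, sep = "\t")
  }, character(1))
  writeLines(lines, path)
}
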