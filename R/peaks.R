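#' Read an accessibility coverage track
#'
#' Accepts bedGraph or wiggle (fixedStep/variableStep) per-base signal, via
#' rtracklayer. Each chromosome becomes one dense per-bp vector anchored at
#' genomic position 0; positions not covered by the file read as 0.
#'
#' @param path Coverage file. Dialect is sniffed: lines starting with
#'   `fixedStep`/`variableStep` mean wiggle, otherwise bedGraph.
#' @return Named list (by chromosome) of `coverage_track` objects, each with
#'   `chrom`, `origin` (0) and `values`. An empty file yields an empty list.
#' @export
read_coverage <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^\\s*(#|track\\b|browser\\b)", lines) &
                nzchar(trimws(lines))]
  if (!length(body)) return(list())
  fmt <- if (any(grepl("^(fixedStep|variableStep)", body))) "wig" else "bedGraph"
  gr <- rtracklayer::import(path, format = fmt)
  if (any(gr$score < 0)) stop("negative coverage value in ", path)
  tracks <- list()
  for (chr in unique(as.character(GenomicRanges::seqnames(gr)))) {
    g <- gr[as.character(GenomicRanges::seqnames(gr)) == chr]
    g <- g[order(GenomicRanges::start(g))]
    s0 <- GenomicRanges::start(g) - 1L   # to 0-based half-open
    e0 <- GenomicRanges::end(g)
    if (length(g) > 1L && any(s0[-1] < e0[-length(e0)])) {
      stop("overlapping coverage intervals on ", chr, " in ", path)
    }
    values <- numeric(max(e0))
    for (i in seq_along(g)) {
      values[(s0[i] + 1L):e0[i]] <- g$score[i]
    }
    tracks[[chr]] <- structure(list(chrom = chr, origin = 0L, values = values),
                               class = "coverage_track")
  }
  tracks
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track> ", x$chrom, ": ", length(x$values),
      " bp from position ", x$origin, ", max signal ",
      format(max(x$values)), "\n", sep = "")
  invisible(x)
}

#' Build a coverage track from a values vector
#'
#' @param values Per-bp non-negative signal.
#' @param chrom Chromosome name.
#' @param origin 0-based genomic position of `values[1]`.
#' @return A `coverage_track`.
#' @export
coverage_track <- function(values, chrom = "chr1", origin = 0L) {
  if (!length(values) || any(values < 0)) {
    stop("values must be non-empty and non-negative")
  }
  structure(list(chrom = chrom, origin = as.integer(origin),
                 values = as.numeric(values)),
            class = "coverage_track")
}

#' Read gene models with exon structure
#'
#' BED12 (one transcript per line with block structure) or GTF input, via
#' rtracklayer. Coordinates are converted to 0-based half-open.
#'
#' @param path BED12 or GTF file; format sniffed from the extension
#'   (`.gtf`/`.gff` vs BED).
#' @return Data.frame with `gene_id`, `chrom`, `strand`, `tx_start`,
#'   `tx_end` and a list-column `exons` of two-column (start, end) matrices.
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.(gtf|gff[23]?)$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "gtf")
    ex <- gr[gr$type == "exon"]
    ids <- if (!is.null(ex$gene_id)) ex$gene_id else ex$gene_name
    rows <- lapply(unique(ids), function(g) {
      e <- ex[ids == g]
      em <- cbind(GenomicRanges::start(e) - 1L, GenomicRanges::end(e))
      em <- em[order(em[, 1]), , drop = FALSE]
      list(gene_id = g,
           chrom = as.character(GenomicRanges::seqnames(e))[1],
           strand = as.character(GenomicRanges::strand(e))[1],
           tx_start = min(em[, 1]), tx_end = max(em[, 2]), exons = em)
    })
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    rows <- lapply(seq_along(gr), function(i) {
      g <- gr[i]
      if (!is.null(g$blocks) && length(g$blocks[[1]])) {
        b <- g$blocks[[1]]
        em <- cbind(GenomicRanges::start(g) - 1L + GenomicRanges::start(b) - 1L,
                    GenomicRanges::start(g) - 1L + GenomicRanges::end(b))
      } else {
        em <- cbind(GenomicRanges::start(g) - 1L, GenomicRanges::end(g))
      }
      list(gene_id = if (!is.null(g$name)) g$name else paste0("gene", i),
           chrom = as.character(GenomicRanges::seqnames(g)),
           strand = as.character(GenomicRanges::strand(g)),
           tx_start = GenomicRanges::start(g) - 1L,
           tx_end = GenomicRanges::end(g), exons = em)
    })
  }
  gene_models(
    gene_id = vapply(rows, `[[`, character(1), "gene_id"),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    tx_start = vapply(rows, function(r) as.integer(r$tx_start), integer(1)),
    tx_end = vapply(rows, function(r) as.integer(r$tx_end), integer(1)),
    exons = lapply(rows, `[[`, "exons"))
}

#' Construct a gene-model table in code
#'
#' @param gene_id,chrom,strand,tx_start,tx_end Parallel vectors; coordinates
#'   0-based half-open.
#' @param exons List of two-column (start, end) matrices, one per gene;
#'   `NULL` makes each gene a single exon spanning its body.
#' @return Gene-model data.frame as from [read_gene_models()].
#' @export
gene_models <- function(gene_id, chrom, strand, tx_start, tx_end,
                        exons = NULL) {
  if (is.null(exons)) {
    exons <- Map(function(s, e) cbind(s, e), tx_start, tx_end)
  }
  df <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                   tx_start = as.integer(tx_start),
                   tx_end = as.integer(tx_end), stringsAsFactors = FALSE)
  df$exons <- exons
  df
}

#' Flanking region of a gene bounded by its neighbours
#'
#' The candidate search space for a gene: from the body end of the nearest
#' upstream gene to the body start of the nearest downstream gene (same
#' chromosome), including the query gene's own body — intragenic, non-exonic
#' peaks stay eligible. Chromosome edges (0 / `chrom_len`) are used where no
#' neighbour exists; a neighbour overlapping the gene clips that side's
#' flank to zero length with a warning.
#'
#' @param gene_id Query gene.
#' @param genes Gene-model data.frame containing the query.
#' @param chrom_len Right edge when no downstream neighbour exists
#'   (default `Inf`).
#' @return Numeric `c(start, end)`, 0-based half-open.
#' @export
flanking_region <- function(gene_id, genes, chrom_len = Inf) {
  i <- match(gene_id, genes$gene_id)
  if (is.na(i)) stop("gene '", gene_id, "' not found in gene models")
  g <- genes[i, ]
  same <- genes[genes$chrom == g$chrom & genes$gene_id != gene_id, ]
  up <- same[same$tx_start < g$tx_start, ]
  dn <- same[same$tx_end > g$tx_end, ]
  left <- if (nrow(up)) max(up$tx_end) else 0
  right <- if (nrow(dn)) min(dn$tx_start) else chrom_len
  if (left > g$tx_start) {
    warning("upstream neighbour overlaps ", gene_id,
            "; upstream flank clipped to zero length")
    left <- g$tx_start
  }
  if (right < g$tx_end) {
    warning("downstream neighbour overlaps ", gene_id,
            "; downstream flank clipped to zero length")
    right <- g$tx_end
  }
  c(start = left, end = right)
}

#' Call accessibility peaks by the tip / 20%-of-tip rule
#'
#' Every local signal maximum with tip value at least `tip_min` seeds a
#' peak; its boundaries extend outward over the contiguous run of positions
#' whose signal is at least `boundary_frac` of that tip. Peaks whose extents
#' overlap are merged, keeping the higher tip. On a flat plateau the tip
#' position is the leftmost maximal position.
#'
#' @param track A `coverage_track`.
#' @param region Optional `c(start, end)` genomic interval (0-based
#'   half-open) restricting the search; `NULL` scans the whole track.
#' @param tip_min Minimum tip signal for a peak (default 20).
#' @param boundary_frac Boundary threshold as a fraction of the tip
#'   (default 0.2); must be in (0, 1).
#' @return Data.frame of peaks sorted by start: `chrom`, `start`, `end`,
#'   `tip_pos`, `tip_value` (0-based half-open).
#' @export
call_peaks <- function(track, region = NULL, tip_min = 20,
                       boundary_frac = 0.2) {
  if (boundary_frac <= 0 || boundary_frac >= 1) {
    stop("boundary_frac must be in (0, 1)")
  }
  if (tip_min <= 0) stop("tip_min must be > 0")
  lo <- track$origin
  hi <- track$origin + length(track$values)
  if (is.null(region)) region <- c(lo, hi)
  a <- max(lo, region[1])
  b <- min(hi, region[2])
  if (a >= b) return(empty_peaks())
  v <- track$values[(a - track$origin + 1L):(b - track$origin)]
  n <- length(v)
  # plateau-aware local maxima: runs of equal value higher than both sides
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  m <- length(r$values)
  left_ok <- c(TRUE, r$values[-1] > r$values[-m])
  right_ok <- c(r$values[-m] > r$values[-1], TRUE)
  tips <- starts[left_ok & right_ok & r$values >= tip_min]
  if (!length(tips)) return(empty_peaks())
  peaks <- lapply(tips, function(tp) {
    # tiny slack so representation error at an exact fraction of the tip
    # cannot flip the ">= 20% of tip" comparison
    thr <- boundary_frac * v[tp] - 1e-9
    s <- tp
    while (s > 1L && v[s - 1L] >= thr) s <- s - 1L
    e <- tp
    while (e < n && v[e + 1L] >= thr) e <- e + 1L
    c(start = a + s - 1L, end = a + e, tip_pos = a + tp - 1L,
      tip_value = v[tp])
  })
  p <- as.data.frame(do.call(rbind, peaks))
  p <- p[order(p$start, p$end), , drop = FALSE]
  # merge overlapping extents, keeping the higher tip
  merged <- p[1, , drop = FALSE]
  for (i in seq_len(nrow(p))[-1]) {
    j <- nrow(merged)
    if (p$start[i] < merged$end[j]) {
      merged$end[j] <- max(merged$end[j], p$end[i])
      if (p$tip_value[i] > merged$tip_value[j]) {
        merged$tip_value[j] <- p$tip_value[i]
        merged$tip_pos[j] <- p$tip_pos[i]
      }
    } else {
      merged <- rbind(merged, p[i, ])
    }
  }
  rownames(merged) <- NULL
  cbind(chrom = track$chrom, merged, stringsAsFactors = FALSE)
}

empty_peaks <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             tip_pos = numeric(0), tip_value = numeric(0),
             stringsAsFactors = FALSE)
}

#' Remove peaks overlapping any exon
#'
#' A peak sharing at least 1 bp with any exon of any gene is dropped;
#' half-open intervals that merely touch do not overlap.
#'
#' @param peaks Peak data.frame from [call_peaks()].
#' @param genes Gene-model data.frame.
#' @return The non-exonic subset of `peaks`.
#' @export
exclude_exonic <- function(peaks, genes) {
  if (!nrow(peaks) || !nrow(genes)) return(peaks)
  keep <- vapply(seq_len(nrow(peaks)), function(i) {
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != peaks$chrom[i]) next
      ex <- genes$exons[[j]]
      if (any(ex[, 1] < peaks$end[i] & ex[, 2] > peaks$start[i])) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nominate putative CRMs flanking a gene
#'
#' Composes the nomination pipeline: restrict the track to the gene's
#' neighbour-bounded flanking region, call tip/boundary peaks, drop
#' exon-overlapping peaks, and extract candidate sequences. Candidates are
#' named `<gene>_<ordinal>` in genomic order.
#'
#' @param gene_id Gene of interest.
#' @param track `coverage_track` on the gene's chromosome.
#' @param genes Gene-model data.frame (bounds and exon filter).
#' @param genome Named character vector or `DNAStringSet` of chromosome
#'   sequences, or a FASTA path; `NULL` skips sequence extraction.
#' @param tip_min,boundary_frac Peak-calling parameters (see
#'   [call_peaks()]).
#' @return Data.frame of candidates: `crm_id`, `chrom`, `start`, `end`,
#'   `tip_pos`, `tip_value`, `sequence` (empty string when `genome` is
#'   `NULL`).
#' @export
nominate_crms <- function(gene_id, track, genes, genome = NULL,
                          tip_min = 20, boundary_frac = 0.2) {
  region <- flanking_region(gene_id, genes,
                            chrom_len = track$origin + length(track$values))
  peaks <- call_peaks(track, region, tip_min, boundary_frac)
  peaks <- exclude_exonic(peaks, genes)
  if (!nrow(peaks)) {
    return(cbind(data.frame(crm_id = character(0)), empty_peaks(),
                 data.frame(sequence = character(0))))
  }
  seqs <- rep("", nrow(peaks))
  if (!is.null(genome)) {
    gen <- load_genome(genome)
    seqs <- vapply(seq_len(nrow(peaks)), function(i) {
      substr(gen[[peaks$chrom[i]]], peaks$start[i] + 1L, peaks$end[i])
    }, character(1))
  }
  out <- cbind(data.frame(crm_id = paste0(gene_id, "_", seq_len(nrow(peaks))),
                          stringsAsFactors = FALSE),
               peaks, data.frame(sequence = seqs, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

## Accept a FASTA path, DNAStringSet or named character vector of chromosomes.
load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), sub("\\s.*$", "", names(genome)))
  }
  as.list(toupper(genome))
}
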