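#' Union accessibility peaks across developmental stages
#'
#' Pools called peaks from several stage tracks (e.g. retina at P1, P7 and
#' 8 weeks) into one non-overlapping interval set: overlapping peaks from
#' different stages merge into a single interval that keeps the highest tip
#' and concatenates the provenance labels.
#'
#' @param sets Named list of peak data.frames (from [call_peaks()]); names
#'   are the stage labels.
#' @return Peak data.frame with an extra `sources` column
#'   (comma-separated stage labels), sorted by start.
#' @export
union_stage_peaks <- function(sets) {
  if (is.null(names(sets))) names(sets) <- paste0("stage", seq_along(sets))
  rows <- do.call(rbind, lapply(names(sets), function(lab) {
    p <- sets[[lab]]
    if (!nrow(p)) return(NULL)
    p$sources <- lab
    p
  }))
  if (is.null(rows) || !nrow(rows)) {
    out <- empty_peaks()
    out$sources <- character(0)
    return(out)
  }
  rows <- rows[order(rows$start, rows$end), , drop = FALSE]
  merged <- rows[1, , drop = FALSE]
  for (i in seq_len(nrow(rows))[-1]) {
    j <- nrow(merged)
    if (rows$chrom[i] == merged$chrom[j] && rows$start[i] < merged$end[j]) {
      merged$end[j] <- max(merged$end[j], rows$end[i])
      merged$sources[j] <- paste(unique(c(
        strsplit(merged$sources[j], ",")[[1]], rows$sources[i])),
        collapse = ",")
      if (rows$tip_value[i] > merged$tip_value[j]) {
        merged$tip_value[j] <- rows$tip_value[i]
        merged$tip_pos[j] <- rows$tip_pos[i]
      }
    } else {
      merged <- rbind(merged, rows[i, ])
    }
  }
  rownames(merged) <- NULL
  merged
}

#' Reject peaks shared with a second tissue
#'
#' Keeps only candidates specific to the tissue of interest: any candidate
#' sharing at least `min_overlap_bp` of sequence with a peak of the other
#' tissue (e.g. accessible in both retina and brain) is removed. With no
#' other-tissue peaks supplied, all candidates are kept and a warning notes
#' that specificity filtering was skipped.
#'
#' @param candidates Peak data.frame.
#' @param other_tissue Peak data.frame for the second tissue, or `NULL`.
#' @param min_overlap_bp Minimum shared bp counting as an overlap
#'   (default 1).
#' @return The tissue-specific subset of `candidates`.
#' @export
tissue_specific_filter <- function(candidates, other_tissue,
                                   min_overlap_bp = 1L) {
  if (is.null(other_tissue) || !nrow(other_tissue)) {
    warning("no other-tissue peaks supplied; specificity filtering skipped")
    return(candidates)
  }
  if (!nrow(candidates)) return(candidates)
  keep <- vapply(seq_len(nrow(candidates)), function(i) {
    same <- other_tissue$chrom == candidates$chrom[i]
    ov <- pmin(other_tissue$end[same], candidates$end[i]) -
      pmax(other_tissue$start[same], candidates$start[i])
    !any(ov >= min_overlap_bp)
  }, logical(1))
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stitch accessible regions into one synthetic CRM
#'
#' Extracts each component peak's forward-strand sequence from the genome
#' and concatenates the components in ascending genomic start order (no
#' spacer by default). The AAV packaging budget is checked:
#' `fits` is true when stitched length + cargo + overhead stays within
#' `limit_bp` (~4.7 kb for AAV).
#'
#' @param peaks Non-overlapping peak data.frame (run [union_stage_peaks()]
#'   first if stages may overlap).
#' @param genome Genome as for [nominate_crms()].
#' @param name Name of the synthetic CRM.
#' @param cargo_bp Cargo size in bp (e.g. a reporter ORF); default 0.
#' @param overhead_bp Vector backbone overhead in bp (ITRs, promoter,
#'   polyA); default 0.
#' @param limit_bp Packaging limit in bp (default 4700).
#' @param spacer Optional spacer sequence inserted between components
#'   (default none).
#' @return A `stitched_crm`: `name`, `components` (data.frame with
#'   provenance, coordinates and per-component sequence), `sequence`,
#'   `total_bp`, and `budget` (`cargo_bp`, `overhead_bp`, `limit_bp`,
#'   `total_insert_bp`, `fits`).
#' @export
stitch <- function(peaks, genome, name = "stitched_crm", cargo_bp = 0L,
                   overhead_bp = 0L, limit_bp = 4700L, spacer = "") {
  if (!nrow(peaks)) stop("no peaks to stitch")
  peaks <- peaks[order(peaks$start, peaks$end), , drop = FALSE]
  if (nrow(peaks) > 1L &&
      any(peaks$start[-1] < peaks$end[-nrow(peaks)] &
          peaks$chrom[-1] == peaks$chrom[-nrow(peaks)])) {
    stop("overlapping peaks; merge them first (see union_stage_peaks)")
  }
  gen <- load_genome(genome)
  seqs <- vapply(seq_len(nrow(peaks)), function(i) {
    chr <- gen[[peaks$chrom[i]]]
    if (is.null(chr) || nchar(chr) < peaks$end[i]) {
      stop("genome does not cover ", peaks$chrom[i], ":", peaks$start[i],
           "-", peaks$end[i])
    }
    substr(chr, peaks$start[i] + 1L, peaks$end[i])
  }, character(1))
  sequence <- paste(seqs, collapse = spacer)
  components <- data.frame(
    source = if (!is.null(peaks$sources)) peaks$sources else "",
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    length = peaks$end - peaks$start, sequence = seqs,
    stringsAsFactors = FALSE)
  total_bp <- nchar(sequence)
  total_insert <- total_bp + cargo_bp + overhead_bp
  structure(list(
    name = name, components = components, sequence = sequence,
    total_bp = total_bp,
    budget = list(cargo_bp = cargo_bp, overhead_bp = overhead_bp,
                  limit_bp = limit_bp, total_insert_bp = total_insert,
                  fits = total_insert <= limit_bp)),
    class = "stitched_crm")
}

#' @export
print.stitched_crm <- function(x, ...) {
  cat("<stitched_crm> ", x$name, ": ", nrow(x$components),
      " component(s), ", x$total_bp, " bp\n", sep = "")
  b <- x$budget
  cat(sprintf("  budget: %d (CRM) + %d (cargo) + %d (overhead) = %d bp vs limit %d — %s\n",
              x$total_bp, b$cargo_bp, b$overhead_bp, b$total_insert_bp,
              b$limit_bp, if (b$fits) "fits" else "DOES NOT FIT"))
  invisible(x)
}

#' Write a stitched CRM as FASTA plus a component table
#'
#' The FASTA header records the concatenation convention (ascending genomic
#' start, forward strand) and the budget outcome.
#'
#' @param x A `stitched_crm`.
#' @param fasta,tsv Output paths (either may be `NULL` to skip).
#' @return `x`, invisibly.
#' @export
write_stitched_crm <- function(x, fasta = NULL, tsv = NULL) {
  if (!is.null(fasta)) {
    hdr <- sprintf(
      ">%s components=%d order=ascending_start strand=+ total_bp=%d fits=%s",
      x$name, nrow(x$components), x$total_bp, tolower(x$budget$fits))
    writeLines(c(hdr, chunk_string(x$sequence, 70L)), fasta)
  }
  if (!is.null(tsv)) {
    write.table(x$components[, c("source", "chrom", "start", "end", "length")],
                tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(x)
}

chunk_string <- function(s, width) {
  if (!nchar(s)) return(character(0))
  starts <- seq(1L, nchar(s), by = width)
  vapply(starts, function(i) substr(s, i, min(i + width - 1L, nchar(s))),
         character(1))
}
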