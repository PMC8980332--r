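#' Classifier configuration for the TFBS-density prescreen
#'
#' Bundles the thresholds of the two-axis density classifier. Defaults are
#' the published operating point: hits are split at raw log-odds ("JASPAR
#' score") cuts 10 and 11, merged within 5 bp, normalised per 100 bp, and a
#' candidate is called likely-active when its density at score > 10 exceeds
#' 1.7 and its density at score > 11 exceeds 1 (rule `AND`; quadrant A2).
#'
#' @param thr_low Raw-score cut for the x-axis density (default 10).
#' @param thr_high Raw-score cut for the y-axis density (default 11).
#' @param density_x_cut Density cut on the x-axis, per 100 bp (default 1.7).
#' @param density_y_cut Density cut on the y-axis, per 100 bp (default 1.0).
#' @param merge_window_bp Hits whose starts are within this many bp count
#'   once (default 5).
#' @param combine_rule `"AND"` (both axes must exceed their cut; default)
#'   or `"OR"`.
#' @param relative_threshold Relative-score scan threshold (default 0.80).
#' @param chain `"anchor"` (default): a hit joins a cluster if within
#'   `merge_window_bp` of the cluster's first hit; `"neighbor"`: within the
#'   window of the previous hit.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(thr_low = 10, thr_high = 11,
                              density_x_cut = 1.7, density_y_cut = 1.0,
                              merge_window_bp = 5L,
                              combine_rule = c("AND", "OR"),
                              relative_threshold = 0.80,
                              chain = c("anchor", "neighbor")) {
  combine_rule <- match.arg(combine_rule)
  chain <- match.arg(chain)
  if (thr_high < thr_low) stop("thr_high must be >= thr_low")
  if (density_x_cut <= 0 || density_y_cut <= 0) stop("density cuts must be > 0")
  structure(list(thr_low = thr_low, thr_high = thr_high,
                 density_x_cut = density_x_cut, density_y_cut = density_y_cut,
                 merge_window_bp = as.integer(merge_window_bp),
                 combine_rule = combine_rule,
                 relative_threshold = relative_threshold, chain = chain),
            class = "classifier_config")
}

#' Detect long tandem repeats in a DNA sequence
#'
#' Finds maximal intervals where a short unit (length `<= max_unit`) repeats
#' at least `min_copies` consecutive times over at least `min_total_len` bp
#' — e.g. `CTCCCT` units or `ACACACACACACAC` microsatellite runs. Motif hits
#' falling inside such regions are excluded from the density statistic,
#' since runs of a repeated unit tile spurious matches.
#'
#' @param seq DNA string.
#' @param max_unit Maximum repeat-unit length in bp (default 6, at most 10).
#' @param min_copies Minimum consecutive copies (default 3).
#' @param min_total_len Minimum total span in bp (default 12).
#' @return A `repeat_mask`: data.frame with 0-based half-open `start`,
#'   `end`, the smallest repeating `unit` length, and `copies`
#'   (full copies of that unit within the interval). Overlapping detections
#'   are merged into maximal intervals.
#' @export
detect_tandem_repeats <- function(seq, max_unit = 6L, min_copies = 3L,
                                  min_total_len = 12L) {
  if (max_unit < 1L || max_unit > 10L) stop("max_unit must be in 1..10")
  if (min_copies < 1L || min_total_len < 1L) stop("parameters must be positive")
  s <- strsplit(toupper(as.character(seq)[1]), "")[[1]]
  n <- length(s)
  found <- list()
  for (u in seq_len(min(max_unit, n - 1L))) {
    same <- s[seq_len(n - u)] == s[seq_len(n - u) + u]
    r <- rle(same)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      span <- r$lengths[k] + u            # bp covered by the periodic run
      if (span >= min_total_len && span %/% u >= min_copies) {
        found[[length(found) + 1L]] <-
          c(start = starts[k] - 1L, end = starts[k] - 1L + span, unit = u)
      }
    }
  }
  if (!length(found)) {
    return(structure(data.frame(start = integer(0), end = integer(0),
                                unit = integer(0), copies = integer(0)),
                     class = c("repeat_mask", "data.frame")))
  }
  m <- as.data.frame(do.call(rbind, found))
  m <- m[order(m$start, m$end), , drop = FALSE]
  # merge overlapping/adjacent periodic intervals, keeping the smallest unit
  merged <- m[1, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1]) {
    j <- nrow(merged)
    if (m$start[i] <= merged$end[j]) {
      merged$end[j] <- max(merged$end[j], m$end[i])
      merged$unit[j] <- min(merged$unit[j], m$unit[i])
    } else {
      merged <- rbind(merged, m[i, ])
    }
  }
  merged$copies <- (merged$end - merged$start) %/% merged$unit
  rownames(merged) <- NULL
  structure(merged, class = c("repeat_mask", "data.frame"))
}

#' Merge nearby motif hits into TFBS counts
#'
#' Hits are pooled across all motifs and strands and clustered greedily left
#' to right on their start coordinates: a hit whose start lies within
#' `merge_window_bp` (inclusive) of the open cluster's anchor joins it,
#' otherwise it opens a new cluster. The cluster count is the "TFBS count"
#' entering the density statistic. Input order is irrelevant (hits are
#' sorted internally).
#'
#' @param hits Hit data.frame from [scan_sequence()], or a numeric vector of
#'   start coordinates.
#' @param merge_window_bp Non-negative clustering window in bp (default 5).
#' @param chain `"anchor"` (distance measured to the cluster's first hit,
#'   default) or `"neighbor"` (to the previous hit).
#' @return Integer cluster count.
#' @export
merge_hits <- function(hits, merge_window_bp = 5L,
                       chain = c("anchor", "neighbor")) {
  chain <- match.arg(chain)
  if (merge_window_bp < 0) stop("merge_window_bp must be non-negative")
  starts <- if (is.data.frame(hits)) hits$start else as.numeric(hits)
  if (length(starts) == 0L) return(0L)
  starts <- sort(starts)
  count <- 1L
  ref <- starts[1]
  for (x in starts[-1]) {
    if (x - ref <= merge_window_bp) {
      if (chain == "neighbor") ref <- x
    } else {
      count <- count + 1L
      ref <- x
    }
  }
  count
}

#' TFBS density of a candidate CRM at two score thresholds
#'
#' Scans the candidate on both strands at the configured relative threshold,
#' drops hits lying fully inside a tandem-repeat mask interval, splits the
#' survivors into raw-score > `thr_low` and > `thr_high` sets, merges each
#' set independently, and normalises the merged counts by the full candidate
#' length times 100. Masking removes hits, never length.
#'
#' @param seq Candidate DNA string (or named character vector).
#' @param profiles List of `motif_profile` objects (the cell-type-enriched
#'   TF panel).
#' @param cfg A [classifier_config()].
#' @param mask A `repeat_mask`, `NULL` to auto-detect with
#'   [detect_tandem_repeats()] defaults, or `NA` to disable masking.
#' @param crm_id Candidate identifier.
#' @return A one-row data.frame: `crm_id`, `length_bp`, `count_low`,
#'   `count_high`, `density_low`, `density_high`, `quadrant`,
#'   `predicted_active`.
#' @export
tfbs_density <- function(seq, profiles, cfg = classifier_config(),
                         mask = NULL, crm_id = NULL) {
  if (is.null(crm_id)) {
    crm_id <- if (!is.null(names(seq))) names(seq)[1] else "crm"
  }
  seq <- toupper(as.character(seq)[1])
  len <- nchar(seq)
  if (len == 0L) stop("zero-length candidate sequence")
  if (length(profiles) == 0L) stop("empty profile list")
  if (is.null(mask)) mask <- detect_tandem_repeats(seq)
  hits <- scan_sequence(seq, profiles, cfg$relative_threshold, seq_id = crm_id)
  hits <- drop_masked_hits(hits, mask)
  n_low <- merge_hits(hits[hits$raw_score > cfg$thr_low, , drop = FALSE],
                      cfg$merge_window_bp, cfg$chain)
  n_high <- merge_hits(hits[hits$raw_score > cfg$thr_high, , drop = FALSE],
                       cfg$merge_window_bp, cfg$chain)
  dp <- data.frame(crm_id = crm_id, length_bp = len,
                   count_low = n_low, count_high = n_high,
                   density_low = n_low / len * 100,
                   density_high = n_high / len * 100,
                   stringsAsFactors = FALSE)
  cbind(dp, classify(dp, cfg))
}

## Hits fully contained in any mask interval are dropped; partial overlaps
## are kept (conservative reading of repeat skipping).
drop_masked_hits <- function(hits, mask) {
  if (length(mask) == 1L && is.na(mask)) return(hits)
  if (!nrow(hits) || !nrow(mask)) return(hits)
  inside <- vapply(seq_len(nrow(hits)), function(i) {
    any(hits$start[i] >= mask$start & hits$end[i] <= mask$end)
  }, logical(1))
  hits[!inside, , drop = FALSE]
}

#' Quadrant call for a density profile
#'
#' Places a candidate on the two-threshold density plot: x = density at
#' raw score > `thr_low` against `density_x_cut`, y = density at raw score
#' > `thr_high` against `density_y_cut`. Quadrant A2 (x above cut AND y
#' above cut, strict inequalities) holds the likely-active candidates;
#' points on a cut line are not in A2. A1 is high-y/low-x, A3 low-x/low-y,
#' A4 high-x/low-y. `predicted_active` applies `combine_rule`.
#'
#' @param dp Data.frame with `density_low` and `density_high` columns (one
#'   or more rows).
#' @param cfg A [classifier_config()].
#' @return Data.frame with `quadrant` and `predicted_active`.
#' @export
classify <- function(dp, cfg = classifier_config()) {
  hx <- dp$density_low > cfg$density_x_cut
  hy <- dp$density_high > cfg$density_y_cut
  quadrant <- ifelse(hx & hy, "A2",
              ifelse(hy, "A1", ifelse(hx, "A4", "A3")))
  active <- if (cfg$combine_rule == "AND") hx & hy else hx | hy
  data.frame(quadrant = quadrant, predicted_active = active,
             stringsAsFactors = FALSE)
}

#' Density profiles for every candidate in a FASTA file
#'
#' @param fasta Path to a FASTA of candidate CRM sequences (record ids are
#'   used as `crm_id`).
#' @param profiles TF motif panel (list of `motif_profile`).
#' @param cfg A [classifier_config()].
#' @param mask Passed to [tfbs_density()] per candidate.
#' @return Data.frame, one row per candidate, in file order.
#' @export
density_table <- function(fasta, profiles, cfg = classifier_config(),
                          mask = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  out <- lapply(seq_along(seqs), function(i) {
    tfbs_density(as.character(seqs[[i]]), profiles, cfg, mask,
                 crm_id = sub("\\s.*$", "", names(seqs)[i]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
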