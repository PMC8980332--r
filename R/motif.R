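#' @importFrom stats rnbinom rnorm runif p.adjust wilcox.test setNames
#' @importFrom utils read.delim write.table packageVersion
#' @importFrom methods is
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Parse a JASPAR raw position frequency matrix file
#'
#' Reads the JASPAR "raw PFM" text dialect: each record is a `>ID NAME`
#' header followed by four rows of counts, one per base in the order
#' A, C, G, T, optionally written as `A  [ 4 19  0 ... ]`.
#'
#' @param path Path to a JASPAR-format PFM text file containing one or more
#'   matrices.
#' @param pseudocount Pseudocount added (distributed by background frequency)
#'   when converting counts to log-odds weights; must be positive.
#' @param background Numeric vector of four background probabilities for
#'   A, C, G, T; must be positive and sum to 1.
#' @return A list of `motif_profile` objects in file order. Each holds the
#'   count matrix (`pfm`), the log2-odds weight matrix (`pwm`), and the
#'   minimum/maximum attainable window scores.
#' @examples
#' pfm_file <- tempfile(fileext = ".pfm")
#' writeLines(c(">MA0000.1 TOY", "A [ 10 0 0 0 ]", "C [ 0 10 0 0 ]",
#'              "G [ 0 0 10 0 ]", "T [ 0 0 0 10 ]"), pfm_file)
#' profs <- load_jaspar_pfm(pfm_file)
#' profs[[1]]
#' @export
load_jaspar_pfm <- function(path, pseudocount = 1.0,
                            background = rep(0.25, 4)) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  lines <- lines[keep]
  headers <- grep("^>", lines)
  if (length(headers) == 0L) {
    stop("no JASPAR '>' header found in ", path)
  }
  profiles <- vector("list", length(headers))
  bounds <- c(headers, length(lines) + 1L)
  for (k in seq_along(headers)) {
    h <- lines[headers[k]]
    body <- lines[seq(bounds[k] + 1L, bounds[k + 1L] - 1L)]
    if (length(body) != 4L) {
      stop("matrix under header '", h, "' (line ", idx[headers[k]],
           ") has ", length(body), " rows; expected 4 (A, C, G, T)")
    }
    tokens <- strsplit(sub("^>\\s*", "", h), "\\s+")[[1]]
    motif_id <- tokens[1]
    tf_name <- if (length(tokens) >= 2) paste(tokens[-1], collapse = " ") else motif_id
    rows <- lapply(seq_along(body), function(i) {
      ln <- gsub("[][]", " ", body[i])
      # strip an optional leading base letter
      ln <- sub("^\\s*[ACGTacgt]\\s+", " ", paste0(" ", ln))
      vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      if (any(is.na(vals)) || length(vals) == 0L) {
        stop("unparseable count row for motif ", motif_id,
             " (line ", idx[bounds[k] + i], "): '", body[i], "'")
      }
      vals
    })
    ncols <- vapply(rows, length, integer(1))
    if (length(unique(ncols)) != 1L) {
      stop("motif ", motif_id, ": rows have unequal column counts (",
           paste(ncols, collapse = ", "), ")")
    }
    pfm <- do.call(rbind, rows)
    rownames(pfm) <- DNA_BASES
    profiles[[k]] <- new_motif_profile(motif_id, tf_name, pfm,
                                       pseudocount, background)
  }
  profiles
}

new_motif_profile <- function(motif_id, tf_name, pfm, pseudocount, background) {
  if (any(pfm < 0)) stop("motif ", motif_id, ": negative counts in PFM")
  if (any(colSums(pfm) <= 0)) {
    stop("motif ", motif_id, ": a column has zero total count")
  }
  w <- pfm_to_pwm(pfm, pseudocount = pseudocount, background = background)
  structure(
    list(motif_id = motif_id, tf_name = tf_name, pfm = pfm,
         pwm = w$pwm, pseudocount = pseudocount, background = background,
         score_min = w$score_min, score_max = w$score_max),
    class = "motif_profile")
}

#' Convert a position frequency matrix to a log-odds weight matrix
#'
#' Each weight is
#' `log2((count + pseudocount * background) / (column_total + pseudocount) /
#' background)`, the usual JASPAR-style log2-odds with the pseudocount
#' distributed by background frequency. The minimum and maximum attainable
#' window scores are the sums of per-column minima and maxima.
#'
#' @param pfm 4 x L matrix of non-negative counts, rows A, C, G, T.
#' @param pseudocount Positive pseudocount.
#' @param background Four background probabilities summing to 1.
#' @return A list with `pwm` (4 x L numeric), `score_min` and `score_max`.
#' @export
pfm_to_pwm <- function(pfm, pseudocount = 1.0, background = rep(0.25, 4)) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0) {
    stop("pseudocount must be a single positive number")
  }
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9) {
    stop("background must be 4 positive probabilities summing to 1")
  }
  pfm <- as.matrix(pfm)
  if (nrow(pfm) != 4L) stop("pfm must have 4 rows (A, C, G, T)")
  colsum <- colSums(pfm)
  p <- (pfm + pseudocount * background) / rep(colsum + pseudocount, each = 4L)
  pwm <- log2(p / background)
  dimnames(pwm) <- list(DNA_BASES, NULL)
  list(pwm = pwm,
       score_min = sum(apply(pwm, 2L, min)),
       score_max = sum(apply(pwm, 2L, max)))
}

#' @export
print.motif_profile <- function(x, ...) {
  cat("<motif_profile> ", x$motif_id, " (", x$tf_name, "), length ",
      ncol(x$pfm), " bp\n", sep = "")
  cat("  consensus:", consensus_string(x), "\n")
  cat(sprintf("  score range: [%.3f, %.3f]\n", x$score_min, x$score_max))
  invisible(x)
}

consensus_string <- function(profile) {
  paste(DNA_BASES[apply(profile$pwm, 2L, which.max)], collapse = "")
}

## Integer encoding of a DNA string: A=1 C=2 G=3 T=4, N (or other) = NA.
encode_dna <- function(bases) {
  m <- match(strsplit(toupper(bases), "")[[1]], DNA_BASES)
  m
}

#' Reverse complement of a DNA string
#'
#' @param bases DNA string over A, C, G, T, N (case-insensitive).
#' @return The reverse complement, upper case.
#' @export
revcomp <- function(bases) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(bases))))
}

#' Score one window against a weight matrix
#'
#' The raw score is the sum of per-column log2-odds weights of the window's
#' bases; on the minus strand the reverse complement of the window is read.
#' An N base contributes the column minimum, so degenerate sequence can only
#' lose hits. The relative score rescales the raw score to [0, 1] between
#' the matrix's minimum and maximum attainable scores.
#'
#' @param profile A `motif_profile`.
#' @param window DNA string whose length equals the motif length.
#' @param strand `"+"` or `"-"`.
#' @return List with `raw_score` and `relative_score`.
#' @export
score_window <- function(profile, window, strand = "+") {
  L <- ncol(profile$pwm)
  if (nchar(window) != L) {
    stop("window length ", nchar(window), " != motif length ", L)
  }
  if (strand == "-") window <- revcomp(window)
  idx <- encode_dna(window)
  colmin <- apply(profile$pwm, 2L, min)
  v <- profile$pwm[cbind(idx, seq_len(L))]
  v[is.na(idx)] <- colmin[is.na(idx)]
  raw <- sum(v)
  list(raw_score = raw,
       relative_score = (raw - profile$score_min) /
         (profile$score_max - profile$score_min))
}

## Vectorised forward-strand scoring of every window of one profile.
## Returns raw scores for starts 1 .. n-L+1 (1-based); N scores column min.
scan_forward <- function(pwm, enc) {
  L <- ncol(pwm)
  n <- length(enc)
  nw <- n - L + 1L
  if (nw < 1L) return(numeric(0))
  colmin <- apply(pwm, 2L, min)
  acc <- numeric(nw)
  for (j in seq_len(L)) {
    idx <- enc[seq_len(nw) + j - 1L]
    v <- pwm[cbind(idx, rep.int(j, nw))]
    v[is.na(idx)] <- colmin[j]
    acc <- acc + v
  }
  acc
}

#' Scan a sequence for motif occurrences on both strands
#'
#' Every window of every profile, on both strands, whose relative score
#' reaches `relative_threshold` is reported once. Coordinates are 0-based,
#' half-open, anchored on the forward strand for hits on either strand.
#'
#' @param seq A DNA string, or a named length-1 character vector (the name
#'   becomes `seq_id`).
#' @param profiles List of `motif_profile` objects.
#' @param relative_threshold Minimum relative score in [0, 1]; a window is a
#'   hit when its relative score is `>=` this value. Default 0.80, the
#'   JASPAR SCAN convention used for the TFBS density statistic.
#' @param seq_id Identifier recorded in the hit table.
#' @return A data.frame of hits sorted by (start, motif_id, strand):
#'   `seq_id`, `motif_id`, `tf_name`, `start`, `end`, `strand`,
#'   `raw_score`, `relative_score`.
#' @export
scan_sequence <- function(seq, profiles, relative_threshold = 0.80,
                          seq_id = NULL) {
  if (is.null(seq_id)) {
    seq_id <- if (!is.null(names(seq))) names(seq)[1] else "seq"
  }
  seq <- toupper(as.character(seq)[1])
  if (length(profiles) == 0L) stop("empty profile list")
  if (inherits(profiles, "motif_profile")) profiles <- list(profiles)
  if (relative_threshold < 0 || relative_threshold > 1) {
    stop("relative_threshold must be in [0, 1]")
  }
  enc_f <- encode_dna(seq)
  enc_r <- encode_dna(revcomp(seq))
  n <- length(enc_f)
  out <- list()
  for (p in profiles) {
    L <- ncol(p$pwm)
    span <- p$score_max - p$score_min
    for (str in c("+", "-")) {
      raw <- scan_forward(p$pwm, if (str == "+") enc_f else enc_r)
      if (!length(raw)) next
      rel <- (raw - p$score_min) / span
      hit <- which(rel >= relative_threshold)
      if (!length(hit)) next
      # minus-strand windows were found on the reverse complement; map the
      # start back to forward coordinates: fwd_start0 = n - rev_start0 - L
      start0 <- if (str == "+") hit - 1L else n - (hit - 1L) - L
      out[[length(out) + 1L]] <- data.frame(
        seq_id = seq_id, motif_id = p$motif_id, tf_name = p$tf_name,
        start = start0, end = start0 + L, strand = str,
        raw_score = raw[hit], relative_score = rel[hit],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_hits(seq_id))
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$start, hits$motif_id,
                     match(hits$strand, c("+", "-"))), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function(seq_id = character(0)) {
  data.frame(seq_id = character(0), motif_id = character(0),
             tf_name = character(0), start = integer(0), end = integer(0),
             strand = character(0), raw_score = numeric(0),
             relative_score = numeric(0), stringsAsFactors = FALSE)
}

#' Scan every record of a FASTA file
#'
#' @param fasta Path to a (multi-record) FASTA file.
#' @inheritParams scan_sequence
#' @return One combined hit data.frame; records are scanned in file order.
#' @export
scan_fasta <- function(fasta, profiles, relative_threshold = 0.80) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  out <- lapply(seq_along(seqs), function(i) {
    scan_sequence(as.character(seqs[[i]]), profiles, relative_threshold,
                  seq_id = sub("\\s.*$", "", names(seqs)[i]))
  })
  do.call(rbind, out)
}
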