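# Independent brute-force oracles used to cross-check the implementation.

# Exhaustive double-strand window enumeration: scores every window of every
# profile with score_window() one at a time, keeps those at or above the
# relative threshold, and sorts like scan_sequence().
oracle_scan <- function(seq, profiles, relative_threshold = 0.80,
                        seq_id = "seq") {
  seq <- toupper(seq)
  n <- nchar(seq)
  rows <- list()
  for (p in profiles) {
    L <- ncol(p$pwm)
    if (n < L) next
    for (s0 in 0:(n - L)) {
      win <- substr(seq, s0 + 1, s0 + L)
      for (str in c("+", "-")) {
        sc <- score_window(p, win, str)
        if (sc$relative_score >= relative_threshold) {
          rows[[length(rows) + 1]] <- data.frame(
            seq_id = seq_id, motif_id = p$motif_id, tf_name = p$tf_name,
            start = s0, end = s0 + L, strand = str,
            raw_score = sc$raw_score, relative_score = sc$relative_score,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(seq_id = character(0), motif_id = character(0),
                      tf_name = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      raw_score = numeric(0), relative_score = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$motif_id,
                   match(out$strand, c("+", "-"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Literal left-to-right re-simulation of the anchor-based greedy merge rule.
oracle_merge <- function(starts, window = 5) {
  starts <- sort(starts)
  if (!length(starts)) return(0L)
  count <- 0L
  anchor <- -Inf
  for (x in starts) {
    if (x - anchor > window) {
      count <- count + 1L
      anchor <- x
    }
  }
  count
}

# Exhaustive two-sided rank-sum p-value by enumerating every split of the
# pooled sample, with average ranks for ties (2 * min tail, capped at 1).
oracle_ranksum <- function(a, b) {
  pooled <- c(a, b)
  rk <- rank(pooled)
  na <- length(a)
  obs <- sum(rk[seq_len(na)])
  ws <- apply(utils::combn(length(pooled), na), 2, function(ix) sum(rk[ix]))
  eps <- 1e-9
  min(1, 2 * min(mean(ws <= obs + eps), mean(ws >= obs - eps)))
}

# All permutations of 1..n as rows of a matrix (n small).
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# A small mixed-sharpness toy panel for scan tests.
toy_panel <- function() {
  list(make_profile("ACGTAC", 0.85, motif_id = "TOY1"),
       make_profile("TTGACA", 0.9, motif_id = "TOY2"))
}

# Triangular test signal: tip `tv` at `tip_pos`, dropping by `slope` per bp.
triangle_track <- function(n, tip_pos, tv, slope, chrom = "chr1") {
  pos <- seq_len(n) - 1
  coverage_track(pmax(0, tv - slope * abs(pos - tip_pos)), chrom = chrom)
}
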