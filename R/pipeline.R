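#' Run the CRM density prescreen end to end
#'
#' Reads candidate sequences and a TF motif panel, computes each
#' candidate's TFBS density profile at the two raw-score thresholds, calls
#' quadrants, and writes the per-candidate table, a two-column scatter
#' table (the density plot's coordinates), and a run manifest. Outputs are
#' a deterministic function of the inputs and configuration: rerunning
#' with identical inputs reproduces identical bytes.
#'
#' @param fasta Candidate CRM FASTA (record ids become `crm_id`).
#' @param pfm JASPAR-format PFM file with the TF panel.
#' @param out_dir Output directory (created if needed).
#' @param cfg A [classifier_config()].
#' @param mask Passed to [tfbs_density()] (`NULL` = auto tandem-repeat
#'   mask).
#' @return Invisibly, the density data.frame; files written:
#'   `density.tsv`, `scatter.tsv`, `manifest.txt`.
#' @export
crm_prescreen <- function(fasta, pfm, out_dir, cfg = classifier_config(),
                          mask = NULL) {
  if (!file.exists(fasta)) {
    stop("candidate FASTA not found: ", fasta)
  }
  if (!file.exists(pfm)) {
    stop("TF panel PFM not found: ", pfm,
         " (produce one with write_jaspar_pfm() or select_tfs())")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  profiles <- load_jaspar_pfm(pfm)
  dens <- density_table(fasta, profiles, cfg, mask)
  hdr <- config_header(cfg)
  dens_path <- file.path(out_dir, "density.tsv")
  write_tsv_with_header(format_density(dens), dens_path, hdr)
  scat_path <- file.path(out_dir, "scatter.tsv")
  scat <- data.frame(crm_id = dens$crm_id,
                     density_low = sprintf("%.6g", dens$density_low),
                     density_high = sprintf("%.6g", dens$density_high))
  write_tsv_with_header(scat, scat_path, hdr)
  manifest <- c(
    paste0("package_version\t", as.character(packageVersion("crmscan"))),
    paste0("n_candidates\t", nrow(dens)),
    paste0("n_profiles\t", length(profiles)),
    paste0("input_fasta_md5\t", unname(tools::md5sum(fasta))),
    paste0("input_pfm_md5\t", unname(tools::md5sum(pfm))),
    sub("^# ", "", hdr))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(dens)
}

config_header <- function(cfg) {
  vapply(names(unclass(cfg)), function(k) {
    paste0("# ", k, "=", format(cfg[[k]]))
  }, character(1))
}

format_density <- function(dens) {
  data.frame(crm_id = dens$crm_id, length_bp = dens$length_bp,
             count_low = dens$count_low, count_high = dens$count_high,
             density_low = sprintf("%.6g", dens$density_low),
             density_high = sprintf("%.6g", dens$density_high),
             quadrant = dens$quadrant,
             predicted_active = dens$predicted_active,
             stringsAsFactors = FALSE)
}

write_tsv_with_header <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write motif hits as TSV and optionally BED6
#'
#' @param hits Hit data.frame from [scan_sequence()]/[scan_fasta()].
#' @param tsv Output TSV path, or `NULL`.
#' @param bed Output BED6 path (score column = `round(100 * relative)`), or
#'   `NULL`.
#' @return `hits`, invisibly.
#' @export
write_hits <- function(hits, tsv = NULL, bed = NULL) {
  if (!is.null(tsv)) {
    out <- hits
    out$raw_score <- sprintf("%.6g", out$raw_score)
    out$relative_score <- sprintf("%.6g", out$relative_score)
    write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bed)) {
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", hits$seq_id, hits$start,
                       hits$end, hits$motif_id,
                       as.integer(round(100 * hits$relative_score)),
                       hits$strand), bed)
  }
  invisible(hits)
}
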