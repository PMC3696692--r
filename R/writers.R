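# Tabular output writers shared by the pipeline and by interactive use.

#' Write a distance trace as CSV (frame, time, value)
#' @param trace a `DistanceTrace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_trace_csv <- function(trace, path) {
  df <- data.frame(frame = trace$frame_index,
                   time_ns = if (is.null(trace$time)) NA_real_ else trace$time,
                   distance_A = trace$d)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a distance histogram as TSV (bin_lo, bin_hi, p)
#' @param hist a `DistanceHistogram`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_histogram_tsv <- function(hist, path) {
  df <- data.frame(bin_lo = head(hist$bin_edges, -1),
                   bin_hi = hist$bin_edges[-1],
                   p = hist$p)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write theoretical B-factors as CSV
#' @param bf a `TheoreticalBFactors` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bfactor_csv <- function(bf, path) {
  write.csv(as.data.frame(bf), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write hydrogen-bond occupancies and defect calls as CSV
#'
#' The geometric criterion used is echoed as comment header lines.
#' @param defects a `HelixDefectMap` (or `HBondOccupancyMap`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occupancy_csv <- function(defects, path) {
  crit <- attr(defects, "criterion")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(crit))
    writeLines(sprintf("# criterion: d(N,O) <= %.2f A%s", crit$d_NO_max,
                       if (crit$use_hydrogens)
                         sprintf(", N-H...O >= %.0f deg", crit$angle_min) else ""), con)
  thr <- attr(defects, "threshold_absent")
  if (!is.null(thr)) writeLines(sprintf("# defect: absent > %.0f%% of frames", 100 * thr), con)
  write.csv(as.data.frame(defects), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a distance distribution as TSV with a JSON sidecar
#'
#' @param result a `TikhonovResult`.
#' @param path output TSV path (`r_nm`, `p`); the sidecar
#'   `<path>.json` records alpha, residual, penalty and modulation depth.
#' @return `path`, invisibly.
#' @export
write_pr_tsv <- function(result, path) {
  df <- data.frame(r_nm = result$p_hat$r, p = result$p_hat$p)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- list(alpha = result$alpha, residual_norm = result$residual_norm,
               penalty_norm = result$penalty_norm, lambda = result$lambda_est)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
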