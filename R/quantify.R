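#' Quantify one ASE reaction from a trace
#'
#' Runs the full measurement chain on one electropherogram: peak detection
#' and integration, ladder sizing of the apexes, assignment of the detected
#' peaks to the ASE's expected inclusion/exclusion amplicons, molar
#' correction, and psi. Peaks beyond the two catalog amplicons are ignored
#' for psi and counted in `n_extra_peaks`.
#'
#' @param trace a `ce_trace`.
#' @param ase one catalog row.
#' @param calibration a `size_calibration` from [calibrate_ladder()].
#' @param min_height,min_separation passed to [detect_peaks()].
#' @param rel_tol passed to [assign_amplicons()].
#' @param min_total passed to [compute_psi()].
#' @return one-row data.frame `ase_id`, `cell_line`, `condition`,
#'   `batch_day`, `psi`, `inclusion_molar`, `exclusion_molar`,
#'   `n_extra_peaks`.
#' @export
quantify_trace <- function(trace, ase, calibration, min_height = 50,
                           min_separation = 0.5, rel_tol = 0.10, min_total = 0) {
  peaks <- detect_peaks(trace, min_height = min_height,
                        min_separation = min_separation)
  peaks$called_size_bp <- if (nrow(peaks)) calibration$size_of(peaks$apex_time)
                          else numeric(0)
  slots <- assign_amplicons(peaks, ase, rel_tol = rel_tol)
  inc <- quantify_molar(slots$inclusion)
  exc <- quantify_molar(slots$exclusion)
  n_extra <- nrow(peaks) - sum(!is.null(slots$inclusion), !is.null(slots$exclusion))
  md <- trace$metadata
  data.frame(ase_id = ase$ase_id, cell_line = md$cell_line,
             condition = md$condition, batch_day = md$batch_day,
             psi = compute_psi(inc, exc, min_total = min_total),
             inclusion_molar = inc, exclusion_molar = exc,
             n_extra_peaks = n_extra, stringsAsFactors = FALSE)
}

#' Quantify every sample of a simulated or loaded screen
#'
#' Dispatches on what the screen carries: rendered traces go through
#' [quantify_trace()] (detection, sizing, assignment); a pre-quantified peak
#' table skips detection and goes straight to assignment and molar
#' correction.
#'
#' @param screen a `sim_screen`, or a list with `samples`, `catalog` and
#'   either `traces` or `peaks` (see [simulate_screen()] for the schemas).
#' @inheritParams quantify_trace
#' @return data.frame of psi records (one row per sample x ASE) with columns
#'   `ase_id`, `cell_line`, `condition`, `batch_day`, `psi`,
#'   `inclusion_molar`, `exclusion_molar`, `n_extra_peaks`.
#' @export
quantify_screen <- function(screen, min_height = 50, min_separation = 0.5,
                            rel_tol = 0.10, min_total = 0) {
  catalog <- screen$catalog
  if (!is.null(screen$traces)) {
    calibration <- calibrate_ladder(screen$ladder)
    rows <- lapply(screen$traces, function(tr) {
      ase <- catalog[catalog$ase_id == tr$metadata$ase_id, , drop = FALSE]
      quantify_trace(tr, ase, calibration, min_height = min_height,
                     min_separation = min_separation, rel_tol = rel_tol,
                     min_total = min_total)
    })
  } else if (!is.null(screen$peaks)) {
    samples <- screen$samples
    pk <- screen$peaks
    grp <- split(seq_len(nrow(pk)), list(pk$sample_id, pk$ase_id), drop = TRUE)
    rows <- lapply(grp, function(idx) {
      sub <- pk[idx, , drop = FALSE]
      ase <- catalog[catalog$ase_id == sub$ase_id[1L], , drop = FALSE]
      slots <- assign_amplicons(sub, ase, rel_tol = rel_tol)
      inc <- quantify_molar(slots$inclusion)
      exc <- quantify_molar(slots$exclusion)
      s <- samples[samples$sample_id == sub$sample_id[1L], , drop = FALSE]
      data.frame(ase_id = ase$ase_id, cell_line = s$cell_line,
                 condition = s$condition, batch_day = s$batch_day,
                 psi = compute_psi(inc, exc, min_total = min_total),
                 inclusion_molar = inc, exclusion_molar = exc,
                 n_extra_peaks = nrow(sub) - sum(!is.null(slots$inclusion),
                                                 !is.null(slots$exclusion)),
                 stringsAsFactors = FALSE)
    })
  } else {
    stop("screen carries neither traces nor a peak table", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$ase_id, out$cell_line, out$batch_day, out$condition), ]
  rownames(out) <- NULL
  out
}
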