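#' Calibrate a DNA sizing ladder
#'
#' Fits the standard log-linear migration model: piecewise-linear
#' interpolation of log10(size) against migration time through the ladder
#' points. The fitted map is exact at every ladder point and strictly
#' increasing over the ladder range. Evaluation outside the range
#' extrapolates the terminal segment's slope and warns.
#'
#' @param ladder_peaks data.frame with columns `time` and `size_bp`, both
#'   strictly increasing, at least two rows.
#' @return A `size_calibration`: list with the ladder and a vectorized
#'   `size_of(time)` function.
#' @export
calibrate_ladder <- function(ladder_peaks) {
  if (!is.data.frame(ladder_peaks) || !all(c("time", "size_bp") %in% names(ladder_peaks)))
    stop("ladder_peaks must have columns time and size_bp", call. = FALSE)
  tt <- ladder_peaks$time
  ss <- ladder_peaks$size_bp
  if (length(tt) < 2L)
    stop("at least two ladder points are required", call. = FALSE)
  if (any(diff(tt) <= 0) || any(diff(ss) <= 0))
    stop("ladder times and sizes must be strictly increasing", call. = FALSE)
  ls <- log10(ss)
  size_of <- function(time) {
    out <- numeric(length(time))
    inside <- time >= tt[1] & time <= tt[length(tt)]
    if (any(!inside, na.rm = TRUE))
      warning("evaluating size calibration outside the ladder range; ",
              "extrapolating from the terminal segment", call. = FALSE)
    out[inside] <- stats::approx(tt, ls, xout = time[inside], ties = "ordered")$y
    lo <- which(time < tt[1])
    if (length(lo)) {
      slope <- (ls[2] - ls[1]) / (tt[2] - tt[1])
      out[lo] <- ls[1] + slope * (time[lo] - tt[1])
    }
    hi <- which(time > tt[length(tt)])
    if (length(hi)) {
      k <- length(tt)
      slope <- (ls[k] - ls[k - 1]) / (tt[k] - tt[k - 1])
      out[hi] <- ls[k] + slope * (time[hi] - tt[k])
    }
    10^out
  }
  structure(list(ladder = ladder_peaks, size_of = size_of),
            class = "size_calibration")
}

#' Detect and integrate peaks in an electropherogram trace
#'
#' A constant baseline offset (the trace's 5th signal percentile) is
#' subtracted, then peaks are local maxima of the corrected signal above
#' `min_height`. Candidates closer than `min_separation` are merged, keeping
#' the taller apex. Each retained peak is integrated by the trapezoid rule
#' between its flanking valleys (the signal minima separating it from its
#' neighbours, or the trace ends).
#'
#' @param trace a `ce_trace` or list with numeric `time` (strictly
#'   increasing) and `signal` of equal length.
#' @param min_height minimum apex height above baseline, signal units.
#' @param min_separation minimum apex spacing, time units.
#' @return data.frame `apex_time`, `height`, `area`, sorted by `apex_time`;
#'   zero rows when nothing exceeds `min_height`.
#' @export
detect_peaks <- function(trace, min_height = 50, min_separation = 0.5) {
  tt <- trace$time
  y <- trace$signal
  if (is.null(tt) || is.null(y) || length(tt) == 0L)
    stop("trace is empty", call. = FALSE)
  if (length(tt) != length(y))
    stop("trace time and signal lengths differ", call. = FALSE)
  if (any(diff(tt) <= 0))
    stop("trace time must be strictly increasing", call. = FALSE)
  y <- y - stats::quantile(y, 0.05, names = FALSE)

  n <- length(y)
  empty <- data.frame(apex_time = numeric(0), height = numeric(0), area = numeric(0))
  if (n < 3L) return(empty)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  cand <- which(is_max & y >= min_height)
  if (!length(cand)) return(empty)

  # merge: keep taller apex when two candidates are closer than min_separation
  keep <- integer(0)
  for (i in cand[order(-y[cand], tt[cand])]) {
    if (!length(keep) || all(abs(tt[i] - tt[keep]) >= min_separation))
      keep <- c(keep, i)
  }
  keep <- sort(keep)

  # valley-to-valley bounds: minimum of the corrected signal between apexes
  bounds <- c(1L, vapply(seq_len(length(keep) - 1L), function(j) {
    seg <- keep[j]:keep[j + 1L]
    seg[which.min(y[seg])]
  }, integer(1)), n)
  areas <- vapply(seq_along(keep), function(j) {
    seg <- bounds[j]:bounds[j + 1L]
    trapz_area(tt[seg], y[seg])
  }, numeric(1))
  data.frame(apex_time = tt[keep], height = y[keep], area = areas)
}

# internal: trapezoid rule
trapz_area <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Assign detected peaks to an ASE's expected amplicons
#'
#' Each detected peak is considered only for the expected amplicon (inclusion
#' or exclusion) whose size is nearest its called size, so no peak can fill
#' both slots. Within a slot the match must lie within `rel_tol` relative
#' size error; the nearest in-window peak wins, with ties on size distance
#' broken by larger area. Configuration is rejected when one expected size
#' falls inside the other's tolerance window (assignment would be ambiguous).
#'
#' @param peaks data.frame with `called_size_bp` and `area`.
#' @param ase one catalog row (see [generate_ase_catalog()]).
#' @param rel_tol relative size tolerance, 0 < rel_tol < 0.5.
#' @return list with `inclusion` and `exclusion`, each a one-row data.frame
#'   from `peaks` or `NULL` when unmatched.
#' @export
assign_amplicons <- function(peaks, ase, rel_tol = 0.10) {
  stopifnot(rel_tol > 0, rel_tol < 0.5)
  e_inc <- ase$size_inclusion_bp
  e_exc <- ase$size_exclusion_bp
  if (abs(e_inc - e_exc) <= rel_tol * max(e_inc, e_exc))
    stop("expected amplicon sizes ", e_exc, "/", e_inc,
         " are within rel_tol of each other; assignment would be ambiguous",
         call. = FALSE)
  match_slot <- function(expected, other) {
    if (is.null(peaks) || nrow(peaks) == 0L) return(NULL)
    d_own <- abs(peaks$called_size_bp - expected)
    d_other <- abs(peaks$called_size_bp - other)
    ok <- d_own <= d_other & d_own <= rel_tol * expected
    if (!any(ok)) return(NULL)
    idx <- which(ok)
    idx <- idx[order(d_own[idx], -peaks$area[idx])]
    peaks[idx[1L], , drop = FALSE]
  }
  list(inclusion = match_slot(e_inc, e_exc),
       exclusion = match_slot(e_exc, e_inc))
}

#' Molar correction of a peak
#'
#' Fluorescence of an intercalating dye is mass-proportional, so a peak's
#' area over-weights long fragments. Dividing by the called fragment length
#' gives a quantity proportional to molecule count.
#'
#' @param peak one-row data.frame (or list) with `area` and `called_size_bp`.
#' @return numeric molar amount, `area / called_size_bp`.
#' @export
quantify_molar <- function(peak) {
  if (is.null(peak)) return(NA_real_)
  size <- peak$called_size_bp
  if (any(!is.finite(size)) || any(size <= 0))
    stop("called_size_bp must be positive", call. = FALSE)
  peak$area / size
}
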