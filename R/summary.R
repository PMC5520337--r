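#' Format a count pair as the percentage a screen report prints
#'
#' Two reporting conventions are supported: nearest integer with halves
#' rounded up (the default; 28/96 prints as "29"), and truncation to one
#' decimal place (11/14 prints as "78.5"). The raw fraction is what every
#' computation uses; formatting applies only to reports.
#'
#' @param k,n numerator and denominator counts.
#' @param mode `"integer"` (round half up) or `"truncate1"`.
#' @return character vector of formatted percentages (no "%" sign).
#' @export
format_percent <- function(k, n, mode = c("integer", "truncate1")) {
  mode <- match.arg(mode)
  pct <- 100 * k / n
  if (mode == "integer") sprintf("%d", as.integer(floor(pct + 0.5)))
  else sprintf("%.1f", floor(pct * 10) / 10)
}

#' Summarize a screen's change calls
#'
#' Counts of changed ASEs overall and per cell line, the consensus
#' multiplicity histogram (how many ASEs changed in exactly k cell lines),
#' and the inclusion/exclusion split among change events, with both raw
#' fractions and report-formatted percentages.
#'
#' @param calls data.frame from [call_changes()].
#' @param n_ases total number of ASEs assayed (>= number of distinct
#'   `ase_id` values in `calls`).
#' @return list of class `screen_summary`: `n_ases`, `n_changed_any`,
#'   `pct_changed_any`, `per_cell_line` (named changed counts),
#'   `multiplicity` (named integer vector over k = 1..n cell lines),
#'   `direction_counts` (inclusion/exclusion event counts),
#'   `pct_inclusion_events`, `formatted` (printed strings).
#' @export
summarize_screen <- function(calls, n_ases) {
  n_distinct <- length(unique(calls$ase_id))
  if (n_ases < n_distinct)
    stop("n_ases (", n_ases, ") is smaller than the number of distinct ASEs ",
         "in the calls (", n_distinct, ")", call. = FALSE)
  cell_lines <- sort(unique(calls$cell_line))
  changed <- calls[calls$changed, , drop = FALSE]
  per_line <- vapply(cell_lines, function(cl) sum(changed$cell_line == cl), integer(1))
  mult_of_ase <- table(factor(changed$ase_id))
  multiplicity <- vapply(seq_along(cell_lines),
                         function(k) sum(mult_of_ase == k), integer(1))
  names(multiplicity) <- seq_along(cell_lines)
  n_changed_any <- length(unique(changed$ase_id))
  dir_counts <- c(inclusion = sum(changed$direction == "inclusion"),
                  exclusion = sum(changed$direction == "exclusion"))
  n_events <- sum(dir_counts)
  structure(list(
    n_ases = n_ases,
    n_changed_any = n_changed_any,
    pct_changed_any = 100 * n_changed_any / n_ases,
    per_cell_line = per_line,
    multiplicity = multiplicity,
    direction_counts = dir_counts,
    pct_inclusion_events = if (n_events > 0) 100 * dir_counts[["inclusion"]] / n_events
                           else NA_real_,
    formatted = list(
      changed_any = format_percent(n_changed_any, n_ases),
      inclusion_events = if (n_events > 0) format_percent(dir_counts[["inclusion"]], n_events)
                         else NA_character_
    )
  ), class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf("Screen summary: %d/%d ASEs (%s%%) changed in >= 1 cell line\n",
              x$n_changed_any, x$n_ases, x$formatted$changed_any))
  cat("  changed per cell line: ",
      paste(sprintf("%s=%d", names(x$per_cell_line), x$per_cell_line),
            collapse = ", "), "\n", sep = "")
  cat("  multiplicity (changed in exactly k lines): ",
      paste(sprintf("k=%s:%d", names(x$multiplicity), x$multiplicity),
            collapse = ", "), "\n", sep = "")
  if (!is.na(x$pct_inclusion_events))
    cat(sprintf("  direction: %d inclusion / %d exclusion events (%s%% inclusion)\n",
                x$direction_counts[["inclusion"]], x$direction_counts[["exclusion"]],
                x$formatted$inclusion_events))
  invisible(x)
}

#' Consensus multiplicity distribution of change calls
#'
#' For k = 1..(number of cell lines), which ASEs changed in exactly k cell
#' lines, and cumulatively in at least k.
#'
#' @param calls data.frame from [call_changes()] covering >= 2 cell lines.
#' @return list: `histogram` (named counts, exactly-k), `exactly`
#'   (list of ASE id vectors per k), `at_least` (cumulative lists).
#' @export
consensus_distribution <- function(calls) {
  cell_lines <- unique(calls$cell_line)
  if (length(cell_lines) < 2L)
    stop("consensus distribution needs calls from >= 2 cell lines", call. = FALSE)
  changed <- calls[calls$changed, , drop = FALSE]
  n_lines <- length(cell_lines)
  mult <- table(factor(changed$ase_id))
  exactly <- lapply(seq_len(n_lines), function(k) sort(names(mult)[mult == k]))
  at_least <- lapply(seq_len(n_lines), function(k) sort(names(mult)[mult >= k]))
  names(exactly) <- names(at_least) <- seq_len(n_lines)
  list(histogram = vapply(exactly, length, integer(1)),
       exactly = exactly, at_least = at_least)
}
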