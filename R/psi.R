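#' Percent splicing index from molar amounts
#'
#' psi is the molar percentage of the inclusion isoform:
#' `100 * inclusion / (inclusion + exclusion)`. The index is missing (NA)
#' when both amounts are missing or the total molar amount falls below
#' `min_total` (too little product to quantify). A single missing slot is
#' treated as zero amount only when the other slot alone exceeds `min_total`.
#'
#' @param inclusion_molar,exclusion_molar non-negative molar amounts
#'   (vectorized; NA = amplicon not detected).
#' @param min_total molar floor below which psi is not reported.
#' @return numeric vector of psi in \[0, 100\], NA where not quantifiable.
#' @export
compute_psi <- function(inclusion_molar, exclusion_molar, min_total = 0) {
  if (any(inclusion_molar < 0, na.rm = TRUE) || any(exclusion_molar < 0, na.rm = TRUE))
    stop("molar amounts must be non-negative", call. = FALSE)
  n <- max(length(inclusion_molar), length(exclusion_molar))
  inc <- rep_len(inclusion_molar, n)
  exc <- rep_len(exclusion_molar, n)
  both_na <- is.na(inc) & is.na(exc)
  one_na <- xor(is.na(inc), is.na(exc))
  other <- ifelse(is.na(inc), exc, inc)
  rescue <- one_na & !is.na(other) & other >= min_total & other > 0
  # a lone detected amplicon counts as a pure isoform only above the floor
  inc2 <- ifelse(is.na(inc) & rescue, 0, inc)
  exc2 <- ifelse(is.na(exc) & rescue, 0, exc)
  total <- inc2 + exc2
  psi <- ifelse(!is.na(total) & total >= min_total & total > 0,
                100 * inc2 / total, NA_real_)
  psi[both_na | (one_na & !rescue)] <- NA_real_
  psi
}

#' Same-day delta-psi of knockdown samples against mock controls
#'
#' For every siRNA psi record, delta-psi is that record's psi minus the psi
#' of the mock transfection of the same cell line performed on the same
#' batch day. Missing psi in either member propagates to a missing
#' delta-psi. Positive delta-psi means a shift toward exon inclusion.
#'
#' @param psi_records data.frame with columns `ase_id`, `cell_line`,
#'   `condition` (`"mock"`, `"siRNA1"`, `"siRNA2"`), `batch_day`, `psi`.
#' @return data.frame `ase_id`, `cell_line`, `sirna`, `batch_day`,
#'   `delta_psi`.
#' @export
compute_delta_psi <- function(psi_records) {
  required <- c("ase_id", "cell_line", "condition", "batch_day", "psi")
  missing_cols <- setdiff(required, names(psi_records))
  if (length(missing_cols))
    stop("psi_records is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  kd <- psi_records[psi_records$condition != "mock", , drop = FALSE]
  mock <- psi_records[psi_records$condition == "mock", , drop = FALSE]
  key <- function(d) paste(d$ase_id, d$cell_line, d$batch_day, sep = "\r")
  m <- match(key(kd), key(mock))
  if (anyNA(m)) {
    bad <- kd[which(is.na(m))[1L], ]
    stop(sprintf("no same-day mock for sample (%s, %s, day %s, %s)",
                 bad$ase_id, bad$cell_line, bad$batch_day, bad$condition),
         call. = FALSE)
  }
  out <- data.frame(ase_id = kd$ase_id, cell_line = kd$cell_line,
                    sirna = kd$condition, batch_day = kd$batch_day,
                    delta_psi = kd$psi - mock$psi[m],
                    stringsAsFactors = FALSE)
  out <- out[order(out$ase_id, out$cell_line, out$sirna), ]
  rownames(out) <- NULL
  out
}

#' Dual-siRNA change rule
#'
#' An ASE is called changed in a cell line when both independent siRNAs
#' shift psi by at least `threshold` percentage points (the threshold is
#' inclusive) in the same direction. Discordant responses (opposite signs)
#' are vetoed, as are pairs with a missing delta-psi. Under `lenient = TRUE`
#' only one siRNA must reach the threshold, but the signs must still agree
#' and both shifts be non-zero.
#'
#' @param dpsi1,dpsi2 signed delta-psi of siRNA1 and siRNA2 (vectorized).
#' @param threshold change threshold in psi percentage points (> 0).
#' @param lenient use the one-siRNA-over-threshold variant.
#' @return data.frame `changed` (logical), `direction` (`"inclusion"`,
#'   `"exclusion"` or `"none"`), `reason` (`"called"`, `"below_threshold"`,
#'   `"discordant"`, `"not_evaluable"`).
#' @export
call_change <- function(dpsi1, dpsi2, threshold = 8, lenient = FALSE) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("`threshold` must be a single positive number", call. = FALSE)
  n <- max(length(dpsi1), length(dpsi2))
  d1 <- rep_len(as.numeric(dpsi1), n)
  d2 <- rep_len(as.numeric(dpsi2), n)
  evaluable <- !is.na(d1) & !is.na(d2)
  concordant <- evaluable & sign(d1) == sign(d2) & sign(d1) != 0
  over <- if (lenient) pmax(abs(d1), abs(d2)) >= threshold
          else         pmin(abs(d1), abs(d2)) >= threshold
  changed <- concordant & !is.na(over) & over
  direction <- rep("none", n)
  direction[changed & d1 > 0] <- "inclusion"
  direction[changed & d1 < 0] <- "exclusion"
  reason <- rep("below_threshold", n)
  reason[!evaluable] <- "not_evaluable"
  reason[evaluable & !concordant] <- "discordant"
  reason[changed] <- "called"
  data.frame(changed = changed, direction = direction, reason = reason,
             stringsAsFactors = FALSE)
}

#' Apply the change rule across a screen
#'
#' Pairs the two per-siRNA delta-psi records of every (ASE, cell line) and
#' applies [call_change()]. An ASE with a missing delta-psi in either siRNA
#' is kept as not evaluable (`changed = FALSE`, reason `"not_evaluable"`).
#'
#' @param delta_records output of [compute_delta_psi()].
#' @inheritParams call_change
#' @return data.frame `ase_id`, `cell_line`, `dpsi1`, `dpsi2`, `changed`,
#'   `direction`, `reason`.
#' @export
call_changes <- function(delta_records, threshold = 8, lenient = FALSE) {
  d1 <- delta_records[delta_records$sirna == "siRNA1", , drop = FALSE]
  d2 <- delta_records[delta_records$sirna == "siRNA2", , drop = FALSE]
  key <- function(d) paste(d$ase_id, d$cell_line, sep = "\r")
  all_keys <- unique(key(delta_records))
  wide <- data.frame(
    ase_id = sub("\r.*", "", all_keys),
    cell_line = sub(".*\r", "", all_keys),
    dpsi1 = d1$delta_psi[match(all_keys, key(d1))],
    dpsi2 = d2$delta_psi[match(all_keys, key(d2))],
    stringsAsFactors = FALSE
  )
  cc <- call_change(wide$dpsi1, wide$dpsi2, threshold = threshold, lenient = lenient)
  out <- cbind(wide, cc)
  out <- out[order(out$ase_id, out$cell_line), ]
  rownames(out) <- NULL
  out
}
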