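#' Plant ground-truth splicing effects for a simulated knockdown screen
#'
#' Builds the truth table the simulator renders into electropherograms: a
#' baseline percent splicing index (psi, percent of the inclusion isoform)
#' per (ASE, cell line), a signed knockdown effect on the psi scale for true
#' target ASEs, and per-siRNA knockdown fractions that scale the realized
#' shift. A true target keeps one direction (inclusion or exclusion) across
#' every cell line in which it responds; a configurable fraction of non-null
#' ASEs respond with opposite sign in the two siRNAs and must later be vetoed
#' by the concordance rule.
#'
#' @param catalog ASE catalog from [generate_ase_catalog()].
#' @param cell_lines character vector of cell line names; must all appear in
#'   `kd_table`.
#' @param prop_null fraction of ASEs with no planted effect anywhere.
#' @param effect_dist list with `mean_abs` and `sd`: the absolute planted
#'   effect (percentage points of psi) is drawn from |N(mean_abs, sd)|.
#' @param kd_table data.frame with columns `cell_line`, `sirna`,
#'   `kd_fraction`; exactly two siRNA rows per cell line
#'   (default [rbm10_kd_table()]).
#' @param discordant_rate fraction of non-null ASEs whose two siRNAs shift
#'   psi in opposite directions.
#' @param respond_prob probability that a non-null ASE responds in a given
#'   cell line (responses in a subset of lines reproduce the consensus
#'   multiplicity structure of the screens).
#' @param baseline_range range of the uniform baseline psi draw (percent).
#' @param seed integer seed.
#' @return An object of class `truth_table`: list with `effects` (data.frame
#'   `ase_id`, `gene`, `cell_line`, `baseline_psi`, `effect_dpsi`,
#'   `concordant`) and `kd` (the kd_table restricted to `cell_lines`).
#' @export
generate_truth <- function(catalog, cell_lines, prop_null = 0.5,
                           effect_dist = list(mean_abs = 20, sd = 5),
                           kd_table = rbm10_kd_table(),
                           discordant_rate = 0, respond_prob = 0.6,
                           baseline_range = c(20, 80), seed = NULL) {
  validate_catalog(catalog, min_size = 1L, max_size = .Machine$integer.max)
  stopifnot(prop_null >= 0, prop_null <= 1,
            discordant_rate >= 0, discordant_rate <= 1,
            respond_prob >= 0, respond_prob <= 1)
  validate_kd_table(kd_table, cell_lines)
  if (!is.null(seed)) set.seed(seed)

  n <- nrow(catalog)
  is_null <- stats::runif(n) < prop_null
  sign_ase <- sample(c(-1, 1), n, replace = TRUE)   # direction conserved per ASE
  concord <- is_null | (stats::runif(n) >= discordant_rate)

  eff <- expand.grid(ase_id = catalog$ase_id, cell_line = cell_lines,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- match(eff$ase_id, catalog$ase_id)
  eff$gene <- catalog$gene[idx]
  eff$baseline_psi <- stats::runif(nrow(eff), baseline_range[1], baseline_range[2])
  responds <- !is_null[idx] & stats::runif(nrow(eff)) < respond_prob
  mag <- abs(stats::rnorm(nrow(eff), effect_dist$mean_abs, effect_dist$sd))
  eff$effect_dpsi <- ifelse(responds, sign_ase[idx] * mag, 0)
  eff$concordant <- concord[idx]
  eff <- eff[order(match(eff$ase_id, catalog$ase_id), match(eff$cell_line, cell_lines)),
             c("ase_id", "gene", "cell_line", "baseline_psi", "effect_dpsi", "concordant")]
  rownames(eff) <- NULL

  kd <- kd_table[kd_table$cell_line %in% cell_lines, , drop = FALSE]
  rownames(kd) <- NULL
  structure(list(effects = eff, kd = kd), class = "truth_table")
}

validate_kd_table <- function(kd_table, cell_lines) {
  required <- c("cell_line", "sirna", "kd_fraction")
  if (!is.data.frame(kd_table) || !all(required %in% names(kd_table)))
    stop("kd_table must have columns cell_line, sirna, kd_fraction", call. = FALSE)
  if (any(kd_table$kd_fraction < 0 | kd_table$kd_fraction > 1))
    stop("kd_fraction values must lie in [0, 1]", call. = FALSE)
  for (cl in cell_lines) {
    sir <- kd_table$sirna[kd_table$cell_line == cl]
    if (!setequal(sir, c("siRNA1", "siRNA2")) || length(sir) != 2L)
      stop("kd_table must have exactly siRNA1 and siRNA2 rows for cell line '",
           cl, "'", call. = FALSE)
  }
  invisible(kd_table)
}

#' Realized per-siRNA effects implied by a truth table
#'
#' The realized shift for siRNA s in a cell line is
#' `effect_dpsi * kd_s / max(kd over the line's siRNAs)`, so the stronger
#' knockdown expresses the full planted effect and the weaker one a
#' proportionally smaller shift. For discordant ASEs the siRNA2 shift has its
#' sign flipped. The knocked-down psi is the baseline plus the realized shift,
#' clamped to \[0, 100\]; `realized_dpsi` is the post-clamp shift actually
#' observable on the psi scale.
#'
#' @param truth a `truth_table`.
#' @return data.frame `ase_id`, `cell_line`, `sirna`, `baseline_psi`,
#'   `psi_kd` (clamped), `realized_dpsi`.
#' @export
realized_effects <- function(truth) {
  stopifnot(inherits(truth, "truth_table"))
  kd <- truth$kd
  kd_max <- tapply(kd$kd_fraction, kd$cell_line, max)
  out <- merge(truth$effects, kd, by = "cell_line", sort = FALSE)
  scale <- out$kd_fraction / as.numeric(kd_max[out$cell_line])
  flip <- ifelse(!out$concordant & out$sirna == "siRNA2", -1, 1)
  raw <- out$effect_dpsi * scale * flip
  out$psi_kd <- pmin(100, pmax(0, out$baseline_psi + raw))
  out$realized_dpsi <- out$psi_kd - out$baseline_psi
  out <- out[order(out$ase_id, out$cell_line, out$sirna),
             c("ase_id", "cell_line", "sirna", "baseline_psi", "psi_kd",
               "realized_dpsi")]
  rownames(out) <- NULL
  out
}

#' Change calls implied by the truth table at zero noise
#'
#' Applies the same dual-siRNA rule used on measured data ([call_change()])
#' to the truth table's realized (clamped) effects, giving the exact calls a
#' noise-free measurement must recover.
#'
#' @param truth a `truth_table`.
#' @param threshold change threshold in psi percentage points.
#' @param lenient use the one-siRNA-over-threshold variant of the rule.
#' @return data.frame `ase_id`, `cell_line`, `dpsi1`, `dpsi2`, `changed`,
#'   `direction`.
#' @export
truth_calls <- function(truth, threshold = 8, lenient = FALSE) {
  re <- realized_effects(truth)
  wide <- merge(re[re$sirna == "siRNA1", c("ase_id", "cell_line", "realized_dpsi")],
                re[re$sirna == "siRNA2", c("ase_id", "cell_line", "realized_dpsi")],
                by = c("ase_id", "cell_line"), suffixes = c("1", "2"))
  cc <- call_change(wide$realized_dpsi1, wide$realized_dpsi2,
                    threshold = threshold, lenient = lenient)
  out <- data.frame(ase_id = wide$ase_id, cell_line = wide$cell_line,
                    dpsi1 = wide$realized_dpsi1, dpsi2 = wide$realized_dpsi2,
                    changed = cc$changed, direction = cc$direction,
                    stringsAsFactors = FALSE)
  out <- out[order(out$ase_id, out$cell_line), ]
  rownames(out) <- NULL
  out
}

# internal: true psi of one (ase, cell_line, condition) under the truth table
true_psi <- function(truth, re, ase_id, cell_line, condition) {
  if (condition == "mock") {
    i <- which(truth$effects$ase_id == ase_id & truth$effects$cell_line == cell_line)
    return(truth$effects$baseline_psi[i])
  }
  j <- which(re$ase_id == ase_id & re$cell_line == cell_line & re$sirna == condition)
  re$psi_kd[j]
}
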