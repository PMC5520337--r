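# Simulated migration model: migration time is linear in log10(fragment size),
# the same functional form the ladder calibration fits. Units are arbitrary.
sim_time_of_size <- function(size_bp) 30 * log10(size_bp)

#' Default simulated sizing ladder
#'
#' Ladder fragments spanning 25-850 bp with migration times from the
#' simulator's log-linear migration model. Calibrating on this ladder and
#' evaluating inside its range inverts the simulator's sizing exactly.
#'
#' @return data.frame with columns `time`, `size_bp`, both strictly increasing.
#' @export
default_ladder <- function() {
  sizes <- c(25, 50, 100, 150, 200, 300, 400, 500, 700, 850)
  data.frame(time = sim_time_of_size(sizes), size_bp = sizes)
}

#' Default simulator noise model
#'
#' `baseline_sd`: additive Gaussian trace noise in signal units (default set
#' so a mid-range amplicon peak has signal-to-noise around 50).
#' `size_jitter_sd`: sd of the multiplicative lognormal sizing error, so
#' called sizes are `size * exp(N(0, size_jitter_sd))`.
#' `amount_cv`: coefficient of variation of the lognormal amount noise on
#' each isoform's molar amount.
#'
#' @param baseline_sd,size_jitter_sd,amount_cv non-negative scalars.
#' @return named list.
#' @export
noise_model <- function(baseline_sd = 8, size_jitter_sd = 0.02, amount_cv = 0.05) {
  stopifnot(baseline_sd >= 0, size_jitter_sd >= 0, amount_cv >= 0)
  list(baseline_sd = baseline_sd, size_jitter_sd = size_jitter_sd,
       amount_cv = amount_cv)
}

#' Synthesize a capillary electrophoresis trace for one sample
#'
#' Renders every ASE in `catalog` as two Gaussian peaks (inclusion and
#' exclusion amplicons) on a fluorescence-versus-migration-time trace. Peak
#' area is mass-proportional (molar amount x fragment length, as for an
#' intercalating dye), peak centers are placed by the simulator's migration
#' model after multiplicative sizing error, and i.i.d. Gaussian baseline
#' noise is added. The molar split between the two amplicons realizes the
#' sample's true psi under `truth`.
#'
#' Real instruments run one RT-PCR reaction (one ASE) per well; pass a
#' one-row catalog to emulate that, as [simulate_screen()] does.
#'
#' @param sample list or one-row data.frame with `cell_line`, `condition`
#'   (`"mock"`, `"siRNA1"` or `"siRNA2"`) and `batch_day`.
#' @param catalog ASE catalog rows to render.
#' @param truth a `truth_table` covering the catalog and cell line.
#' @param noise noise parameters from [noise_model()].
#' @param total_molar total molar amount per ASE (arbitrary units).
#' @param peak_sd_time Gaussian peak sd in migration-time units.
#' @param grid time grid; default covers the [default_ladder()] range.
#' @param seed optional seed (omit to draw from the current RNG stream).
#' @return A `ce_trace`: list with `time`, `signal` and `metadata`.
#' @export
synthesize_trace <- function(sample, catalog, truth, noise = noise_model(),
                             total_molar = 1, peak_sd_time = 0.15,
                             grid = seq(40, 90, by = 0.05), seed = NULL) {
  stopifnot(noise$baseline_sd >= 0, noise$size_jitter_sd >= 0, noise$amount_cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  re <- realized_effects(truth)
  signal <- numeric(length(grid))
  for (i in seq_len(nrow(catalog))) {
    psi <- true_psi(truth, re, catalog$ase_id[i], sample$cell_line, sample$condition)
    mol <- molar_pair(psi, total_molar, noise$amount_cv)
    sizes <- c(catalog$size_inclusion_bp[i], catalog$size_exclusion_bp[i])
    called <- sizes * exp(stats::rnorm(2L, 0, noise$size_jitter_sd))
    centers <- sim_time_of_size(called)
    areas <- mol * sizes                      # fluorescence mass ~ molar x length
    for (k in 1:2) {
      amp <- areas[k] / (peak_sd_time * sqrt(2 * pi))
      signal <- signal + amp * exp(-(grid - centers[k])^2 / (2 * peak_sd_time^2))
    }
  }
  if (noise$baseline_sd > 0)
    signal <- signal + stats::rnorm(length(grid), 0, noise$baseline_sd)
  structure(list(time = grid, signal = signal,
                 metadata = list(cell_line = sample$cell_line,
                                 condition = sample$condition,
                                 batch_day = sample$batch_day,
                                 ase_id = if (nrow(catalog) == 1L) catalog$ase_id else NA_character_)),
            class = "ce_trace")
}

# internal: noisy molar amounts of (inclusion, exclusion) realizing psi
molar_pair <- function(psi, total_molar, amount_cv) {
  mol <- total_molar * c(psi, 100 - psi) / 100
  if (amount_cv > 0) {
    sdlog <- sqrt(log(1 + amount_cv^2))
    mol <- mol * stats::rlnorm(2L, -sdlog^2 / 2, sdlog)
  }
  mol
}

#' Sample sheet for a simulated screen
#'
#' One mock and two siRNA transfections per cell line. With
#' `sirna_days = "shared"` (the default) all three share one batch day and
#' hence one same-day mock; with `"separate"` each siRNA is transfected on
#' its own day with its own mock, so the two delta-psi values carry
#' independent control noise.
#'
#' @param cell_lines character vector.
#' @param sirna_days `"shared"` or `"separate"`.
#' @return data.frame `sample_id`, `cell_line`, `condition`, `batch_day`.
#' @export
screen_sample_sheet <- function(cell_lines, sirna_days = c("shared", "separate")) {
  sirna_days <- match.arg(sirna_days)
  rows <- lapply(cell_lines, function(cl) {
    if (sirna_days == "shared") {
      data.frame(cell_line = cl, condition = c("mock", "siRNA1", "siRNA2"),
                 batch_day = 1L, stringsAsFactors = FALSE)
    } else {
      data.frame(cell_line = cl,
                 condition = c("mock", "siRNA1", "mock", "siRNA2"),
                 batch_day = c(1L, 1L, 2L, 2L), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$sample_id <- sprintf("%s_day%d_%s", out$cell_line, out$batch_day, out$condition)
  out[, c("sample_id", "cell_line", "condition", "batch_day")]
}

#' Simulate a full knockdown splicing screen
#'
#' Generates every sample of a screen, either as rendered electropherogram
#' traces (one reaction per ASE per sample, the realistic route through peak
#' detection and sizing) or as a pre-quantified peak table (the fast bypass:
#' called sizes and areas with the same sizing and amount noise, skipping
#' trace rendering).
#'
#' @param catalog ASE catalog.
#' @param truth matching `truth_table`.
#' @param noise [noise_model()] parameters.
#' @param output `"traces"` or `"peaks"`.
#' @param sirna_days see [screen_sample_sheet()].
#' @param total_molar total molar amount per ASE reaction.
#' @param seed integer seed for the whole screen.
#' @return list of class `sim_screen`: `samples`, `catalog`, `truth`,
#'   `ladder`, and `traces` (list of `ce_trace`) or `peaks` (data.frame
#'   `sample_id`, `ase_id`, `called_size_bp`, `area`).
#' @export
simulate_screen <- function(catalog, truth, noise = noise_model(),
                            output = c("traces", "peaks"),
                            sirna_days = c("shared", "separate"),
                            total_molar = 1, seed = NULL) {
  output <- match.arg(output)
  sirna_days <- match.arg(sirna_days)
  if (!is.null(seed)) set.seed(seed)
  cell_lines <- unique(truth$effects$cell_line)
  samples <- screen_sample_sheet(cell_lines, sirna_days)
  re <- realized_effects(truth)
  res <- list(samples = samples, catalog = catalog, truth = truth,
              ladder = default_ladder())

  if (output == "traces") {
    traces <- vector("list", nrow(samples) * nrow(catalog))
    n <- 0L
    for (s in seq_len(nrow(samples))) {
      for (i in seq_len(nrow(catalog))) {
        n <- n + 1L
        tr <- synthesize_trace(samples[s, ], catalog[i, , drop = FALSE], truth,
                               noise = noise, total_molar = total_molar)
        tr$metadata$sample_id <- samples$sample_id[s]
        traces[[n]] <- tr
      }
    }
    res$traces <- traces
  } else {
    n_rxn <- nrow(samples) * nrow(catalog)
    idx_s <- rep(seq_len(nrow(samples)), each = nrow(catalog))
    idx_a <- rep(seq_len(nrow(catalog)), times = nrow(samples))
    psi <- mapply(function(s, i) {
      true_psi(truth, re, catalog$ase_id[i], samples$cell_line[s],
               samples$condition[s])
    }, idx_s, idx_a)
    mol_inc <- total_molar * psi / 100
    mol_exc <- total_molar * (100 - psi) / 100
    if (noise$amount_cv > 0) {
      sdlog <- sqrt(log(1 + noise$amount_cv^2))
      mol_inc <- mol_inc * stats::rlnorm(n_rxn, -sdlog^2 / 2, sdlog)
      mol_exc <- mol_exc * stats::rlnorm(n_rxn, -sdlog^2 / 2, sdlog)
    }
    size_inc <- catalog$size_inclusion_bp[idx_a]
    size_exc <- catalog$size_exclusion_bp[idx_a]
    jit <- function(sz) sz * exp(stats::rnorm(n_rxn, 0, noise$size_jitter_sd))
    peaks <- data.frame(
      sample_id = rep(samples$sample_id[idx_s], 2L),
      ase_id = rep(catalog$ase_id[idx_a], 2L),
      called_size_bp = c(jit(size_inc), jit(size_exc)),
      area = c(mol_inc * size_inc, mol_exc * size_exc),
      stringsAsFactors = FALSE
    )
    res$peaks <- peaks[order(peaks$sample_id, peaks$ase_id, peaks$called_size_bp), ]
    rownames(res$peaks) <- NULL
  }
  class(res) <- "sim_screen"
  res
}
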