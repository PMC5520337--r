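#' Fixed SMN-like cassette-exon event
#'
#' A fixture alternative splicing event (ASE) modelled on the SMN exon 7
#' cassette: the alternative exon is 54 bp, so the inclusion amplicon is
#' 54 bp longer than the exclusion amplicon (276 vs 330 bp with the default
#' flanking primers used here).
#'
#' @return A one-row data.frame with the catalog schema (see
#'   [generate_ase_catalog()]).
#' @export
smn_ase <- function() {
  data.frame(
    ase_id = "SMN2_e7",
    gene = "SMN2",
    size_inclusion_bp = 330L,
    size_exclusion_bp = 276L,
    inclusion_is_long = TRUE,
    stringsAsFactors = FALSE
  )
}

#' Knockdown fractions for the two siRNA transfections of each cell line
#'
#' Protein-level knockdown fractions (96 h post transfection) for the five
#' cancer cell lines screened, two independent siRNAs per line. Used by the
#' simulator to scale planted splicing effects: within a cell line the siRNA
#' with the larger knockdown expresses the larger realized shift.
#'
#' @return data.frame with columns `cell_line`, `sirna` (`"siRNA1"`/`"siRNA2"`)
#'   and `kd_fraction` in \[0, 1\].
#' @export
rbm10_kd_table <- function() {
  data.frame(
    cell_line = rep(c("MCF-7", "MDA-MB-231", "OVCAR-3", "PC-3", "SKOV-3"), each = 2L),
    sirna = rep(c("siRNA1", "siRNA2"), times = 5L),
    kd_fraction = c(0.67, 0.60, 0.53, 0.80, 0.55, 0.80, 0.67, 0.90, 0.80, 0.93),
    stringsAsFactors = FALSE
  )
}

#' Generate a catalog of two-amplicon alternative splicing events
#'
#' Each ASE yields two RT-PCR amplicons: one for the isoform including the
#' alternative region and one for the isoform excluding it. Amplicon sizes
#' are kept within the 150-700 bp window resolvable by microfluidic capillary
#' electrophoresis, and the two sizes differ by at least `min_diff` bp (the
#' alternative region length) so the peaks are separable.
#'
#' @param n_ases number of events to generate (>= 1).
#' @param seed integer seed; identical seeds reproduce the catalog exactly.
#' @param two_ase_gene_frac fraction of genes carrying two ASEs (the screens
#'   assay a few genes at two events each, e.g. 96 ASEs from 92 genes).
#' @param min_size,max_size amplicon size window in bp.
#' @param min_diff,max_diff bounds on the alternative region length in bp.
#' @param min_rel_diff minimum size difference relative to the longer
#'   amplicon, so the two peaks stay unambiguous under the default 10%
#'   relative matching tolerance of [assign_amplicons()].
#' @param include_smn if TRUE the first row is the fixed SMN-like fixture from
#'   [smn_ase()].
#' @return data.frame with columns `ase_id`, `gene`, `size_inclusion_bp`,
#'   `size_exclusion_bp`, `inclusion_is_long`.
#' @export
generate_ase_catalog <- function(n_ases, seed = NULL, two_ase_gene_frac = 0.04,
                                 min_size = 150L, max_size = 700L,
                                 min_diff = 20L, max_diff = 250L,
                                 min_rel_diff = 0.12, include_smn = FALSE) {
  if (!is.numeric(n_ases) || length(n_ases) != 1L || is.na(n_ases) || n_ases < 1)
    stop("`n_ases` must be a single integer >= 1", call. = FALSE)
  n_ases <- as.integer(n_ases)
  stopifnot(min_size >= 1L, max_size > min_size + min_diff, min_diff >= 1L)
  if (!is.null(seed)) set.seed(seed)

  n_rand <- n_ases - as.integer(include_smn)
  # gene labels: a fraction of genes contribute two events each
  n_dual <- min(floor(two_ase_gene_frac / (1 + two_ase_gene_frac) * n_rand),
                n_rand %/% 2L)
  n_genes <- n_rand - n_dual
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  gene_of <- c(genes, if (n_dual > 0L) genes[seq_len(n_dual)])
  if (n_rand > 0L) gene_of <- gene_of[seq_len(n_rand)]

  rows <- NULL
  if (n_rand > 0L) {
    # short amplicon first, then a difference large enough that the pair is
    # resolvable both absolutely (min_diff) and relative to the longer
    # amplicon (min_rel_diff)
    short_max <- min(max_size - min_diff, floor(max_size * (1 - min_rel_diff)))
    short <- round(stats::runif(n_rand, min_size, short_max))
    diff_lo <- pmax(min_diff, ceiling(short * min_rel_diff / (1 - min_rel_diff)))
    diff_hi <- pmin(max_diff, max_size - short)
    diff <- round(stats::runif(n_rand, diff_lo, pmax(diff_lo, diff_hi)))
    long <- short + diff
    inclusion_is_long <- rep(TRUE, n_rand)
    rows <- data.frame(
      ase_id = sprintf("ASE%04d", seq_len(n_rand)),
      gene = gene_of,
      size_inclusion_bp = as.integer(ifelse(inclusion_is_long, long, short)),
      size_exclusion_bp = as.integer(ifelse(inclusion_is_long, short, long)),
      inclusion_is_long = inclusion_is_long,
      stringsAsFactors = FALSE
    )
  }
  out <- if (include_smn) rbind(smn_ase(), rows) else rows
  rownames(out) <- NULL
  validate_catalog(out, min_size = min_size, max_size = max_size, min_diff = min_diff)
  out
}

# internal: invariant checks shared by the generator and the TSV reader
validate_catalog <- function(catalog, min_size = 150L, max_size = 700L, min_diff = 1L) {
  required <- c("ase_id", "gene", "size_inclusion_bp", "size_exclusion_bp",
                "inclusion_is_long")
  missing <- setdiff(required, names(catalog))
  if (length(missing))
    stop("catalog is missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(catalog$ase_id))
    stop("catalog ase_id values must be unique", call. = FALSE)
  long <- pmax(catalog$size_inclusion_bp, catalog$size_exclusion_bp)
  short <- pmin(catalog$size_inclusion_bp, catalog$size_exclusion_bp)
  ok_order <- ifelse(catalog$inclusion_is_long,
                     catalog$size_inclusion_bp > catalog$size_exclusion_bp,
                     catalog$size_exclusion_bp > catalog$size_inclusion_bp)
  if (!all(ok_order))
    stop("inclusion_is_long flag inconsistent with amplicon sizes", call. = FALSE)
  if (any(short < min_size) || any(long > max_size))
    stop(sprintf("amplicon sizes must lie in [%d, %d] bp", min_size, max_size),
         call. = FALSE)
  if (any(long - short < min_diff))
    stop(sprintf("amplicon size difference must be >= %d bp", min_diff), call. = FALSE)
  invisible(catalog)
}
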