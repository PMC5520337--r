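#' Build the delta-psi matrix of changed ASEs
#'
#' Rows are ASEs called changed in at least one cell line, columns are cell
#' lines; each entry is the representative delta-psi of that (ASE, cell
#' line): the mean of the two per-siRNA shifts. Entries where the ASE was
#' not evaluable are NA. Row names are `gene|ase_id` so heatmap rows carry
#' gene symbols.
#'
#' @param delta_records data.frame from [compute_delta_psi()].
#' @param calls data.frame from [call_changes()].
#' @param catalog ASE catalog (for gene labels); optional.
#' @return numeric matrix, or an empty 0-row matrix when nothing changed.
#' @export
build_dpsi_matrix <- function(delta_records, calls, catalog = NULL) {
  changed_ases <- sort(unique(calls$ase_id[calls$changed]))
  cell_lines <- sort(unique(calls$cell_line))
  m <- matrix(NA_real_, nrow = length(changed_ases), ncol = length(cell_lines),
              dimnames = list(changed_ases, cell_lines))
  if (length(changed_ases) == 0L) return(m)
  rep_val <- tapply(delta_records$delta_psi,
                    list(delta_records$ase_id, delta_records$cell_line),
                    function(v) mean(v))
  common_r <- intersect(rownames(rep_val), changed_ases)
  m[common_r, colnames(rep_val)] <- rep_val[common_r, , drop = FALSE]
  if (!is.null(catalog)) {
    g <- catalog$gene[match(rownames(m), catalog$ase_id)]
    rownames(m) <- paste(g, rownames(m), sep = "|")
  }
  m
}

#' Two-way hierarchical clustering of a delta-psi matrix
#'
#' Agglomerative clustering of rows (ASEs/genes) and columns (cell lines)
#' with Euclidean distance and either average or Ward linkage. "ward"
#' follows the classic ward.D convention: the Lance-Williams Ward update on
#' unsquared Euclidean input distances. Missing entries are imputed as 0
#' (no shift, the neutral value on the delta-psi scale) before distances are
#' computed; `impute` = "pairwise" uses pairwise-complete Euclidean
#' distances instead.
#'
#' @param mat numeric matrix from [build_dpsi_matrix()], >= 2 rows.
#' @param linkage `"average"` or `"ward"`.
#' @param impute `"zero"` (default) or `"pairwise"`.
#' @return list of class `cluster_tree`: `rows` and `cols` (hclust objects;
#'   `cols` is NULL for < 2 columns), `matrix` (the imputed matrix), and
#'   `linkage`.
#' @export
hierarchical_cluster <- function(mat, linkage = c("average", "ward"),
                                 impute = c("zero", "pairwise")) {
  linkage <- match.arg(linkage)
  impute <- match.arg(impute)
  if (!is.matrix(mat) || nrow(mat) < 2L)
    stop("clustering needs a matrix with >= 2 rows", call. = FALSE)
  method <- if (linkage == "ward") "ward.D" else "average"
  dist_of <- function(x) {
    if (impute == "zero") {
      x[is.na(x)] <- 0
      stats::dist(x, method = "euclidean")
    } else {
      d <- stats::dist(x, method = "euclidean")  # stats::dist is pairwise-complete
      if (anyNA(d)) stop("pairwise-complete distance undefined for some row pair",
                         call. = FALSE)
      d
    }
  }
  imputed <- mat
  if (impute == "zero") imputed[is.na(imputed)] <- 0
  rows <- stats::hclust(dist_of(mat), method = method)
  cols <- if (ncol(mat) >= 2L) stats::hclust(dist_of(t(mat)), method = method)
          else NULL
  structure(list(rows = rows, cols = cols, matrix = imputed, linkage = linkage),
            class = "cluster_tree")
}

#' Cut a cluster tree into k groups
#'
#' Cuts the row dendrogram below its k-1 highest merges, assigning each row
#' to one of k clusters.
#'
#' @param tree a `cluster_tree` (or a plain hclust object).
#' @param k number of clusters, 1 <= k <= number of rows.
#' @return named integer vector of cluster memberships.
#' @export
cut_k <- function(tree, k) {
  hc <- if (inherits(tree, "cluster_tree")) tree$rows else tree
  n <- length(hc$order)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n)
    stop("`k` must lie in [1, ", n, "]", call. = FALSE)
  stats::cutree(hc, k = as.integer(k))
}

#' Export a clustered matrix as a TSV heatmap table
#'
#' Writes the matrix reordered by the dendrogram leaf orders (the layout a
#' heatmap would draw), plus the leaf orders themselves.
#'
#' @param tree a `cluster_tree`.
#' @param path output TSV path.
#' @return invisibly, the reordered matrix.
#' @export
export_heatmap_tsv <- function(tree, path) {
  m <- tree$matrix[tree$rows$order,
                   if (!is.null(tree$cols)) tree$cols$order else seq_len(ncol(tree$matrix)),
                   drop = FALSE]
  df <- data.frame(row = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}
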