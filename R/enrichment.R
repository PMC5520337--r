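#' Read a GMT gene-set file
#'
#' GMT is the de facto tab-delimited gene-set format: one set per line as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Gene symbols are
#' uppercased and deduplicated within a set; set order is preserved.
#'
#' @param path path to a GMT file.
#' @return list of class `gene_set_collection`: `sets` (named list of
#'   character vectors), `descriptions`, `source` (the path).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descriptions <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L)
      stop(sprintf("malformed GMT line %d: need name, description and >= 1 gene", i),
           call. = FALSE)
    name <- fields[1L]
    if (name %in% names(sets))
      stop(sprintf("duplicate gene-set name '%s' at GMT line %d", name, i),
           call. = FALSE)
    sets[[name]] <- unique(toupper(fields[-(1:2)]))
    descriptions[name] <- fields[2L]
  }
  structure(list(sets = sets, descriptions = descriptions, source = path),
            class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#'
#' @param collection a `gene_set_collection`, or a named list of character
#'   vectors (descriptions default to the set names).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  if (inherits(collection, "gene_set_collection")) {
    sets <- collection$sets
    desc <- collection$descriptions
  } else {
    sets <- collection
    desc <- stats::setNames(names(sets), names(sets))
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation test of changed genes
#'
#' For each gene set, tests whether the changed genes hit the set more often
#' than drawing the same number of genes from the assayed universe would:
#' one-sided hypergeometric upper tail `P(X >= k)` with population `N`
#' (universe size), `K` successes (universe genes in the set), `n` draws
#' (changed genes) and `k` observed hits. Sets are intersected with the
#' universe first; sets disjoint from the universe are skipped. P-values are
#' Benjamini-Hochberg adjusted across the tested sets.
#'
#' The universe is gene-level: a gene assayed at two ASEs counts once.
#'
#' @param changed_genes character vector, must be a subset of
#'   `universe_genes`.
#' @param universe_genes character vector of all assayed genes (>= 2).
#' @param collection a `gene_set_collection`.
#' @return data.frame `set`, `k`, `K`, `n`, `N`, `p_value`, `p_adjust`,
#'   `genes` (comma-separated hits), ordered by `p_value`; attribute
#'   `skipped` lists sets disjoint from the universe.
#' @export
test_overrepresentation <- function(changed_genes, universe_genes, collection) {
  universe <- unique(toupper(universe_genes))
  changed <- unique(toupper(changed_genes))
  if (length(universe) < 2L)
    stop("universe must contain >= 2 genes", call. = FALSE)
  off <- setdiff(changed, universe)
  if (length(off))
    stop("changed genes not in the universe: ", paste(off, collapse = ", "),
         call. = FALSE)
  N <- length(universe)
  n <- length(changed)
  rows <- list()
  skipped <- character(0)
  for (nm in names(collection$sets)) {
    set_u <- intersect(collection$sets[[nm]], universe)
    K <- length(set_u)
    if (K == 0L) {
      skipped <- c(skipped, nm)
      next
    }
    hits <- intersect(changed, set_u)
    k <- length(hits)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    rows[[nm]] <- data.frame(set = nm, k = k, K = K, n = n, N = N,
                             p_value = p, genes = paste(sort(hits), collapse = ","),
                             stringsAsFactors = FALSE)
  }
  if (length(skipped))
    message("skipped ", length(skipped),
            " gene set(s) disjoint from the universe: ",
            paste(skipped, collapse = ", "))
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(set = character(0), k = integer(0), K = integer(0),
                         n = integer(0), N = integer(0), p_value = numeric(0),
                         genes = character(0), stringsAsFactors = FALSE)
  out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set),
             c("set", "k", "K", "n", "N", "p_value", "p_adjust", "genes")]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
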