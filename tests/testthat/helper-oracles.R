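# Independent oracles and fixture builders used across the suite. These stay
# deliberately separate from the implementation paths they check.

# Sum of Gaussians on a time grid, as a ce_trace-shaped list.
make_gaussian_trace <- function(centers, amps, sds, grid = seq(0, 50, by = 0.01),
                                baseline = 0, metadata = list()) {
  sds <- rep_len(sds, length(centers))
  signal <- rep(baseline, length(grid))
  for (i in seq_along(centers))
    signal <- signal + amps[i] * exp(-(grid - centers[i])^2 / (2 * sds[i]^2))
  structure(list(time = grid, signal = signal, metadata = metadata),
            class = "ce_trace")
}

# Naive agglomerative clustering by the Lance-Williams update rules, run on a
# plain distance matrix. Returns merge heights in merge order. Independent of
# stats::hclust: full matrix updates, explicit cluster-size bookkeeping.
lance_williams_heights <- function(d, method = c("average", "ward.D")) {
  method <- match.arg(method)
  d <- as.matrix(d)
  n <- nrow(d)
  active <- seq_len(n)
  sizes <- rep(1L, n)
  heights <- numeric(n - 1L)
  diag(d) <- Inf
  for (step in seq_len(n - 1L)) {
    sub <- d[active, active, drop = FALSE]
    idx <- which(sub == min(sub), arr.ind = TRUE)[1L, ]
    i <- active[min(idx)]; j <- active[max(idx)]
    heights[step] <- d[i, j]
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      d_new <- if (method == "average") {
        (ni * d[k, i] + nj * d[k, j]) / (ni + nj)
      } else {
        ((nk + ni) * d[k, i] + (nk + nj) * d[k, j] - nk * d[i, j]) / (nk + ni + nj)
      }
      d[k, i] <- d[i, k] <- d_new
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

# Exact hypergeometric upper tail by enumeration of every possible draw.
brute_force_hyper_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)   # successes are items 1..K
  mean(hits >= k)
}

# Small zero-noise simulated screen, quantified end to end.
quantified_toy_screen <- function(n_ases = 10, cell_lines = c("MCF-7", "PC-3"),
                                  seed = 11, prop_null = 0.4,
                                  output = "peaks", noise = noise_model(0, 0, 0),
                                  ...) {
  catalog <- generate_ase_catalog(n_ases, seed = seed)
  truth <- generate_truth(catalog, cell_lines, prop_null = prop_null,
                          seed = seed + 1, ...)
  screen <- simulate_screen(catalog, truth, noise = noise, output = output,
                            seed = seed + 2)
  psi <- quantify_screen(screen)
  list(catalog = catalog, truth = truth, screen = screen, psi = psi,
       delta = compute_delta_psi(psi))
}
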