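# Small-scene parameters used across tests; clean = no nuisance effects.
tiny_scene <- function(seed = 1L, clean = TRUE, ...) {
  defaults <- list(image_size = c(96L, 96L), well_radius = 40,
                   n_grains = 12L, grain_radius_range = c(3, 5), seed = seed)
  if (clean) defaults <- c(defaults, list(mycelium_growth_rate = 0,
                                          illumination_gradient = 0,
                                          noise_sd = 0))
  do.call(scene_params, utils::modifyList(defaults, list(...)))
}

hours14d <- seq(0, 336, by = 24)  # 15 time points over 14 days

# exact straight-line remaining-% curve: 100 - slope * t
line_curve <- function(times = seq(0, 300, by = 20), slope = 1) {
  kinetic_curve(times, 100 - slope * times)
}

# brute-force one-way ANOVA F: explicit two-loop sums of squares
brute_force_F <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ssb <- 0; ssw <- 0
  for (g in groups) {
    ssb <- ssb + length(g) * (mean(g) - gm)^2
    for (v in g) ssw <- ssw + (v - mean(g))^2
  }
  k <- length(groups); N <- length(all_v)
  (ssb / (k - 1)) / (ssw / (N - k))
}

# explicit per-pixel double-loop white count within a closed interval
loop_count <- function(frame, low, high, well = NULL) {
  cnt <- 0L
  for (i in seq_len(nrow(frame))) for (j in seq_len(ncol(frame))) {
    inwell <- is.null(well) || well[i, j]
    if (inwell && frame[i, j] >= low && frame[i, j] <= high)
      cnt <- cnt + 1L
  }
  cnt
}

# max-t permutation oracle for pairwise comparisons of 3 groups of 3
perm_maxt_pvalues <- function(groups, n_perm = 1e4, seed = 1) {
  v <- unlist(groups); n <- lengths(groups); k <- length(groups)
  idx <- split(seq_along(v), rep(seq_len(k), n))
  stat <- function(vals) {
    m <- vapply(idx, function(ii) mean(vals[ii]), numeric(1))
    mse <- sum(vapply(idx, function(ii) sum((vals[ii] - mean(vals[ii]))^2),
                      numeric(1))) / (length(v) - k)
    pr <- utils::combn(k, 2)
    q <- abs(m[pr[2, ]] - m[pr[1, ]]) /
      sqrt(mse / 2 * (1 / n[pr[1, ]] + 1 / n[pr[2, ]]))
    q
  }
  q_obs <- stat(v)
  withr::with_seed(seed, {
    maxs <- replicate(n_perm, max(stat(v[sample.int(length(v))])))
  })
  vapply(q_obs, function(q) (1 + sum(maxs >= q)) / (1 + n_perm), numeric(1))
}
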