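#' Scene parameters for synthetic well images
#'
#' Describes one simulated well of a culture plate: bright polymer grains
#' (PHB/BDF particles) resting on darker agar, progressively overgrown by a
#' whitish mycelium whose grey level lies strictly between the agar and the
#' grains. A smooth multiplicative illumination field and additive Gaussian
#' pixel noise emulate non-ideal acquisition.
#'
#' @param image_size integer vector `c(height, width)` in pixels.
#' @param well_center numeric `c(row, col)` of the well centre; defaults to
#'   the image centre.
#' @param well_radius well radius in pixels; the well must fit in the image.
#' @param n_grains number of polymer grains.
#' @param grain_radius_range `c(min, max)` grain radius in pixels.
#' @param grain_intensity,agar_intensity,mycelium_intensity grey levels in
#'   `[0, 1]`; must satisfy `grain > mycelium > agar`.
#' @param mycelium_growth_rate fraction of the well area newly covered by
#'   mycelium per hour (coverage saturates at 1).
#' @param illumination_gradient maximum relative deviation of the smooth
#'   multiplicative illumination field (0 disables it).
#' @param noise_sd standard deviation of additive Gaussian pixel noise, in
#'   grey levels (0 disables it).
#' @param seed integer seed; all randomness of one simulated series flows
#'   from it.
#' @return An object of class `scene_params`.
#' @seealso [simulate_image_series()]
#' @export
scene_params <- function(image_size = c(256L, 256L),
                         well_center = NULL,
                         well_radius = 0.43 * min(image_size),
                         n_grains = 40L,
                         grain_radius_range = c(4, 9),
                         grain_intensity = 0.85,
                         agar_intensity = 0.15,
                         mycelium_intensity = 0.55,
                         mycelium_growth_rate = 0.002,
                         illumination_gradient = 0.08,
                         noise_sd = 0.02,
                         seed = 1L) {
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size < 8L))
    stop_phb("image_size must be c(height, width), each >= 8")
  if (is.null(well_center)) well_center <- (image_size + 1) / 2
  ints <- c(grain_intensity, mycelium_intensity, agar_intensity)
  if (any(ints < 0) || any(ints > 1))
    stop_phb("intensities must lie in [0, 1]")
  if (!(grain_intensity > mycelium_intensity &&
        mycelium_intensity > agar_intensity))
    stop_phb("intensities must satisfy grain > mycelium > agar")
  if (well_center[1] - well_radius < 1 || well_center[1] + well_radius > image_size[1] ||
      well_center[2] - well_radius < 1 || well_center[2] + well_radius > image_size[2])
    stop_phb("well does not fit inside the image")
  if (length(grain_radius_range) != 2L || any(grain_radius_range <= 0) ||
      grain_radius_range[1] > grain_radius_range[2])
    stop_phb("grain_radius_range must be c(min, max) with 0 < min <= max")
  if (mycelium_growth_rate < 0 || illumination_gradient < 0 || noise_sd < 0)
    stop_phb("rates, gradient and noise_sd must be non-negative")
  structure(list(
    image_size = image_size, well_center = as.numeric(well_center),
    well_radius = as.numeric(well_radius), n_grains = as.integer(n_grains),
    grain_radius_range = as.numeric(grain_radius_range),
    grain_intensity = grain_intensity, agar_intensity = agar_intensity,
    mycelium_intensity = mycelium_intensity,
    mycelium_growth_rate = mycelium_growth_rate,
    illumination_gradient = illumination_gradient,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "scene_params")
}

#' Ground-truth degradation trajectory
#'
#' The remaining fraction of polymer grain area at each imaging time. The
#' trajectory must start at exactly 1 (nothing degraded at t0) and stay in
#' `[0, 1]`. `t50_true` is the first time at which the (linearly
#' interpolated) trajectory crosses 0.5, or `NA` if it never does within
#' the observation window.
#'
#' @param times imaging times in hours, strictly increasing.
#' @param remaining_fraction remaining area fraction at each time.
#' @param t50_true optional exact crossing time (e.g. known analytically);
#'   when omitted it is interpolated from the sampled trajectory.
#' @return An object of class `truth_trajectory`.
#' @export
truth_trajectory <- function(times, remaining_fraction, t50_true = NULL) {
  times <- as.numeric(times); rf <- as.numeric(remaining_fraction)
  if (length(times) == 0L || length(times) != length(rf))
    stop_phb("times and remaining_fraction must be non-empty, equal length")
  if (any(diff(times) <= 0)) stop_phb("times must be strictly increasing")
  if (abs(rf[1] - 1) > 1e-12)
    stop_phb("remaining_fraction must start at 1 (nothing degraded at t0)")
  if (any(rf < 0 | rf > 1)) stop_phb("remaining_fraction must lie in [0, 1]")
  if (is.null(t50_true)) {
    t50_true <- NA_real_
    i <- which(rf <= 0.5)[1]
    if (!is.na(i) && i > 1L) {
      t50_true <- times[i - 1] + (times[i] - times[i - 1]) *
        (rf[i - 1] - 0.5) / (rf[i - 1] - rf[i])
    }
  }
  structure(list(times = times, remaining_fraction = rf,
                 t50_true = t50_true),
            class = "truth_trajectory")
}

#' Logistic degradation trajectory with a prescribed t50
#'
#' Builds a sigmoidal remaining-fraction trajectory, normalized so that the
#' first time point is exactly 1, whose 50%-crossing occurs at `t50`
#' (solved for exactly; `NA`-censored if `t50` lies beyond the last time).
#'
#' @param times imaging times in hours, strictly increasing.
#' @param t50 desired crossing time of the normalized trajectory, hours.
#'   Values beyond `max(times)` give a slow, never-crossing trajectory.
#' @param steepness logistic steepness in 1/hours.
#' @return A [truth_trajectory()].
#' @export
logistic_trajectory <- function(times, t50, steepness = 0.03) {
  times <- as.numeric(times)
  if (steepness <= 0) stop_phb("steepness must be positive")
  f <- function(t, loc) 1 / (1 + exp(steepness * (t - loc)))
  # normalized crossing of location parameter `loc`:
  crossing <- function(loc) {
    f1 <- f(times[1], loc)
    loc + log(2 / f1 - 1) / steepness
  }
  # solve for loc so the normalized curve crosses 0.5 at t50
  lo <- times[1]; hi <- times[1] + 2 * (max(times) - times[1]) + 10 * abs(t50)
  loc <- tryCatch(
    stats::uniroot(function(l) crossing(l) - t50, c(lo, hi), tol = 1e-9)$root,
    error = function(e) t50
  )
  rf <- f(times, loc) / f(times[1], loc)
  rf[1] <- 1
  t50_exact <- crossing(loc)
  if (t50_exact > max(times)) t50_exact <- NA_real_
  truth_trajectory(times, pmin(1, rf), t50_true = t50_exact)
}

# ordered in-well linear pixel indices of one circular grain, centre-out
grain_pixel_order <- function(cy, cx, r, H, W) {
  rows <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
  g <- expand.grid(row = rows, col = cols)
  d2 <- (g$row - cy)^2 + (g$col - cx)^2
  keep <- d2 <= r^2
  g <- g[keep, , drop = FALSE]; d2 <- d2[keep]
  o <- order(d2, g$row, g$col)
  as.integer((g$col[o] - 1L) * H + g$row[o])
}

# place non-overlapping grain centres inside the well by rejection sampling
place_grains <- function(p, radii) {
  n <- length(radii)
  cy <- numeric(n); cx <- numeric(n)
  ord <- order(radii, decreasing = TRUE)  # large grains first packs better
  for (k in seq_len(n)) {
    i <- ord[k]; placed <- FALSE
    for (try in seq_len(4000L)) {
      a <- stats::runif(1, 0, 2 * pi)
      rr <- (p$well_radius - radii[i] - 1.5) * sqrt(stats::runif(1))
      y <- p$well_center[1] + rr * sin(a)
      x <- p$well_center[2] + rr * cos(a)
      prev <- ord[seq_len(k - 1L)]
      if (k == 1L || all((cy[prev] - y)^2 + (cx[prev] - x)^2 >=
                         (radii[prev] + radii[i] + 2)^2)) {
        cy[i] <- y; cx[i] <- x; placed <- TRUE; break
      }
    }
    if (!placed) stop_phb("grains cannot fit in well")
  }
  cbind(row = cy, col = cx)
}

# ordered first-touch pixel indices of correlated random-walk filaments
mycelium_order <- function(p, n_needed) {
  if (n_needed <= 0L) return(integer(0))
  H <- p$image_size[1]; W <- p$image_size[2]
  cy <- p$well_center[1]; cx <- p$well_center[2]; R <- p$well_radius
  seen <- logical(H * W)
  ord <- integer(0)
  filament <- 0L
  while (length(ord) < n_needed && filament < 5000L) {
    filament <- filament + 1L
    a0 <- stats::runif(1, 0, 2 * pi)
    y0 <- cy + 0.97 * R * sin(a0); x0 <- cx + 0.97 * R * cos(a0)
    heading <- a0 + pi + stats::rnorm(1, 0, 0.4)   # roughly inward
    L <- as.integer(round(3 * R))
    th <- heading + cumsum(stats::rnorm(L, 0, 0.25))
    ys <- round(y0 + cumsum(sin(th))); xs <- round(x0 + cumsum(cos(th)))
    ok <- ys >= 1 & ys <= H & xs >= 1 & xs <= W &
      (ys - cy)^2 + (xs - cx)^2 <= R^2
    ys <- ys[ok]; xs <- xs[ok]
    if (!length(ys)) next
    idx <- as.integer((xs - 1) * H + ys)
    # 2-px thickness: pair each step with its right neighbour when in-well
    nb <- idx + H
    nb_ok <- xs + 1 <= W & (ys - cy)^2 + (xs + 1 - cx)^2 <= R^2
    all_idx <- as.vector(rbind(idx, ifelse(nb_ok, nb, idx)))
    new <- all_idx[!seen[all_idx] & !duplicated(all_idx)]
    seen[new] <- TRUE
    ord <- c(ord, new)
  }
  ord
}

# smooth low-order multiplicative illumination field, max |deviation| = g
illumination_field <- function(p) {
  H <- p$image_size[1]; W <- p$image_size[2]
  g <- p$illumination_gradient
  if (g == 0) return(matrix(1, H, W))
  cf <- stats::runif(5, -1, 1)
  yy <- matrix(seq(-1, 1, length.out = H), H, W)
  xx <- matrix(seq(-1, 1, length.out = W), H, W, byrow = TRUE)
  f0 <- cf[1] * xx + cf[2] * yy + cf[3] * xx * yy +
    cf[4] * (xx^2 - 1 / 3) + cf[5] * (yy^2 - 1 / 3)
  m <- max(abs(f0))
  if (m < 1e-12) return(matrix(1, H, W))
  1 + g * f0 / m
}

#' Simulate a well-plate image time series with exact ground truth
#'
#' Renders one well per time point: polymer grains whose total pixel area
#' follows the prescribed remaining-fraction trajectory (each grain shrinks
#' radially, keeping its `round(initial_area * remaining_fraction)` pixels
#' closest to its centre and vanishing below 1 px), a mycelium drawn as
#' correlated random-walk filaments covering `min(1, growth_rate * t)` of
#' the well, then a multiplicative illumination field and additive Gaussian
#' noise, clipped to `[0, 1]`. Pixels outside the well are a dark surround.
#'
#' The emitted object carries the exact truth: per-frame grain pixel counts
#' and boolean truth masks, so downstream thresholding can be verified
#' pixel for pixel.
#'
#' @param params a [scene_params()].
#' @param trajectory a [truth_trajectory()]; its times become the frame
#'   times.
#' @param sample_id,blend_label metadata carried through the pipeline.
#' @return An object of classes `synthetic_image_series` and
#'   `image_series`: frames (numeric matrices in `[0, 1]`), `times`, a
#'   `well` mask, a `truth` data frame `(time_h, grain_px)` and
#'   `truth_masks`.
#' @export
simulate_image_series <- function(params, trajectory,
                                  sample_id = "S1", blend_label = "blend") {
  if (!inherits(params, "scene_params")) stop_phb("params must be scene_params()")
  if (!inherits(trajectory, "truth_trajectory"))
    stop_phb("trajectory must be a truth_trajectory()")
  if (abs(trajectory$remaining_fraction[1] - 1) > 1e-12)
    stop_phb("trajectory must start at remaining fraction 1")
  H <- params$image_size[1]; W <- params$image_size[2]
  times <- trajectory$times; rf <- trajectory$remaining_fraction
  elapsed <- times - times[1]

  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  well <- (yy - params$well_center[1])^2 + (xx - params$well_center[2])^2 <=
    params$well_radius^2
  well_area <- sum(well)

  frames <- vector("list", length(times))
  truth_masks <- vector("list", length(times))
  grain_px <- integer(length(times))

  withr::with_seed(params$seed, {
    radii <- stats::runif(params$n_grains, params$grain_radius_range[1],
                          params$grain_radius_range[2])
    centres <- place_grains(params, radii)
    grains <- lapply(seq_len(params$n_grains), function(i)
      grain_pixel_order(centres[i, 1], centres[i, 2], radii[i], H, W))
    n0 <- lengths(grains)
    if (any(n0 == 0L)) stop_phb("grains cannot fit in well")

    myc_target <- as.integer(round(pmin(1, params$mycelium_growth_rate * elapsed) *
                                     well_area))
    myc <- mycelium_order(params, max(myc_target))

    field <- illumination_field(params)

    base <- matrix(0.02, H, W)
    base[well] <- params$agar_intensity

    for (i in seq_along(times)) {
      img <- base
      m <- min(myc_target[i], length(myc))
      if (m > 0L) img[myc[seq_len(m)]] <- params$mycelium_intensity
      counts <- as.integer(round(n0 * rf[i]))
      px <- unlist(lapply(seq_along(grains), function(g)
        grains[[g]][seq_len(counts[g])]), use.names = FALSE)
      if (length(px)) img[px] <- params$grain_intensity
      tm <- matrix(FALSE, H, W)
      if (length(px)) tm[px] <- TRUE
      grain_px[i] <- length(px)
      truth_masks[[i]] <- tm
      img <- img * field
      if (params$noise_sd > 0)
        img <- img + matrix(stats::rnorm(H * W, 0, params$noise_sd), H, W)
      frames[[i]] <- clamp01(img)
    }
  })

  structure(list(
    frames = frames, times = times, sample_id = sample_id,
    blend_label = blend_label, well = well,
    truth = data.frame(time_h = times, grain_px = grain_px),
    truth_masks = truth_masks, t50_true = trajectory$t50_true,
    params = params
  ), class = c("synthetic_image_series", "image_series"))
}

#' Simulate a noisy replicate degradation curve
#'
#' Applies multiplicative Gaussian noise to a ground-truth trajectory and
#' renormalizes so the first value is exactly 100, emulating the
#' remaining-percentage curve the image pipeline would produce (the image
#' statistic is always normalized by its own first frame).
#'
#' @param trajectory a [truth_trajectory()].
#' @param noise_sd relative noise standard deviation (0.05 = 5% noise).
#' @param seed integer seed.
#' @param sample_id,blend_label,replicate metadata.
#' @return A [kinetic_curve()] with attribute `t50_true`.
#' @export
simulate_kinetic_curve <- function(trajectory, noise_sd = 0.05, seed = 1L,
                                   sample_id = "S1", blend_label = "blend",
                                   replicate = 1L) {
  if (!inherits(trajectory, "truth_trajectory"))
    stop_phb("trajectory must be a truth_trajectory()")
  v <- withr::with_seed(seed, {
    raw <- trajectory$remaining_fraction *
      (1 + stats::rnorm(length(trajectory$times), 0, noise_sd))
    100 * raw / raw[1]
  })
  out <- kinetic_curve(trajectory$times, v, sample_id = sample_id,
                       blend_label = blend_label, replicate = replicate)
  attr(out, "t50_true") <- trajectory$t50_true
  out
}
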