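#' Ordinary least-squares polynomial fit of a degradation curve
#'
#' Fits remaining-% values on powers of time by OLS. Internally the time
#' axis is affinely mapped to `[0, 1]` for numerical stability (raw
#' monomials of hour-scale times are badly conditioned beyond degree 3);
#' coefficients on the original time axis are recovered by exact
#' polynomial composition.
#'
#' @param curve a [kinetic_curve()].
#' @param degree polynomial degree, `>= 1`; needs `n >= degree + 2` points
#'   so at least one residual degree of freedom remains.
#' @return An object of class `poly_fit`: `coefficients` (ascending, on
#'   the hour axis), `r2`, `adj_r2`, `f_statistic`, `f_pvalue`, `fitted`,
#'   `residuals`, plus the scaled-basis coefficients used for prediction.
#' @export
fit_polynomial <- function(curve, degree) {
  if (!inherits(curve, "kinetic_curve")) stop_phb("curve must be a kinetic_curve")
  degree <- as.integer(degree)
  if (degree < 1L) stop_phb("degree must be >= 1")
  t <- curve$times; y <- curve$values
  ok <- is.finite(y)
  t <- t[ok]; y <- y[ok]
  n <- length(y)
  if (n < degree + 2L) stop_phb("insufficient points: need n >= degree + 2")
  sstot <- sum((y - mean(y))^2)
  if (sstot < 1e-10) stop_phb("no variance")
  t0 <- t[1]; s <- diff(range(t))
  u <- (t - t0) / s
  X <- outer(u, 0:degree, "^")
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  r2 <- 1 - rss / sstot
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - degree - 1)
  fstat <- (r2 / degree) / ((1 - r2) / (n - degree - 1))
  f_pvalue <- stats::pf(fstat, degree, n - degree - 1, lower.tail = FALSE)
  b <- unname(fit$coefficients)
  # compose with u = (t - t0)/s to get ascending coefficients in t
  raw <- numeric(degree + 1L); raw[1] <- b[1]
  base <- c(-t0 / s, 1 / s); cur <- 1
  for (j in seq_len(degree)) {
    cur <- polymul(cur, base)
    raw[seq_along(cur)] <- raw[seq_along(cur)] + b[j + 1L] * cur
  }
  names(raw) <- c("(Intercept)", "t", if (degree > 1) paste0("t^", 2:degree))
  structure(list(degree = degree, coefficients = raw, coef_scaled = b,
                 scale = c(t0 = t0, s = s), r2 = r2, adj_r2 = adj_r2,
                 f_statistic = fstat, f_pvalue = f_pvalue,
                 fitted = unname(fit$fitted.values),
                 residuals = unname(fit$residuals),
                 n = n, times = t, values = y),
            class = "poly_fit")
}

predict_poly <- function(fit, times) {
  u <- (times - fit$scale[["t0"]]) / fit$scale[["s"]]
  polyval_asc(fit$coef_scaled, u)
}

# Permutation null of the minimum overall-F p-value across candidate
# degrees: shuffling values against times makes any time dependence
# vanish, so the returned p-value is an exact-level test of "some
# polynomial trend exists", however many degrees are tried. The first
# observation stays in place: a remaining-% curve is normalized by its own
# t0 frame, so its first value is exactly 100 with zero noise and is not
# exchangeable with the later points — only positions 2..n are shuffled.
perm_min_pvalue <- function(times, values, degrees, n_perm, seed) {
  n <- length(values)
  t0 <- times[1]; s <- diff(range(times))
  u <- (times - t0) / s
  perms <- withr::with_seed(seed, {
    matrix(replicate(n_perm, c(1L, 1L + sample.int(n - 1L))), nrow = n)
  })
  Y <- matrix(values[perms], nrow = n)
  sstot <- sum((values - mean(values))^2)  # invariant under permutation
  minp <- rep(1, n_perm)
  for (d in degrees) {
    qr_d <- qr(outer(u, 0:d, "^"))
    rss <- colSums(qr.resid(qr_d, Y)^2)
    r2 <- pmax(0, 1 - rss / sstot)
    fstat <- (r2 / d) / pmax((1 - r2) / (n - d - 1), 1e-300)
    p <- stats::pf(fstat, d, n - d - 1, lower.tail = FALSE)
    minp <- pmin(minp, p)
  }
  minp
}

#' Select the polynomial degree for a degradation curve
#'
#' Fits degrees `1..min(max_degree, n - 2)`, requires the model family to
#' be significant, and among the individually significant degrees (overall
#' F-test p < `alpha`) returns the one maximizing the adjusted R-squared,
#' breaking ties towards the lowest degree.
#'
#' Because up to `max_degree` F-tests are inspected, family significance
#' is assessed by a permutation test of the minimum p-value across the
#' candidate degrees (values shuffled against times, `n_perm` draws),
#' which holds the overall type-I error at `alpha` exactly regardless of
#' how many degrees compete. A curve with no real time trend is therefore
#' declared "no significant model" with probability `1 - alpha`.
#'
#' @param curve a [kinetic_curve()] with at least 4 points.
#' @param max_degree highest degree tried (default 6).
#' @param alpha significance level of the F-screen (default 0.05).
#' @param n_perm permutation draws for the family gate.
#' @param perm_seed seed of the (fixed) permutation draw.
#' @return The selected `poly_fit`, with a `selection` data frame (one row
#'   per candidate degree) and the family gate p-value attached.
#' @export
select_degree <- function(curve, max_degree = 6L, alpha = 0.05,
                          n_perm = 499L, perm_seed = 1L) {
  if (!inherits(curve, "kinetic_curve")) stop_phb("curve must be a kinetic_curve")
  ok <- is.finite(curve$values)
  n <- sum(ok)
  if (n < 4L) stop_phb("need at least 4 points to select a degree")
  degrees <- seq_len(min(max_degree, n - 2L))
  fits <- lapply(degrees, function(d) fit_polynomial(curve, d))
  pvals <- vapply(fits, `[[`, numeric(1), "f_pvalue")
  adj <- vapply(fits, `[[`, numeric(1), "adj_r2")
  selection <- data.frame(
    degree = degrees,
    r2 = vapply(fits, `[[`, numeric(1), "r2"),
    adj_r2 = adj, f_pvalue = pvals,
    significant = pvals < alpha
  )
  minp_null <- perm_min_pvalue(curve$times[ok], curve$values[ok], degrees,
                               n_perm, perm_seed)
  gate_p <- (1 + sum(minp_null <= min(pvals))) / (1 + n_perm)
  if (gate_p >= alpha || !any(selection$significant))
    stop_phb("no significant model")
  cand <- which(selection$significant)
  best <- cand[adj[cand] >= max(adj[cand]) - 1e-10][1]  # tie -> lowest degree
  out <- fits[[best]]
  out$selection <- selection
  out$gate_pvalue <- gate_p
  out$alpha <- alpha
  out
}

#' Extract the half-degradation time from a fitted curve
#'
#' Finds the smallest time in the observed window at which the fitted
#' polynomial equals `level` (% remaining): a sign-change scan on a
#' 2000-point grid followed by bisection to `|dt| < 1e-6` h. The fit is
#' never extrapolated; if the fitted curve stays above `level` the result
#' is right-censored (`"> t_max"`), if it stays below, left-censored.
#'
#' @param fit a `poly_fit` (e.g. from [select_degree()]).
#' @param level crossing level in percent remaining (default 50).
#' @return A list with `t50` (hours, or `NA` when censored), `censored`
#'   (`NA` or a marker string) and the `fit_window`.
#' @export
extract_t50 <- function(fit, level = 50) {
  if (!inherits(fit, "poly_fit")) stop_phb("fit must be a poly_fit")
  tmin <- min(fit$times); tmax <- max(fit$times)
  grid <- seq(tmin, tmax, length.out = 2000L)
  fv <- predict_poly(fit, grid) - level
  hit <- which(fv == 0)[1]
  if (!is.na(hit))
    return(list(t50 = grid[hit], censored = NA_character_,
                fit_window = c(tmin, tmax)))
  cross <- which(fv[-length(fv)] * fv[-1] < 0)[1]
  if (is.na(cross)) {
    marker <- if (all(fv > 0)) sprintf("> %g", tmax) else sprintf("< %g", tmin)
    return(list(t50 = NA_real_, censored = marker, fit_window = c(tmin, tmax)))
  }
  root <- stats::uniroot(function(t) predict_poly(fit, t) - level,
                         lower = grid[cross], upper = grid[cross + 1L],
                         tol = 1e-7)$root
  list(t50 = root, censored = NA_character_, fit_window = c(tmin, tmax))
}

#' Fit a degradation curve and estimate its half-degradation time
#'
#' The central estimator of the package: selects a polynomial degree by the
#' significance-screened adjusted-R-squared rule ([select_degree()]) and
#' reads off the first time the fitted remaining-% curve crosses `level`
#' ([extract_t50()]), without extrapolating beyond the observed window.
#'
#' @param curve a [kinetic_curve()] of remaining-%.
#' @param max_degree,alpha,n_perm,perm_seed passed to [select_degree()].
#' @param level crossing level in percent remaining (default 50, i.e. t50).
#' @return An object of class `t50_fit` with `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `plot` and `simulate` methods.
#'   Fields include `degree`, `coefficients` (ascending, hour axis), `r2`,
#'   `adj_r2`, `f_pvalue`, `t50` (`NA` when censored), `censored` and
#'   `fit_window`.
#' @examples
#' tr <- logistic_trajectory(seq(0, 336, by = 24), t50 = 120)
#' cv <- simulate_kinetic_curve(tr, noise_sd = 0.03, seed = 7)
#' fit <- t50_fit(cv)
#' fit
#' coef(fit)
#' @export
t50_fit <- function(curve, max_degree = 6L, alpha = 0.05, level = 50,
                    n_perm = 499L, perm_seed = 1L) {
  sel <- select_degree(curve, max_degree = max_degree, alpha = alpha,
                       n_perm = n_perm, perm_seed = perm_seed)
  cr <- extract_t50(sel, level = level)
  structure(c(sel, list(t50 = cr$t50, censored = cr$censored,
                        fit_window = cr$fit_window, level = level,
                        curve = curve)),
            class = c("t50_fit", "poly_fit"))
}

#' @export
print.t50_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Polynomial degradation-kinetics fit: %s (%s)\n",
              x$curve$sample_id, x$curve$blend_label))
  cat(sprintf("  degree %d (of %d candidates), R2 = %.*g, adj R2 = %.*g, F p = %.3g\n",
              x$degree, nrow(x$selection), digits, x$r2, digits, x$adj_r2,
              x$f_pvalue))
  if (is.na(x$t50)) {
    cat(sprintf("  t%g: censored, %s h\n", x$level, x$censored))
  } else {
    cat(sprintf("  t%g = %.*g h (window %g..%g h)\n", x$level, digits,
                x$t50, x$fit_window[1], x$fit_window[2]))
  }
  invisible(x)
}

#' @export
summary.t50_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.t50_fit")
}

#' @export
print.summary.t50_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  family significance gate: p = %.3g (alpha = %g)\n",
              f$gate_pvalue, f$alpha))
  cat("\nCandidate degrees:\n")
  print(f$selection, row.names = FALSE, digits = 4)
  cat("\nCoefficients (hour axis, ascending):\n")
  print(f$coefficients)
  invisible(x)
}

#' @export
coef.t50_fit <- function(object, ...) object$coefficients

#' @export
predict.t50_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$times
  predict_poly(object, times)
}

#' @export
fitted.t50_fit <- function(object, ...) object$fitted

#' @export
residuals.t50_fit <- function(object, ...) object$residuals

#' @export
plot.t50_fit <- function(x, ...) {
  graphics::plot(x$curve$times, x$curve$values, pch = 16,
                 xlab = "time (h)", ylab = "remaining polymer area (%)",
                 main = sprintf("%s (%s)", x$curve$sample_id,
                                x$curve$blend_label), ...)
  tt <- seq(x$fit_window[1], x$fit_window[2], length.out = 200)
  graphics::lines(tt, predict_poly(x, tt), col = "firebrick", lwd = 2)
  graphics::abline(h = x$level, lty = 3)
  if (!is.na(x$t50)) graphics::abline(v = x$t50, lty = 2, col = "grey40")
  invisible(x)
}

#' @export
simulate.t50_fit <- function(object, nsim = 1, seed = NULL, ...) {
  sigma <- sqrt(sum(object$residuals^2) / (object$n - object$degree - 1))
  draw <- function() object$fitted + stats::rnorm(object$n, 0, sigma)
  sims <- if (is.null(seed)) replicate(nsim, draw())
  else withr::with_seed(seed, replicate(nsim, draw()))
  out <- as.data.frame(sims)
  names(out) <- paste0("sim_", seq_len(nsim))
  attr(out, "times") <- object$times
  out
}
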