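# Bivariate Morlet wavelet analysis of number strings.
#
# The position axis is treated as a spatial series with unit spacing; gap
# positions (encoded 0) enter the transform as-is. The continuous Morlet
# transform follows the standard FFT formulation (zero-padded to the next
# power of two, dyadic scale grid, cone of influence from the e-folding
# length). Coherence uses a boxcar smoothing operator: over position with a
# window proportional to scale, and over scale with a fixed 0.6-octave
# window. Significance is Monte-Carlo: surrogate series matching the
# originals' lengths, means and variances.

#' Parameters for bivariate wavelet analysis
#'
#' @param omega0 Morlet central angular frequency; 6 gives Fourier period
#'   ~= 1.033 x scale.
#' @param period_min,period_max Shortest/longest Fourier period analysed,
#'   in alignment positions.
#' @param suboctaves Voices per octave of the dyadic scale grid.
#' @param n_surrogates Number of surrogate pairs for significance testing.
#' @param sig_level_local Significance level for local (cell-wise) joint
#'   periods.
#' @param sig_level_avg Significance level for average-power periods.
#' @param surrogate_model `"white"` (default) or `"ar1"` surrogate null.
#' @param rng_seed Seed for the surrogate generator.
#' @return A list of class `wavelet_params`.
#' @export
wavelet_params <- function(omega0 = 6, period_min = 2, period_max = 256,
                           suboctaves = 20, n_surrogates = 100,
                           sig_level_local = 0.05, sig_level_avg = 0.1,
                           surrogate_model = c("white", "ar1"),
                           rng_seed = 1) {
  surrogate_model <- match.arg(surrogate_model)
  stopifnot(period_min > 0, period_min < period_max, suboctaves >= 1,
            n_surrogates >= 1,
            sig_level_local > 0, sig_level_local < 1,
            sig_level_avg > 0, sig_level_avg < 1)
  structure(list(omega0 = omega0, period_min = period_min,
                 period_max = period_max, suboctaves = suboctaves,
                 n_surrogates = n_surrogates,
                 sig_level_local = sig_level_local,
                 sig_level_avg = sig_level_avg,
                 surrogate_model = surrogate_model, rng_seed = rng_seed),
            class = "wavelet_params")
}

.fourier_factor <- function(omega0) 4 * pi / (omega0 + sqrt(2 + omega0^2))

.scale_grid <- function(n, params) {
  ff <- .fourier_factor(params$omega0)
  pmax_eff <- params$period_max
  if (pmax_eff > n) {
    warning("period_max (", pmax_eff, ") exceeds signal length (", n,
            "); clipped")
    pmax_eff <- n
  }
  s0 <- params$period_min / ff
  dj <- 1 / params$suboctaves
  J <- floor(log2(pmax_eff / params$period_min) * params$suboctaves)
  scales <- s0 * 2^((0:J) * dj)
  list(scales = scales, periods = ff * scales, ff = ff)
}

#' Continuous Morlet wavelet transform
#'
#' @param x Numeric vector, length >= 4; the mean is removed internally.
#' @param params A [wavelet_params()] object.
#' @return Object of class `cwt`: list with complex matrix `wave`
#'   (periods x positions), `periods`, `scales`, `coi` (per-position maximum
#'   trustworthy Fourier period), and `n`.
#' @export
morlet_cwt <- function(x, params = wavelet_params()) {
  x <- as.numeric(x); n <- length(x)
  if (n < 4L) stop("need at least 4 positions")
  g <- .scale_grid(n, params)
  xd <- x - mean(x)
  npad <- 2^ceiling(log2(n))
  fx <- stats::fft(c(xd, rep(0, npad - n)))
  k <- 0:(npad - 1)
  omega <- ifelse(k <= npad / 2, 2 * pi * k / npad, -2 * pi * (npad - k) / npad)
  pos <- omega > 0
  wave <- matrix(complex(real = 0), length(g$scales), n)
  for (j in seq_along(g$scales)) {
    s <- g$scales[j]
    daughter <- numeric(npad)
    daughter[pos] <- sqrt(2 * pi * s) * pi^(-0.25) *
      exp(-0.5 * (s * omega[pos] - params$omega0)^2)
    w <- stats::fft(fx * daughter, inverse = TRUE) / npad
    wave[j, ] <- w[seq_len(n)]
  }
  d <- pmin(seq_len(n) - 1, n - seq_len(n))
  coi <- g$ff / sqrt(2) * pmax(d, 1e-8)
  structure(list(wave = wave, periods = g$periods, scales = g$scales,
                 coi = coi, n = n, params = params),
            class = "cwt")
}

# Truncated boxcar moving average along a vector (odd window w).
.boxcar <- function(v, w) {
  if (w <= 1L) return(v)
  h <- w %/% 2L
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(0L, seq_len(n) - h - 1L)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

.boxcar_cols <- function(mat, w) {
  if (w <= 1L) return(mat)
  h <- w %/% 2L
  n <- nrow(mat)
  cs <- rbind(0, apply(mat, 2, cumsum))
  lo <- pmax(0L, seq_len(n) - h - 1L)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]) / (hi - lo)
}

# Smoothing operator S: boxcar over positions (window ~ scale) then over
# scales (fixed 0.6-octave window).
.smooth_wavelet <- function(mat, scales, suboctaves) {
  out <- mat
  for (j in seq_along(scales)) {
    out[j, ] <- .boxcar(mat[j, ], 2L * (floor(scales[j]) %/% 2L) + 1L)
  }
  m <- 2L * floor(0.3 * suboctaves) + 1L
  .boxcar_cols(out, m)
}

.coherence_from_waves <- function(wx, wy, scales, suboctaves) {
  inv_s <- 1 / scales
  px <- .smooth_wavelet(sweep(Mod(wx)^2, 1, inv_s, "*"), scales, suboctaves)
  py <- .smooth_wavelet(sweep(Mod(wy)^2, 1, inv_s, "*"), scales, suboctaves)
  wxy <- wx * Conj(wy)
  sre <- .smooth_wavelet(sweep(Re(wxy), 1, inv_s, "*"), scales, suboctaves)
  sim <- .smooth_wavelet(sweep(Im(wxy), 1, inv_s, "*"), scales, suboctaves)
  denom <- px * py
  coh <- (sre^2 + sim^2) / ifelse(denom > 0, denom, Inf)
  pmin(pmax(coh, 0), 1)  # matrix first: pmax/pmin keep its dim attributes
}

#' Cross-wavelet spectrum of two number strings
#'
#' Computes W_xy = W_x . conj(W_y): `cross_power` is its modulus
#' (a covariance analogue resolved by position and period) and `phase` its
#' argument, the local phase difference between the two strings.
#'
#' @param x,y Equal-length numeric vectors.
#' @param params A [wavelet_params()] object.
#' @return Object of class `cross_wavelet` with fields `positions`,
#'   `periods`, `cross_power`, `phase`, `coi`, the underlying complex
#'   transforms, and `params`.
#' @export
cross_wavelet <- function(x, y, params = wavelet_params()) {
  if (length(x) != length(y)) stop("length mismatch")
  cx <- morlet_cwt(x, params)
  cy <- morlet_cwt(y, params)
  wxy <- cx$wave * Conj(cy$wave)
  structure(list(positions = seq_len(cx$n), periods = cx$periods,
                 scales = cx$scales, coi = cx$coi,
                 wave_x = cx$wave, wave_y = cy$wave, wave_xy = wxy,
                 cross_power = Mod(wxy), phase = Arg(wxy),
                 params = params, n = cx$n),
            class = "cross_wavelet")
}

#' Wavelet coherence of two number strings
#'
#' Smoothed, normalized cross-spectrum magnitude
#' `|S(W_xy / s)|^2 / (S(|W_x|^2 / s) . S(|W_y|^2 / s))`, clipped to
#' \[0, 1\]: a local, scale-resolved correlation analogue. Without the
#' smoothing operator S this quantity degenerates to 1 everywhere.
#'
#' @inheritParams cross_wavelet
#' @return A `cross_wavelet` result additionally carrying `coherence`.
#' @export
wavelet_coherence <- function(x, y, params = wavelet_params()) {
  res <- cross_wavelet(x, y, params)
  res$coherence <- .coherence_from_waves(res$wave_x, res$wave_y, res$scales,
                                         params$suboctaves)
  res
}

# In-cone logical mask (periods x positions).
.cone_mask <- function(periods, coi) {
  outer(periods, coi, `<=`)
}

.surrogate_series <- function(template, model) {
  n <- length(template)
  mu <- mean(template); sdv <- stats::sd(template)
  if (model == "white" || sdv == 0) {
    return(stats::rnorm(n, mu, sdv))
  }
  fit <- tryCatch(stats::ar(template, order.max = 1, aic = FALSE,
                            method = "yule-walker"),
                  error = function(e) NULL)
  phi <- if (!is.null(fit) && length(fit$ar)) fit$ar[1] else 0
  phi <- max(-0.99, min(0.99, phi))
  z <- as.numeric(stats::arima.sim(list(ar = phi), n))
  mu + sdv * z / stats::sd(z)
}

#' Surrogate significance for joint periodicity
#'
#' Monte-Carlo test against a null of `n_surrogates` surrogate pairs with
#' the originals' lengths, means and variances. Coherence cells inside the
#' cone of influence are called significant when they exceed the
#' (1 - sig_level_local) quantile of surrogate coherence pooled per period;
#' average cross-power per period is significant when it exceeds the
#' (1 - sig_level_avg) quantile of the surrogate averages.
#'
#' @inheritParams cross_wavelet
#' @return A `cross_wavelet` result carrying, in addition to power, phase
#'   and coherence: `sig_local` (logical matrix), `avg_power` (per-period
#'   in-cone mean cross power), `avg_sig` (logical), and the per-period
#'   thresholds `coh_threshold`, `avg_threshold`.
#' @export
significance <- function(x, y, params = wavelet_params()) {
  if (params$n_surrogates < 20) {
    warning("fewer than 20 surrogates: significance quantiles are coarse")
  }
  res <- wavelet_coherence(x, y, params)
  params <- .clip_params(params, length(x))
  np <- length(res$periods)
  mask <- .cone_mask(res$periods, res$coi)
  res$avg_power <- vapply(seq_len(np), function(j) {
    idx <- which(mask[j, ])
    if (length(idx)) mean(res$cross_power[j, idx]) else NA_real_
  }, numeric(1))

  # thin in-cone positions so the pooled surrogate sample stays bounded
  pool_idx <- lapply(seq_len(np), function(j) {
    idx <- which(mask[j, ])
    if (!length(idx)) return(integer(0))
    idx[unique(round(seq(1, length(idx), length.out = min(25, length(idx)))))]
  })

  ns <- params$n_surrogates
  coh_pool <- vector("list", np)
  for (j in seq_len(np)) {
    coh_pool[[j]] <- matrix(NA_real_, ns, length(pool_idx[[j]]))
  }
  avg_null <- matrix(NA_real_, ns, np)

  .with_seed(params$rng_seed, {
    for (s in seq_len(ns)) {
      xs <- .surrogate_series(x, params$surrogate_model)
      ys <- .surrogate_series(y, params$surrogate_model)
      cxs <- morlet_cwt(xs, params)
      cys <- morlet_cwt(ys, params)
      wxy <- Mod(cxs$wave * Conj(cys$wave))
      coh <- .coherence_from_waves(cxs$wave, cys$wave, cxs$scales,
                                   params$suboctaves)
      for (j in seq_len(np)) {
        if (length(pool_idx[[j]])) {
          coh_pool[[j]][s, ] <- coh[j, pool_idx[[j]]]
          avg_null[s, j] <- mean(wxy[j, mask[j, ]])
        }
      }
    }
  })

  res$coh_threshold <- vapply(seq_len(np), function(j) {
    v <- as.vector(coh_pool[[j]])
    if (!length(v) || all(is.na(v))) return(Inf)
    stats::quantile(v, 1 - params$sig_level_local, na.rm = TRUE, names = FALSE)
  }, numeric(1))
  res$avg_threshold <- vapply(seq_len(np), function(j) {
    v <- avg_null[, j]
    if (all(is.na(v))) return(Inf)
    stats::quantile(v, 1 - params$sig_level_avg, na.rm = TRUE, names = FALSE)
  }, numeric(1))

  res$sig_local <- (res$coherence > res$coh_threshold) & mask
  res$avg_sig <- !is.na(res$avg_power) & (res$avg_power > res$avg_threshold)
  res
}

# morlet_cwt may warn about clipping once per call; surrogate loops would
# repeat it, so clip the params up front.
.clip_params <- function(params, n) {
  if (params$period_max > n) params$period_max <- n
  params
}

#' Full bivariate wavelet analysis
#'
#' Orchestrates [cross_wavelet()], [wavelet_coherence()] and
#' [significance()] into one complete result (the input for
#' [render_wavelet_plots()]).
#'
#' @inheritParams cross_wavelet
#' @return A complete `cross_wavelet` result.
#' @export
bivariate_wavelet <- function(x, y, params = wavelet_params()) {
  if (params$period_max > length(x)) {
    warning("period_max (", params$period_max, ") exceeds signal length (",
            length(x), "); clipped")
    params <- .clip_params(params, length(x))
  }
  significance(x, y, params)
}

#' Classify a phase difference
#'
#' Angles in (-pi/2, pi/2) are in-phase (conserved, synchronous regions);
#' angles in (pi/2, pi\] and \[-pi, -pi/2\] are out-of-phase.
#'
#' @param phase Numeric vector of angles in (-pi, pi\].
#' @return Character vector: `"in_phase"` or `"out_of_phase"`.
#' @export
phase_classification <- function(phase) {
  phase <- as.numeric(phase)
  if (any(phase > pi + 1e-9 | phase <= -pi - 1e-9)) {
    stop("phase angles must lie in (-pi, pi]")
  }
  ifelse(phase > -pi / 2 & phase < pi / 2, "in_phase", "out_of_phase")
}

#' @export
print.cross_wavelet <- function(x, ...) {
  cat("Bivariate Morlet wavelet result: ", x$n, " positions x ",
      length(x$periods), " periods (", format(min(x$periods), digits = 4),
      "-", format(max(x$periods), digits = 4), ")\n", sep = "")
  cat("fields: ", paste(intersect(c("cross_power", "phase", "coherence",
                                    "sig_local", "avg_power", "avg_sig"),
                                  names(x)), collapse = ", "), "\n", sep = "")
  invisible(x)
}
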