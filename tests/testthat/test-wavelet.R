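# Morlet transform, cross-spectrum, coherence, phase, significance.

fast_params <- function(...) {
  args <- utils::modifyList(list(suboctaves = 8, n_surrogates = 30),
                            list(...))
  do.call(wavelet_params, args)
}

test_that("the Morlet transform localizes known signals", {
  L <- 356
  t <- seq_len(L)
  p <- wavelet_params(suboctaves = 10)
  # pure cosine of period 32: modulus peaks at the nearest scale, mid-signal
  x <- cos(2 * pi * t / 32)
  cw <- morlet_cwt(x, p)
  mid <- which(cw$coi >= 64)                      # away from the cone
  peak_period <- cw$periods[which.max(rowMeans(Mod(cw$wave[, mid])))]
  expect_lt(abs(log2(peak_period / 32)), 0.11)    # within one voice or so

  # zero vector transforms to zero
  expect_equal(max(Mod(suppressWarnings(morlet_cwt(numeric(64), p))$wave)), 0)

  # delta spike: small-period modulus concentrates at the spike
  d <- numeric(L); d[L / 2] <- 1
  cd <- morlet_cwt(d, p)
  expect_equal(which.max(Mod(cd$wave[1, ])), L / 2)

  # FFT route equals direct time-domain convolution away from the edges
  set.seed(31)
  x <- rnorm(128)
  cw <- morlet_cwt(x, wavelet_params(period_max = 64, suboctaves = 4))
  for (j in c(8, 12, 15)) {          # scales comfortably above Nyquist
    for (t0 in c(40, 64, 90)) {
      expect_equal(cw$wave[j, t0],
                   oracle_morlet_point(x, cw$scales[j], t0),
                   tolerance = 1e-6)
    }
  }
})

test_that("period_max beyond the signal length is clipped with a warning", {
  expect_warning(cw <- morlet_cwt(rnorm(100), wavelet_params(period_max = 256)),
                 "clipped")
  expect_lte(max(cw$periods), 1.04 * 100)
})

test_that("the cross-spectrum has the analytic phase structure", {
  L <- 356; t <- seq_len(L)
  p <- wavelet_params(suboctaves = 8)
  x <- rand_numstring(L, seed = 12)
  # self-comparison: exactly real, non-negative, phase 0
  self <- cross_wavelet(x, x, p)
  expect_equal(max(abs(self$phase)), 0)
  expect_true(all(self$cross_power >= 0))

  # quarter-period shift of a sinusoid: phase ~ +/- pi/2 at that period
  P <- 32
  a <- cos(2 * pi * t / P)
  b <- cos(2 * pi * (t - P / 4) / P)
  cx <- cross_wavelet(a, b, p)
  j <- which.min(abs(cx$periods - P))
  mid <- which(cx$coi >= 2 * P)
  expect_lt(max(abs(abs(cx$phase[j, mid]) - pi / 2)), 0.15)

  # swapping arguments preserves power, negates phase
  y <- rand_numstring(L, seed = 13)
  xy <- cross_wavelet(x, y, p); yx <- cross_wavelet(y, x, p)
  expect_equal(xy$cross_power, yx$cross_power, tolerance = 1e-12)
  expect_equal(xy$phase[abs(xy$phase) < 3], -yx$phase[abs(xy$phase) < 3],
               tolerance = 1e-8)

  # positive rescaling of one input scales power, leaves phase
  x5 <- cross_wavelet(x, 5 * y, p)
  expect_equal(x5$cross_power, 5 * xy$cross_power, tolerance = 1e-10)
  expect_equal(x5$phase, xy$phase, tolerance = 1e-10)

  expect_error(cross_wavelet(x, y[-1], p), "mismatch")
})

test_that("coherence is a smoothed, bounded correlation analogue", {
  L <- 356
  x <- rand_numstring(L, seed = 14)
  p <- wavelet_params(suboctaves = 8)
  # linear dependence: coherence ~ 1 inside the cone
  res <- wavelet_coherence(x, 2 * x + 7, p)
  incone <- outer(res$periods, res$coi, `<=`)
  expect_gt(min(res$coherence[incone]), 0.99)
  expect_true(all(res$coherence >= 0 & res$coherence <= 1))

  # smoothing must be active: unsmoothed coherence would be identically 1
  set.seed(15)
  noise <- wavelet_coherence(rnorm(L), rnorm(L), p)
  expect_lt(min(noise$coherence), 0.2)

  # swap symmetry and amplitude invariance
  y <- rand_numstring(L, seed = 16)
  expect_equal(wavelet_coherence(x, y, p)$coherence,
               wavelet_coherence(y, x, p)$coherence, tolerance = 1e-10)
  expect_equal(wavelet_coherence(x, 3 * y, p)$coherence,
               wavelet_coherence(x, y, p)$coherence, tolerance = 1e-10)

  # a shared period stands out against drifting-phase surroundings
  t <- seq_len(L)
  set.seed(17)
  a <- cos(2 * pi * t / 16) + 0.6 * rnorm(L)
  b <- cos(2 * pi * t / 16) + 0.6 * rnorm(L)
  shared <- wavelet_coherence(a, b, p)
  j16 <- which.min(abs(shared$periods - 16))
  j64 <- which.min(abs(shared$periods - 64))
  mid <- which(shared$coi >= 64)
  expect_gt(mean(shared$coherence[j16, mid]), 0.8)
  expect_gt(mean(shared$coherence[j16, mid]),
            mean(shared$coherence[j64, mid]) + 0.2)
})

test_that("surrogate significance flags planted periodicity deterministically", {
  L <- 356; t <- seq_len(L)
  set.seed(18)
  x <- cos(2 * pi * t / 32) + 0.3 * rnorm(L)
  y <- cos(2 * pi * t / 32) + 0.3 * rnorm(L)
  p <- fast_params(n_surrogates = 60, rng_seed = 5)
  res <- bivariate_wavelet(x, y, p)
  j32 <- which.min(abs(res$periods - 32))
  expect_true(res$avg_sig[j32])
  expect_true(mean(res$sig_local[j32, res$coi >= 32]) > 0.5)

  res2 <- bivariate_wavelet(x, y, p)
  expect_identical(res$sig_local, res2$sig_local)
  expect_identical(res$avg_sig, res2$avg_sig)

  expect_warning(bivariate_wavelet(x, y, fast_params(n_surrogates = 5)),
                 "fewer than 20 surrogates")
})

test_that("phase angles classify into the stated in/out-of-phase ranges", {
  expect_equal(phase_classification(0), "in_phase")
  expect_equal(phase_classification(pi), "out_of_phase")
  expect_equal(phase_classification(-3 * pi / 4), "out_of_phase")
  expect_equal(phase_classification(c(-1.2, 1.2)), rep("in_phase", 2))
  expect_equal(phase_classification(pi / 2), "out_of_phase")  # boundary
  expect_error(phase_classification(4), "pi")
})

test_that("plots and matrices are written and the TSVs round-trip", {
  x <- rand_numstring(128, seed = 19)
  y <- rand_numstring(128, seed = 20)
  res <- bivariate_wavelet(x, y, fast_params(period_max = 64))
  out <- withr::local_tempdir()
  files <- render_wavelet_plots(res, out)
  expect_true(all(file.exists(files)))
  rt <- read_matrix_tsv(files[["coherence_tsv"]])
  expect_equal(rt$mat, res$coherence, tolerance = 1e-12)
  expect_equal(rt$periods, res$periods, tolerance = 1e-12)
  sig <- read_matrix_tsv(files[["sig_local_tsv"]])
  expect_equal(sig$mat == 1, unname(res$sig_local))

  # identical pair: phase image content is uniformly in-phase
  self <- bivariate_wavelet(x, x, fast_params(period_max = 64))
  expect_true(all(phase_classification(self$phase) == "in_phase"))
})
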