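# Correlation, average mutual information, box-counting dimension, and
# their aggregation into relatedness matrices.

test_that("lag autocorrelation follows the printed normalized-covariance form", {
  x <- rand_numstring(80, seed = 2)
  expect_equal(lag_autocorrelation(x, 0), 1.0)
  for (m in c(1, 3, 7)) {
    expect_equal(lag_autocorrelation(x, m), oracle_autocorrelation(x, m),
                 tolerance = 1e-14)
  }
  # stats::acf uses the same shared-mean, full-variance convention
  ref <- as.numeric(acf(x, lag.max = 5, plot = FALSE)$acf)
  expect_equal(vapply(0:5, function(m) lag_autocorrelation(x, m), numeric(1)),
               ref, tolerance = 1e-12)
  # alternating series: closed form R_1 = -(N - 1)/N
  N <- 200
  alt <- rep(c(1, -1), N / 2)
  expect_equal(lag_autocorrelation(alt, 1), -(N - 1) / N)
  expect_error(lag_autocorrelation(rep(3, 10), 1), "constant")
  expect_error(lag_autocorrelation(x, length(x)), "lag")
})

test_that("pairwise correlation hits the synchrony and mirror endpoints", {
  x <- rand_numstring(60, seed = 3)
  expect_equal(pair_correlation(x, x), 1.0)
  expect_equal(pair_correlation(x, 2 * mean(x) - x), -1.0)
  set.seed(4)
  long_a <- rnorm(5000); long_b <- rnorm(5000)
  expect_lt(abs(pair_correlation(long_a, long_b)), 0.05)
  expect_error(pair_correlation(x, rep(1, 60)), "constant")
  expect_error(pair_correlation(1:2, 1:2), "at least 3")
})

test_that("mutual information matches plug-in entropy identities", {
  x <- rand_numstring(200, "volume", gap_frac = 0.1, seed = 5)
  # MI(X, X) = H(X)
  expect_equal(average_mutual_information(x, x), oracle_entropy(x),
               tolerance = 1e-12)
  # constant partner carries no information
  expect_equal(average_mutual_information(x, rep(0, length(x))), 0)
  # hand-computed 4-position toy: joint counts (a,a):2, (a,b):1, (b,b):1
  xs <- c("a", "a", "a", "b"); ys <- c("a", "a", "b", "b")
  hand <- 0.5 * log(0.5 / (0.75 * 0.5)) + 0.25 * log(0.25 / (0.75 * 0.5)) +
    0.25 * log(0.25 / (0.25 * 0.5))
  expect_equal(average_mutual_information(xs, ys), hand, tolerance = 1e-14)
  # bits are nats / log(2)
  expect_equal(average_mutual_information(xs, ys, units = "bits"),
               hand / log(2), tolerance = 1e-14)
  expect_error(average_mutual_information(numeric(0), numeric(0)), "empty")
})

test_that("box-counting dimension reproduces the exact grid cases", {
  # all points in a single cell
  expect_equal(box_counting_dimension(c(1, 1.05), c(2, 2.02)), 0)
  # clean diagonal: 10 occupied cells
  expect_equal(box_counting_dimension(0:9, 0:9), 1.0)
  # full grid: all 100 cells
  g <- expand.grid(x = 0:9, y = 0:9)
  expect_equal(box_counting_dimension(g$x, g$y), 2.0)
  # degenerate zero range
  expect_warning(d0 <- box_counting_dimension(rep(2, 5), rep(2, 5)),
                 "zero value range")
  expect_equal(d0, 0)
  # offset-averaged variant stays in range and differs smoothly
  x <- rand_numstring(150, seed = 6); y <- rand_numstring(150, seed = 7)
  d_plain <- box_counting_dimension(x, y)
  d_off <- box_counting_dimension(x, y, offsets = TRUE)
  expect_true(d_off >= 0 && d_off <= 2)
  expect_lt(abs(d_off - d_plain), 0.3)
})

test_that("each measure equals its brute-force oracle on random fixtures", {
  set.seed(8)
  for (i in 1:30) {
    x <- rand_numstring(120, "volume", gap_frac = 0.1, seed = 100 + i)
    y <- rand_numstring(120, "volume", gap_frac = 0.1, seed = 200 + i)
    expect_equal(pair_correlation(x, y), oracle_pearson(x, y),
                 tolerance = 1e-12)
    expect_equal(average_mutual_information(x, y), oracle_mi(x, y),
                 tolerance = 1e-12)
    expect_equal(box_counting_dimension(x, y), oracle_boxdim(x, y),
                 tolerance = 1e-12)
  }
})

test_that("measures are symmetric and MI is bounded by marginal entropies", {
  for (i in 1:10) {
    x <- rand_numstring(150, "pI_25C", gap_frac = 0.05, seed = 300 + i)
    y <- rand_numstring(150, "pI_25C", gap_frac = 0.05, seed = 400 + i)
    expect_equal(pair_correlation(x, y), pair_correlation(y, x))
    expect_equal(average_mutual_information(x, y),
                 average_mutual_information(y, x))
    expect_equal(box_counting_dimension(x, y), box_counting_dimension(y, x))
    mi <- average_mutual_information(x, y)
    expect_gte(mi, 0)
    expect_lte(mi, min(oracle_entropy(x), oracle_entropy(y)) + 1e-12)
    # self-scatter sits on the diagonal: at most 10 occupied cells
    expect_lte(box_counting_dimension(x, x), 1 + 1e-12)
  }
})

test_that("relatedness tables aggregate per-pair measures across properties", {
  aln <- alignment_set(c("u", "v", "w"),
                       c("GAVLKDERSTYWFPHQCMNI",
                         "GAVLKDERSTYWFPHQCMNI",
                         "GTVLKAERSMYWFPHECMNV"))
  rel <- relatedness_table(aln, "correlation")
  expect_equal(rel$mean["u", "v"], 1.0)
  expect_equal(rel$sd["u", "v"], 0)
  expect_equal(sum(upper.tri(rel$mean)), 3L)
  expect_equal(rel$mean, t(rel$mean))
  expect_equal(rel$properties, default_properties())

  bd <- relatedness_table(aln, "box_dimension")
  expect_equal(bd$properties, c("volume", "pI_25C", "solubility"))

  enc <- encode_alignment(aln, c("volume"))
  expect_error(relatedness_table(enc, "correlation",
                                 properties = c("volume", "solubility")),
               "property 'solubility'")

  f <- withr::local_tempfile(fileext = ".tsv")
  paths <- write_relatedness_tsv(rel, f)
  wide <- readLines(f)
  expect_match(wide[2], "1\\.000 ± 0\\.000")
  long <- read.delim(paths[2])
  expect_equal(nrow(long), 3L * length(rel$properties))
})

test_that("mean correlation declines as substitution load grows", {
  levels <- c(0, 5, 20, 80)
  means <- sapply(levels, function(k) {
    mean(sapply(1:12, function(s) {
      fam <- evolve_family("(root0,desc)", root_length = 356,
                           substitutions = c(desc = k), seed = 1000 + 13 * s + k)
      enc <- encode_alignment(fam$alignment, "volume")
      pair_correlation(enc[["root0"]][["volume"]], enc[["desc"]][["volume"]])
    }))
  })
  expect_true(all(diff(means) < 0))
  expect_equal(means[1], 1.0)
})
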