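# Pairwise relatedness measures between number strings: correlation,
# average mutual information, and box-counting dimension, aggregated across
# physico-chemical properties into Table-style matrices.

#' Lag-m autocorrelation of one number string
#'
#' The normalized lag-m autocovariance
#' \deqn{R_m = \frac{\sum_{t=1}^{N-m} (x_t - \bar x)(x_{t+m} - \bar x)}
#'                  {\sum_{t=1}^{N} (x_t - \bar x)^2}}
#' with the overall mean shared between both sums (the 1/N factors cancel).
#' Ranges over \[-1, 1\]; `m = 0` gives exactly 1.
#'
#' @param x Numeric vector, not constant.
#' @param m Integer lag, `0 <= m < length(x)`.
#' @return Scalar autocorrelation.
#' @export
lag_autocorrelation <- function(x, m) {
  x <- as.numeric(x); n <- length(x)
  if (m < 0 || m >= n) stop("lag must satisfy 0 <= m < length(x)")
  xb <- mean(x)
  denom <- sum((x - xb)^2)
  if (denom == 0) stop("autocorrelation undefined for a constant string")
  idx <- seq_len(n - m)
  sum((x[idx] - xb) * (x[idx + m] - xb)) / denom
}

#' Pairwise correlation between two taxa's number strings
#'
#' Pearson product-moment correlation of two equal-length number strings at
#' lag 0: +1 for perfect synchrony, -1 for exact mirror images about the
#' mean, near 0 for unrelated strings.
#'
#' @param x,y Equal-length numeric vectors (length >= 3), neither constant.
#' @return Scalar in \[-1, 1\].
#' @export
pair_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 positions")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant string")
  }
  stats::cor(x, y)
}

# Plug-in Shannon entropy of a probability vector (zero cells dropped).
.shannon <- function(p, base) {
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

#' Average mutual information between two number strings
#'
#' Treats each distinct encoded value (including the 0 gap code) as a
#' categorical symbol, builds the joint empirical frequency table over
#' aligned positions, and returns the plug-in estimate
#' `MI = H(X) + H(Y) - H(X, Y)`.
#'
#' @param x,y Equal-length vectors (numeric or character), nonempty.
#' @param units `"nats"` (natural log, default) or `"bits"`.
#' @return Non-negative scalar.
#' @export
average_mutual_information <- function(x, y, units = c("nats", "bits")) {
  units <- match.arg(units)
  base <- if (units == "bits") 2 else exp(1)
  if (length(x) != length(y)) stop("length mismatch")
  if (!length(x)) stop("empty input")
  fx <- factor(as.vector(x)); fy <- factor(as.vector(y))
  joint <- table(fx, fy) / length(x)
  hx <- .shannon(rowSums(joint), base)
  hy <- .shannon(colSums(joint), base)
  hxy <- .shannon(as.vector(joint), base)
  hx + hy - hxy
}

# Bin index of values on [lo, lo + 10*w): half-open bins, last bin closed.
.box_bin <- function(v, lo, w) {
  i <- floor((v - lo) / w) + 1L
  pmin(i, 10L)
}

#' Box-counting dimension of a pairwise scatter
#'
#' Plots the points (x_i, y_i), overlays a 10 x 10 grid spanning the common
#' value range of both strings on both axes (bins half-open, last bin
#' closed), counts occupied cells N, and returns `log(N) / log(10)`:
#' 0 when all points share one cell, 1 for a clean diagonal, 2 when every
#' cell is hit. Values near 1 indicate near-identity between taxa; values
#' approaching 2 indicate independence.
#'
#' @param x,y Equal-length numeric vectors.
#' @param offsets If `TRUE`, average the occupied-cell count over a 5 x 5
#'   set of sub-cell grid offsets to mitigate quantization error from
#'   arbitrary grid placement (off by default; the plain anchored grid is
#'   the reference behaviour).
#' @return Scalar in \[0, 2\].
#' @export
box_counting_dimension <- function(x, y, offsets = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("length mismatch")
  if (!length(x)) stop("empty input")
  lo <- min(x, y); hi <- max(x, y)
  if (hi == lo) {
    warning("zero value range; box-counting dimension set to 0")
    return(0)
  }
  w <- (hi - lo) / 10
  if (!offsets) {
    n_occ <- nrow(unique(cbind(.box_bin(x, lo, w), .box_bin(y, lo, w))))
  } else {
    sub <- (0:4) / 5 * w
    counts <- outer(sub, sub, Vectorize(function(ox, oy) {
      ix <- floor((x - (lo - ox)) / w)
      iy <- floor((y - (lo - oy)) / w)
      nrow(unique(cbind(ix, iy)))
    }))
    n_occ <- mean(counts)
  }
  log(n_occ) / log(10)
}

# Default property sets per measure: the five-property set for correlation
# and AMI; volume, isoelectric point and solubility for box dimension.
.measure_default_properties <- function(measure) {
  switch(measure,
         box_dimension = c("volume", "pI_25C", "solubility"),
         default_properties())
}

#' Aggregate a relatedness measure across properties into a taxon matrix
#'
#' For every taxon pair, computes one relatedness measure per property and
#' reports the mean and sample standard deviation across properties — the
#' layout of the published overall-relatedness tables.
#'
#' @param encoded An `encoded_set` from [encode_alignment()], or an
#'   `alignment_set` (encoded internally).
#' @param measure `"correlation"`, `"ami"`, or `"box_dimension"`.
#' @param properties Property names; defaults to the five-property set for
#'   correlation and AMI and to volume/pI/solubility for box dimension.
#' @param units AMI units, passed to [average_mutual_information()].
#' @return Object of class `relatedness_matrix`: list with `measure`,
#'   `labels`, `mean`, `sd` (symmetric matrices), `properties`, and `values`
#'   (taxon x taxon x property array of the per-property measures).
#' @export
relatedness_table <- function(encoded,
                              measure = c("correlation", "ami", "box_dimension"),
                              properties = NULL, units = "nats") {
  measure <- match.arg(measure)
  if (inherits(encoded, "alignment_set")) {
    props <- if (is.null(properties)) .measure_default_properties(measure) else properties
    encoded <- encode_alignment(encoded, props)
  }
  if (!inherits(encoded, "encoded_set")) stop("need an encoded_set or alignment_set")
  if (is.null(properties)) properties <- .measure_default_properties(measure)
  taxa <- attr(encoded, "taxa")
  for (t in taxa) for (p in properties) {
    if (is.null(encoded[[t]][[p]])) {
      stop("missing encoded entry for taxon '", t, "', property '", p, "'")
    }
  }
  fun <- switch(measure,
                correlation = pair_correlation,
                ami = function(a, b) average_mutual_information(a, b, units = units),
                box_dimension = box_counting_dimension)
  n <- length(taxa)
  vals <- array(NA_real_, c(n, n, length(properties)),
                dimnames = list(taxa, taxa, properties))
  for (pi in seq_along(properties)) {
    p <- properties[pi]
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j) {
        v <- fun(encoded[[taxa[i]]][[p]], encoded[[taxa[j]]][[p]])
        vals[i, j, pi] <- v; vals[j, i, pi] <- v
      } else if (i == j) {
        vals[i, i, pi] <- NA_real_
      }
    }
  }
  mn <- apply(vals, c(1, 2), mean)
  sdev <- apply(vals, c(1, 2), stats::sd)
  structure(list(measure = measure, labels = taxa, mean = mn, sd = sdev,
                 properties = properties, values = vals),
            class = "relatedness_matrix")
}

#' @export
print.relatedness_matrix <- function(x, digits = 3, ...) {
  cat("Relatedness matrix (", x$measure, "), aggregated over ",
      length(x$properties), " properties: ",
      paste(x$properties, collapse = ", "), "\n", sep = "")
  n <- length(x$labels)
  cells <- matrix("", n, n, dimnames = list(x$labels, x$labels))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      cells[i, j] <- sprintf("%.*f ± %.*f", digits, x$mean[i, j],
                             digits, x$sd[i, j])
    }
  }
  print(as.data.frame(cells), right = TRUE)
  invisible(x)
}

#' Write a relatedness matrix as TSV
#'
#' Emits two files: `<path>` with the upper-triangle "mean ± sd" layout of
#' the published tables, and `<path base>_long.tsv` with machine-readable
#' rows (taxon_a, taxon_b, property, value).
#'
#' @param x A `relatedness_matrix`.
#' @param path Output path for the wide table.
#' @return Character vector of the two paths written, invisibly.
#' @export
write_relatedness_tsv <- function(x, path) {
  n <- length(x$labels)
  cells <- matrix("", n, n, dimnames = list(x$labels, x$labels))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      cells[i, j] <- sprintf("%.3f ± %.3f", x$mean[i, j], x$sd[i, j])
    }
  }
  wide <- data.frame(taxon = x$labels, cells, check.names = FALSE)
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  long <- do.call(rbind, lapply(seq_along(x$properties), function(pi) {
    p <- x$properties[pi]
    idx <- which(upper.tri(x$mean), arr.ind = TRUE)
    data.frame(taxon_a = x$labels[idx[, 1]], taxon_b = x$labels[idx[, 2]],
               property = p, value = x$values[cbind(idx, pi)])
  }))
  long_path <- sub("\\.tsv$", "", path)
  long_path <- paste0(long_path, "_long.tsv")
  utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, long_path))
}

#' Mean-correlation distance matrix between taxa
#'
#' Convenience bridge for correlation-based trees: the per-pair mean
#' correlation across properties mapped through [similarity_to_distance()].
#'
#' @param encoded An `encoded_set` or `alignment_set`.
#' @param properties Property names (default five-property set).
#' @return Symmetric distance matrix with taxon dimnames.
#' @export
correlation_distance_matrix <- function(encoded, properties = default_properties()) {
  rel <- relatedness_table(encoded, "correlation", properties)
  mn <- rel$mean
  diag(mn) <- 1
  d <- similarity_to_distance(pmin(1, pmax(-1, mn)))
  n <- length(rel$labels)
  d <- matrix(d, n, n, dimnames = list(rel$labels, rel$labels))
  diag(d) <- 0
  d
}
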