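# The four standard renderings of a bivariate wavelet result: average
# power, phase-difference image, coherence map, and cross-power map.

.heat_palette <- function(n = 64) {
  grDevices::colorRampPalette(c("darkblue", "blue", "cyan", "green",
                                "yellow", "orange", "red"))(n)
}

# Phase palette: in-phase angles (-pi/2, pi/2) in green-yellow shades,
# out-of-phase in blue (negative side) and red (positive side).
.phase_palette <- function(nbreaks = 64) {
  mids <- seq(-pi, pi, length.out = nbreaks + 1)
  mids <- (mids[-1] + mids[-length(mids)]) / 2
  blue <- grDevices::colorRampPalette(c("darkblue", "lightblue"))
  grnyel <- grDevices::colorRampPalette(c("greenyellow", "green4",
                                          "yellow"))
  red <- grDevices::colorRampPalette(c("salmon", "darkred"))
  cols <- character(length(mids))
  iblue <- mids <= -pi / 2
  iin <- mids > -pi / 2 & mids < pi / 2
  ired <- mids >= pi / 2
  cols[iblue] <- blue(sum(iblue))
  cols[iin] <- grnyel(sum(iin))
  cols[ired] <- red(sum(ired))
  list(breaks = seq(-pi, pi, length.out = nbreaks + 1), cols = cols)
}

.draw_coi <- function(res) {
  graphics::lines(res$positions, log2(pmin(res$coi, max(res$periods))),
                  lty = 2, col = "black")
}

.draw_arrows <- function(res, step_x = 12, step_t = 6) {
  if (is.null(res$sig_local)) return(invisible())
  idx <- which(res$sig_local, arr.ind = TRUE)
  if (!nrow(idx)) return(invisible())
  keep <- idx[, 1] %% step_t == 0 & idx[, 2] %% step_x == 0
  idx <- idx[keep, , drop = FALSE]
  if (!nrow(idx)) return(invisible())
  usr <- graphics::par("usr")
  len <- (usr[2] - usr[1]) / 50
  a <- res$phase[idx]
  x0 <- res$positions[idx[, 2]]
  y0 <- log2(res$periods)[idx[, 1]]
  graphics::arrows(x0 - len * cos(a) / 2, y0 - len * sin(a) / 8,
                   x0 + len * cos(a) / 2, y0 + len * sin(a) / 8,
                   length = 0.04, col = "black")
}

.image_panel <- function(res, z, main, col, breaks = NULL, legend = TRUE) {
  args <- list(res$positions, log2(res$periods), t(z), col = col,
               xlab = "alignment position", ylab = "Fourier period",
               yaxt = "n", main = main)
  if (!is.null(breaks)) args$breaks <- breaks
  do.call(graphics::image, args)
  at <- pretty(log2(res$periods))
  graphics::axis(2, at = at, labels = 2^at)
  .draw_coi(res)
}

#' Render the four standard wavelet plots and matrix TSVs
#'
#' Writes (A) the average cross-power profile with significance dots,
#' (B) the phase-difference image (green/yellow in-phase, blue/red
#' out-of-phase), (C) the coherence map with significance contours and
#' phase arrows, and (D) the cross-power map with arrows; plus TSV exports
#' of the cross-power, coherence, phase and local-significance matrices.
#'
#' @param res A complete `cross_wavelet` result from [bivariate_wavelet()].
#' @param out_dir Output directory (created if absent).
#' @param format `"png"` or `"svg"`.
#' @param prefix File-name prefix.
#' @return Named character vector of files written, invisibly.
#' @export
render_wavelet_plots <- function(res, out_dir, format = c("png", "svg"),
                                 prefix = "wavelet") {
  format <- match.arg(format)
  stopifnot(inherits(res, "cross_wavelet"))
  if (is.null(res$coherence) || is.null(res$sig_local)) {
    stop("need a complete result from bivariate_wavelet()")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dev_open <- function(p) {
    if (format == "png") grDevices::png(p, width = 900, height = 600)
    else grDevices::svg(p, width = 9, height = 6)
  }
  fp <- function(nm) file.path(out_dir, sprintf("%s_%s.%s", prefix, nm, format))
  files <- c(avg_power = fp("avg_power"), phase = fp("phase"),
             coherence = fp("coherence"), cross_power = fp("cross_power"))

  dev_open(files["avg_power"])
  ok <- !is.na(res$avg_power)
  graphics::plot(res$avg_power[ok], log2(res$periods[ok]), type = "l",
                 xlab = "average cross-wavelet power",
                 ylab = "Fourier period", yaxt = "n",
                 main = "Average cross-wavelet power")
  at <- pretty(log2(res$periods[ok]))
  graphics::axis(2, at = at, labels = 2^at)
  sig <- ok & res$avg_sig
  graphics::points(res$avg_power[sig], log2(res$periods[sig]),
                   pch = 19, col = "red")
  grDevices::dev.off()

  pal <- .phase_palette()
  dev_open(files["phase"])
  .image_panel(res, res$phase, "Phase difference", pal$cols, pal$breaks)
  grDevices::dev.off()

  dev_open(files["coherence"])
  .image_panel(res, res$coherence, "Wavelet coherence", .heat_palette(),
               seq(0, 1, length.out = 65))
  graphics::contour(res$positions, log2(res$periods), t(res$sig_local + 0),
                    levels = 0.5, drawlabels = FALSE, col = "white",
                    add = TRUE)
  .draw_arrows(res)
  grDevices::dev.off()

  dev_open(files["cross_power"])
  .image_panel(res, res$cross_power, "Cross-wavelet power", .heat_palette())
  .draw_arrows(res)
  grDevices::dev.off()

  mats <- c(cross_power = "cross_power", coherence = "coherence",
            phase = "phase", sig_local = "sig_local")
  tsvs <- character(0)
  for (nm in names(mats)) {
    p <- file.path(out_dir, sprintf("%s_%s.tsv", prefix, nm))
    write_matrix_tsv(res[[mats[[nm]]]], res$periods, res$positions, p)
    tsvs[paste0(nm, "_tsv")] <- p
  }
  ap <- file.path(out_dir, sprintf("%s_avg_power.tsv", prefix))
  utils::write.table(
    data.frame(period = res$periods, avg_power = res$avg_power,
               significant = res$avg_sig),
    ap, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(files, tsvs, avg_power_tsv = ap))
}

#' @export
plot.cross_wavelet <- function(x, which = c("coherence", "cross_power",
                                            "phase", "avg_power"), ...) {
  which <- match.arg(which)
  if (which == "avg_power") {
    ok <- !is.na(x$avg_power)
    graphics::plot(x$avg_power[ok], log2(x$periods[ok]), type = "l",
                   xlab = "average cross-wavelet power",
                   ylab = "log2 Fourier period", ...)
    return(invisible(x))
  }
  if (which == "phase") {
    pal <- .phase_palette()
    .image_panel(x, x$phase, "Phase difference", pal$cols, pal$breaks)
  } else if (which == "coherence") {
    if (is.null(x$coherence)) stop("no coherence field; run wavelet_coherence()")
    .image_panel(x, x$coherence, "Wavelet coherence", .heat_palette(),
                 seq(0, 1, length.out = 65))
  } else {
    .image_panel(x, x$cross_power, "Cross-wavelet power", .heat_palette())
  }
  invisible(x)
}

#' Plot per-position conservation profile
#'
#' Mean property value across taxa versus alignment position with a +/- sd
#' scatter band: flat bands mark conserved domains, wide bands mutable
#' regions.
#'
#' @param pv Data frame from [positional_variability()].
#' @param ... Passed to [graphics::plot()].
#' @return `pv`, invisibly.
#' @export
plot_positional_variability <- function(pv, ...) {
  graphics::plot(pv$position, pv$mean, type = "l",
                 xlab = "alignment position", ylab = "property value", ...)
  graphics::polygon(c(pv$position, rev(pv$position)),
                    c(pv$mean + pv$sd, rev(pv$mean - pv$sd)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(pv$position, pv$mean)
  invisible(pv)
}
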