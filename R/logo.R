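#' Letter heights of a sequence logo
#'
#' Standard information-content scaling: the letter for base `b` at
#' position `i` is drawn with height `f(b,i) * IC_i` bits, so a uniform
#' column has empty stacks and a consensus-only column a single
#' (near-)full-height letter.
#'
#' @param profile a `motif_profile`.
#' @return 4 x L numeric matrix of heights in bits (rows A, C, G, T).
#' @export
logo_heights <- function(profile) {
  f <- pwm_frequencies(profile)
  ic <- information_content(profile)$per_position
  sweep(f, 2L, ic, `*`)
}

LOGO_COLORS <- c(A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839")

#' Render a sequence logo to PNG or SVG
#'
#' Stacked-letter logo with one stack per profile position; letters are
#' stacked smallest-first and scaled to their information contribution
#' (see [logo_heights()]). The format follows the file extension
#' (`.png` or `.svg`).
#'
#' @param profile a `motif_profile`.
#' @param path output file ending in `.png` or `.svg`.
#' @param width,height device size in inches.
#' @return invisibly, the height matrix used.
#' @export
render_logo <- function(profile, path, width = 7, height = 2.5) {
  h <- logo_heights(profile)
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop("cannot write logo: directory does not exist: ",
                    dirname(path))
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    grDevices::png(path, width = width, height = height, units = "in",
                   res = 150)
  } else if (ext == "svg") {
    grDevices::svg(path, width = width, height = height)
  } else {
    stop("unsupported logo format: .", ext)
  }
  op <- graphics::par(mar = c(2.5, 3, 0.5, 0.5))
  on.exit({
    graphics::par(op)          # restore before closing, while the device
    grDevices::dev.off()       # is still current
  })
  L <- ncol(h)
  graphics::plot(NA, xlim = c(0.5, L + 0.5), ylim = c(0, 2), xlab = "",
                 ylab = "bits", xaxt = "n", las = 1, bty = "l")
  graphics::axis(1, at = seq_len(L), cex.axis = 0.8)
  for (i in seq_len(L)) {
    ord <- order(h[, i])            # smallest letters at the bottom
    y0 <- 0
    for (b in ord) {
      hb <- h[b, i]
      if (hb < 1e-3) next
      base <- DNA_BASES[b]
      cex <- hb / graphics::strheight(base, cex = 1)
      graphics::text(i, y0 + hb / 2, base, col = LOGO_COLORS[base],
                     cex = cex, font = 2)
      y0 <- y0 + hb
    }
  }
  invisible(h)
}
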