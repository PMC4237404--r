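#' Plot a polar map as a bull's-eye
#'
#' Draws each (slice, sector) cell as a filled annulus segment, apex at the
#' centre and base at the rim, with the fibrous-ring annulus hatched grey.
#' Voltage maps use the package colour scale; transmurality maps a
#' white-to-dark-red ramp; class maps one colour per class. The optional
#' 17-segment overlay is purely graphical - quantities are always computed
#' on the raw grid.
#'
#' @param map A [polar_map()].
#' @param main Plot title.
#' @param segments17 Draw the conventional 17-segment border overlay
#'   (default `FALSE`).
#' @return Invisibly, `map`.
#' @export
plot_bullseye <- function(map, main = map$kind, segments17 = FALSE) {
  stopifnot(inherits(map, "polar_map"))
  op <- graphics::par(mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(-1.05, 1.05), ylim = c(-1.05, 1.05),
                 asp = 1, axes = FALSE, xlab = "", ylab = "", main = main)
  r_in <- (1 - map$annulus_fraction)
  cols <- bullseye_colours(map)
  for (i in seq_len(map$n_slices)) {
    for (j in seq_len(map$n_sectors)) {
      a <- seq((j - 1), j, length.out = 8) * 2 * pi / map$n_sectors
      r0 <- (i - 1) / map$n_slices * r_in
      r1 <- i / map$n_slices * r_in
      graphics::polygon(c(r0 * cos(a), rev(r1 * cos(a))),
                        c(r0 * sin(a), rev(r1 * sin(a))),
                        col = cols[i, j], border = NA)
    }
  }
  a <- seq(0, 2 * pi, length.out = 180)
  graphics::polygon(c(r_in * cos(a), rev(cos(a))),
                    c(r_in * sin(a), rev(sin(a))),
                    col = "grey70", border = "grey40")
  if (segments17) {
    for (r in c(0.35, 0.7, 1) * r_in) {
      graphics::lines(r * cos(a), r * sin(a), col = "black", lwd = 0.5)
    }
    for (k in 0:5) {
      graphics::segments(0.35 * r_in * cos(k * pi / 3),
                         0.35 * r_in * sin(k * pi / 3),
                         r_in * cos(k * pi / 3), r_in * sin(k * pi / 3),
                         lwd = 0.5)
    }
  }
  invisible(map)
}

bullseye_colours <- function(map) {
  v <- map$values
  out <- matrix("grey90", map$n_slices, map$n_sectors)
  if (map$kind %in% c("unipolar_mV", "bipolar_mV")) {
    sc <- noga_colour_scale(if (map$kind == "unipolar_mV") "unipolar" else "bipolar")
    rgb <- voltage_to_rgb(as.vector(v), sc)
    ok <- stats::complete.cases(rgb)
    out[ok] <- grDevices::rgb(rgb[ok, 1], rgb[ok, 2], rgb[ok, 3])
  } else if (map$kind == "transmurality") {
    ramp <- grDevices::colorRamp(c("white", "orange", "darkred"))
    ok <- is.finite(v)
    cc <- ramp(clamp(v[ok], 0, 1)) / 255
    out[ok] <- grDevices::rgb(cc[, 1], cc[, 2], cc[, 3])
  } else {
    lev <- attr(map, "levels")
    pal <- c("steelblue", "gold", "yellowgreen", "firebrick")[seq_along(lev)]
    if (lev[1] == "transmural" || lev[length(lev)] == "transmural") {
      pal <- grDevices::hcl.colors(length(lev), "Zissou 1")
    }
    ok <- is.finite(v)
    out[ok] <- pal[v[ok]]
  }
  out[!map$valid] <- "grey90"
  out
}
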