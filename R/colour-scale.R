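#' Voltage colour scale for rendered polar maps
#'
#' The documented ordered list of (voltage, colour) control points used when
#' rendering voltage polar maps to RGB rasters, following the conventional
#' colour coding of endocardial maps: red for the lowest band (infarct /
#' transmural scar), yellow and green through the intermediate band, blue
#' and violet for normal tissue. Colours between control points are linear
#' interpolations in RGB space; voltages at or beyond the first/last control
#' point take the end colour.
#'
#' @param kind `"bipolar"` (control voltages 0, 0.8, 1.35, 1.9, 2.6 mV) or
#'   `"unipolar"` (0, 5, 10, 15, 25 mV).
#' @return An object of class `colour_scale`: data frame with columns
#'   `voltage_mV`, `r`, `g`, `b` (channels in `[0, 1]`).
#' @export
noga_colour_scale <- function(kind = c("bipolar", "unipolar")) {
  kind <- match.arg(kind)
  v <- if (kind == "bipolar") c(0, 0.8, 1.35, 1.9, 2.6) else c(0, 5, 10, 15, 25)
  sc <- data.frame(
    voltage_mV = v,
    r = c(1, 1, 0, 0, 0.6),
    g = c(0, 1, 1, 0, 0),
    b = c(0, 0, 0, 1, 0.8)
  )
  structure(sc, class = c("colour_scale", "data.frame"), kind = kind)
}

#' Map voltages to RGB along a colour scale
#'
#' @param voltage Numeric vector of voltages (mV); `NA` yields `NA` channels.
#' @param scale A [noga_colour_scale()].
#' @return Matrix with columns `r`, `g`, `b`.
#' @export
voltage_to_rgb <- function(voltage, scale = noga_colour_scale("bipolar")) {
  stopifnot(inherits(scale, "colour_scale"))
  sapply(c("r", "g", "b"), function(ch) {
    stats::approx(scale$voltage_mV, scale[[ch]], xout = voltage, rule = 2)$y
  })
}

#' Recover voltages from an RGB raster image
#'
#' Inverts the rendering colour scale: each pixel is projected onto the
#' nearest point of the piecewise-linear colour polyline in RGB space and
#' assigned the linearly interpolated voltage of that point. Pixels farther
#' than `tol` (Euclidean RGB distance) from every point of the polyline -
#' annotation overlays, background, the fibrous-ring marking - are invalid
#' rather than guessed.
#'
#' @param image Either an `h x w x 3` array of RGB channels in `[0, 1]` (as
#'   returned by `png::readPNG`) or the path of a PNG file.
#' @param scale The [noga_colour_scale()] the image was rendered with.
#' @param tol Maximum RGB distance to the scale polyline (default 0.1).
#' @return List with matrices `values` (voltage, `NA` where invalid) and
#'   `valid`.
#' @export
rgb_to_voltage <- function(image, scale = noga_colour_scale("bipolar"),
                           tol = 0.1) {
  stopifnot(inherits(scale, "colour_scale"))
  if (is.character(image)) image <- png::readPNG(image)
  if (length(dim(image)) != 3L || dim(image)[3] < 3L) {
    stop("`image` must be an RGB array (h x w x >=3)", call. = FALSE)
  }
  h <- dim(image)[1]; w <- dim(image)[2]
  px <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
              as.vector(image[, , 3]))
  ctrl <- as.matrix(scale[, c("r", "g", "b")])
  volt <- scale$voltage_mV

  best_d2 <- rep(Inf, nrow(px))
  best_v <- rep(NA_real_, nrow(px))
  for (s in seq_len(nrow(ctrl) - 1L)) {
    a <- ctrl[s, ]; b <- ctrl[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((px[, 1] - a[1]) * ab[1] + (px[, 2] - a[2]) * ab[2] +
            (px[, 3] - a[3]) * ab[3]) / len2
    t <- clamp(t, 0, 1)
    dx <- px[, 1] - (a[1] + t * ab[1])
    dy <- px[, 2] - (a[2] + t * ab[2])
    dz <- px[, 3] - (a[3] + t * ab[3])
    d2 <- dx^2 + dy^2 + dz^2
    better <- d2 < best_d2
    best_d2[better] <- d2[better]
    best_v[better] <- volt[s] + t[better] * (volt[s + 1L] - volt[s])
  }
  best_v[best_d2 > tol^2] <- NA_real_
  values <- matrix(best_v, h, w)
  list(values = values, valid = !is.na(values))
}

#' Render a voltage polar map as an RGB raster (optionally a PNG file)
#'
#' Rasterises the map with [polar_raster()] and applies the colour scale.
#' Pixels outside the disk are white; the fibrous-ring annulus and invalid
#' cells are mid-grey (out of the colour-scale gamut, so they round-trip to
#' invalid under [rgb_to_voltage()]).
#'
#' @param map A voltage [polar_map()].
#' @param scale Matching [noga_colour_scale()].
#' @param file Optional path of a PNG to write.
#' @param raster_size Raster width/height in pixels (default 200).
#' @return Invisibly, the `h x w x 3` RGB array.
#' @export
render_polar_png <- function(map, scale = NULL, file = NULL,
                             raster_size = 200L) {
  stopifnot(inherits(map, "polar_map"))
  if (is.null(scale)) {
    scale <- noga_colour_scale(
      if (map$kind == "unipolar_mV") "unipolar" else "bipolar")
  }
  ras <- polar_raster(map, raster_size = raster_size)
  rgb <- voltage_to_rgb(as.vector(ras$values), scale)
  img <- array(0, c(raster_size, raster_size, 3))
  for (ch in 1:3) {
    m <- matrix(rgb[, ch], raster_size, raster_size)
    m[is.na(m)] <- 0.5                      # invalid cells: grey
    img[, , ch] <- m
  }
  # outside the disk: white
  ax <- seq_len(raster_size) - (raster_size + 1) / 2
  rr <- sqrt(outer(ax^2, ax^2, `+`))
  outside <- rr > raster_size / 2
  for (ch in 1:3) {
    m <- img[, , ch]
    m[outside] <- 1
    img[, , ch] <- m
  }
  if (!is.null(file)) png::writePNG(img, file)
  invisible(img)
}
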