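#' Bull's-eye polar map
#'
#' A polar (bull's-eye) map of the left ventricle: apex at the centre, base
#' at the rim, `n_slices` concentric rings of `n_sectors` angular cells.
#' Quantitative values live on the raw (slice, sector) grid; the disk raster
#' produced by [polar_raster()] is an interpolated rendering of that grid and
#' is used only for display and colour-scale round-trips. The outer
#' `annulus_fraction` of the disk radius represents the fibrous ring and
#' valve plane and is always invalid.
#'
#' @param values `n_slices` x `n_sectors` numeric matrix (row 1 = apex ring).
#' @param kind One of `"unipolar_mV"`, `"bipolar_mV"`, `"transmurality"`,
#'   `"class_label"`.
#' @param valid Logical matrix of the same dimension marking cells that carry
#'   a value (default: all finite cells).
#' @param disk_radius_mm Physical radius of the bull's-eye disk (default 40).
#' @param annulus_fraction Width of the excluded fibrous-ring annulus as a
#'   fraction of the disk radius (default 0.08).
#' @return An object of class `polar_map`.
#' @export
polar_map <- function(values, kind, valid = NULL,
                      disk_radius_mm = 40, annulus_fraction = 0.08) {
  values <- as.matrix(values)
  if (is.null(valid)) valid <- is.finite(values)
  stopifnot(identical(dim(valid), dim(values)))
  kind <- match.arg(kind, c("unipolar_mV", "bipolar_mV", "transmurality",
                            "class_label"))
  structure(list(
    values = values, valid = valid, kind = kind,
    n_slices = nrow(values), n_sectors = ncol(values),
    disk_radius_mm = disk_radius_mm, annulus_fraction = annulus_fraction
  ), class = "polar_map")
}

#' @export
print.polar_map <- function(x, ...) {
  cat(sprintf("<polar_map: %s> %d rings x %d sectors, %d/%d valid cells\n",
              x$kind, x$n_slices, x$n_sectors, sum(x$valid), length(x$valid)))
  if (x$kind != "class_label" && any(x$valid)) {
    cat(sprintf("  value range: %.3g .. %.3g\n",
                min(x$values[x$valid]), max(x$values[x$valid])))
  }
  invisible(x)
}

# cell centres of the polar grid in disk mm coordinates
polar_cell_centres <- function(n_slices, n_sectors,
                               disk_radius_mm = 40, annulus_fraction = 0.08) {
  i <- rep(seq_len(n_slices), times = n_sectors)
  j <- rep(seq_len(n_sectors), each = n_slices)
  rho <- (i - 0.5) / n_slices * disk_radius_mm * (1 - annulus_fraction)
  ang <- (j - 0.5) * 2 * pi / n_sectors
  data.frame(slice = i, sector = j, u = rho * cos(ang), v = rho * sin(ang))
}

#' Rasterise a polar map onto a disk
#'
#' Renders the (slice, sector) grid of a [polar_map()] as a square raster of
#' the bull's-eye disk using bilinear interpolation in (ring, sector) with
#' periodic wrap in the sector direction, optionally followed by a small
#' fixed box-blur. Pixels outside the disk, inside the fibrous-ring annulus,
#' or whose nearest cell is invalid are `NA`. Quantitative area measurements
#' are always taken on the raw grid, never on this raster.
#'
#' @param map A [polar_map()].
#' @param raster_size Width/height of the square raster in pixels
#'   (default 200).
#' @param smooth Integer half-width of a box smoothing kernel applied to the
#'   raster (default 0 = disabled; display only).
#' @return List with matrices `values` and `valid` (`raster_size` square) and
#'   the pixel size in mm.
#' @export
polar_raster <- function(map, raster_size = 200L, smooth = 0L) {
  stopifnot(inherits(map, "polar_map"))
  n <- as.integer(raster_size)
  R <- map$disk_radius_mm
  px <- 2 * R / n
  ax <- (seq_len(n) - (n + 1) / 2) * px
  xx <- matrix(ax, n, n)
  yy <- t(xx)
  rho <- sqrt(xx^2 + yy^2)
  ang <- atan2(yy, xx) %% (2 * pi)

  r_cells <- R * (1 - map$annulus_fraction)
  inside <- rho <= r_cells

  # continuous (ring, sector) coordinates; clamp radially, wrap angularly
  fi <- clamp(rho / r_cells * map$n_slices + 0.5, 1, map$n_slices)
  fj <- ang / (2 * pi) * map$n_sectors + 0.5

  i0 <- pmin(floor(fi), map$n_slices - 1L); i1 <- i0 + 1L
  wi <- fi - i0
  j0 <- floor(fj)
  wj <- fj - j0
  wrap <- function(j) ((j - 1L) %% map$n_sectors) + 1L
  j0w <- wrap(j0); j1w <- wrap(j0 + 1L)

  vals <- map$values
  vals[!map$valid] <- NA_real_
  at <- function(i, j) vals[cbind(as.vector(i), as.vector(j))]
  v <- (1 - wi) * (1 - wj) * at(i0, j0w) + (1 - wi) * wj * at(i0, j1w) +
    wi * (1 - wj) * at(i1, j0w) + wi * wj * at(i1, j1w)
  v <- matrix(v, n, n)
  v[!inside] <- NA_real_

  if (smooth > 0) {
    k <- 2L * smooth + 1L
    acc <- matrix(0, n, n); cnt <- matrix(0, n, n)
    for (dx in -smooth:smooth) for (dy in -smooth:smooth) {
      sx <- clamp(seq_len(n) + dx, 1L, n)
      sy <- clamp(seq_len(n) + dy, 1L, n)
      vv <- v[sx, sy]
      ok <- !is.na(vv)
      acc[ok] <- acc[ok] + vv[ok]
      cnt <- cnt + ok
    }
    sm <- acc / pmax(cnt, 1)
    sm[cnt == 0] <- NA_real_
    sm[is.na(v)] <- NA_real_
    v <- sm
  }

  list(values = v, valid = !is.na(v), pixel_mm = px)
}

#' Class area fractions of a label map
#'
#' Areas are reported the way planimetric polar-map measurements are: the
#' number of valid cells carrying each class label divided by the total
#' number of valid cells, as a percentage of the mapped LV surface.
#'
#' @param class_map A `polar_map` of kind `"class_label"` (integer-coded
#'   values with a `levels` attribute, as produced by [classify_voltage()]
#'   or [classify_transmurality()]).
#' @return Named numeric vector of percentages summing to 100.
#' @export
area_fractions <- function(class_map) {
  stopifnot(inherits(class_map, "polar_map"),
            class_map$kind == "class_label")
  lev <- attr(class_map, "levels")
  v <- class_map$values[class_map$valid]
  if (length(v) == 0) stop("no valid cells in class map", call. = FALSE)
  counts <- vapply(seq_along(lev), function(k) sum(v == k), numeric(1))
  stats::setNames(100 * counts / length(v), lev)
}

# build an integer-coded class polar map from a numeric map + classifier fn
make_class_map <- function(map, codes, levels) {
  out <- polar_map(codes, "class_label", valid = map$valid,
                   disk_radius_mm = map$disk_radius_mm,
                   annulus_fraction = map$annulus_fraction)
  attr(out, "levels") <- levels
  out
}

# logical cell mask for a set of class labels
class_mask <- function(class_map, labels) {
  lev <- attr(class_map, "levels")
  idx <- match(labels, lev)
  if (anyNA(idx)) stop("unknown class label", call. = FALSE)
  matrix(class_map$values %in% idx, class_map$n_slices, class_map$n_sectors) &
    class_map$valid
}
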