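# Delimited-text round-tripping of every data type, plus config files.
# All writers produce plain CSV so that experiment outputs stay diffable.

#' Write / read a polar map as CSV
#'
#' Long format with one row per cell: `slice`, `sector`, `value`, `valid`.
#' Invalid cells keep an empty value field. Map geometry travels in
#' commented header lines, so `read_polar_map(write_polar_map(m))` is an
#' identity on the data.
#'
#' @param map A [polar_map()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_polar_map <- function(map, path) {
  stopifnot(inherits(map, "polar_map"))
  hdr <- sprintf("# polar_map kind=%s n_slices=%d n_sectors=%d disk_radius_mm=%g annulus_fraction=%g",
                 map$kind, map$n_slices, map$n_sectors,
                 map$disk_radius_mm, map$annulus_fraction)
  df <- data.frame(slice = as.vector(row(map$values)),
                   sector = as.vector(col(map$values)),
                   value = ifelse(as.vector(map$valid),
                                  as.vector(map$values), NA),
                   valid = as.vector(map$valid))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_polar_map
#' @export
read_polar_map <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- strsplit(sub("^# polar_map ", "", hdr), " ")[[1]]
  meta <- stats::setNames(
    lapply(kv, function(s) strsplit(s, "=")[[1]][2]),
    vapply(kv, function(s) strsplit(s, "=")[[1]][1], character(1)))
  df <- utils::read.csv(path, skip = 1L)
  ns <- as.integer(meta$n_slices); nk <- as.integer(meta$n_sectors)
  values <- matrix(NA_real_, ns, nk)
  values[cbind(df$slice, df$sector)] <- df$value
  valid <- matrix(FALSE, ns, nk)
  valid[cbind(df$slice, df$sector)] <- df$valid
  polar_map(values, meta$kind, valid = valid,
            disk_radius_mm = as.numeric(meta$disk_radius_mm),
            annulus_fraction = as.numeric(meta$annulus_fraction))
}

#' Write / read mapping points as CSV
#'
#' Columns: `slice_idx`, `sector_idx`, `x_mm`, `y_mm`, `z_mm`, `u_map`,
#' `v_map`, `upv_mV`, `bipv_mV`, `stable`.
#'
#' @param points A `mapping_points` data frame.
#' @param path CSV path.
#' @return `path` invisibly / the `mapping_points` data frame.
#' @export
write_mapping_points <- function(points, path) {
  hdr <- sprintf("# mapping_points disk_radius_mm=%g annulus_fraction=%g",
                 attr(points, "disk_radius_mm") %||% 40,
                 attr(points, "annulus_fraction") %||% 0.08)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(points), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mapping_points
#' @export
read_mapping_points <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- strsplit(sub("^# mapping_points ", "", hdr), " ")[[1]]
  df <- utils::read.csv(path, skip = 1L)
  class(df) <- c("mapping_points", "data.frame")
  attr(df, "disk_radius_mm") <- as.numeric(strsplit(kv[1], "=")[[1]][2])
  attr(df, "annulus_fraction") <- as.numeric(strsplit(kv[2], "=")[[1]][2])
  df
}

#' Write / read a slice stack as CSV
#'
#' Long format, one row per voxel inside the epicardial border (background
#' voxels are implicit zeros): `slice`, `row`, `col`, `si`, `endo`, `epi`,
#' `remote`. Geometry travels in a commented header.
#'
#' @param stack A [slice_stack()].
#' @param path CSV path.
#' @return `path` invisibly / the `slice_stack`.
#' @export
write_slice_stack <- function(stack, path) {
  stopifnot(inherits(stack, "slice_stack"))
  d <- dim(stack$voxels)
  hdr <- sprintf("# slice_stack n_slices=%d nrow=%d ncol=%d voxel_mm=%g slice_thickness_mm=%g",
                 d[1], d[2], d[3], stack$voxel_mm, stack$slice_thickness_mm)
  keep <- which(stack$epi_mask)
  idx <- arrayInd(keep, d)
  df <- data.frame(slice = idx[, 1], row = idx[, 2], col = idx[, 3],
                   si = stack$voxels[keep],
                   endo = stack$endo_mask[keep],
                   epi = TRUE,
                   remote = stack$remote_mask[keep])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_slice_stack
#' @export
read_slice_stack <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- strsplit(sub("^# slice_stack ", "", hdr), " ")[[1]]
  meta <- stats::setNames(
    lapply(kv, function(s) as.numeric(strsplit(s, "=")[[1]][2])),
    vapply(kv, function(s) strsplit(s, "=")[[1]][1], character(1)))
  df <- utils::read.csv(path, skip = 1L)
  d <- c(meta$n_slices, meta$nrow, meta$ncol)
  vox <- array(0, d)
  endo <- array(FALSE, d)
  epi <- array(FALSE, d)
  remote <- array(FALSE, d)
  lin <- cbind(df$slice, df$row, df$col)
  vox[lin] <- df$si
  endo[lin] <- df$endo
  epi[lin] <- df$epi
  remote[lin] <- df$remote
  slice_stack(vox, meta$voxel_mm, meta$slice_thickness_mm, endo, epi, remote)
}

#' Write / read a cohort configuration as YAML
#'
#' @param config A [cohort_config()].
#' @param path YAML path.
#' @return `path` invisibly / the `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  do.call(cohort_config, yaml::read_yaml(path))
}
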