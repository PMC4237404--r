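# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_if_not_scalar_count <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 1 || x != as.integer(x)) {
    stop(sprintf("`%s` must be a single positive integer", name), call. = FALSE)
  }
  invisible(as.integer(x))
}

# round-half-up; base round() rounds half to even, which makes voxel lookup
# direction-dependent along lattice-aligned rays
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# circular (wrap-around) difference of sector indices, in cells
sector_diff <- function(j, centre, n_sectors) {
  d <- (j - centre) %% n_sectors
  ifelse(d > n_sectors / 2, d - n_sectors, d)
}

# derive a stream of independent sub-seeds from one master seed
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# shared grading of correlation magnitude (standard qualitative nomenclature)
grade_correlation <- function(r) {
  a <- abs(r)
  if (is.na(a)) return(NA_character_)
  if (a > 0.5) "large" else if (a > 0.3) "moderate" else if (a > 0.1) "small" else "negligible"
}
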