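#' Imaging-grid specification
#'
#' Square imaging domain of side `side_length` (cm), centred at the origin,
#' discretised into `n_pixels` x `n_pixels` square cells. Field and dielectric
#' maps are sampled at pixel centres: pixel `(i, j)` (1-based row/column)
#' sits at `x = -L/2 + (j - 1/2) * delta`, `y = -L/2 + (i - 1/2) * delta`.
#' The reference configuration is a 15 cm domain on a 108 x 108 grid
#' (pixel size ~0.139 cm).
#'
#' @param side_length domain edge in cm.
#' @param n_pixels pixels per side (>= 8).
#' @return an object of class `mwt_grid` with fields `side_length`,
#'   `n_pixels`, `pixel_size`, and pixel-centre coordinate vectors `x`, `y`.
#' @examples
#' g <- grid_spec(15, 108)
#' g$pixel_size # ~0.1389 cm
#' @export
grid_spec <- function(side_length = 15, n_pixels = 108) {
  stopifnot(is.numeric(side_length), side_length > 0)
  n_pixels <- as.integer(n_pixels)
  if (n_pixels < 8L) abort("`n_pixels` must be at least 8.", class = "mwtomo_bad_grid")
  delta <- side_length / n_pixels
  centers <- -side_length / 2 + (seq_len(n_pixels) - 0.5) * delta
  structure(
    list(side_length = side_length, n_pixels = n_pixels,
         pixel_size = delta, x = centers, y = centers),
    class = "mwt_grid"
  )
}

#' @export
print.mwt_grid <- function(x, ...) {
  cat(sprintf("<mwt_grid> %g x %g cm, %d x %d pixels (%.4f cm/pixel)\n",
              x$side_length, x$side_length, x$n_pixels, x$n_pixels, x$pixel_size))
  invisible(x)
}

# pixel-centre coordinate matrices (row i -> y, column j -> x)
grid_coords <- function(grid) {
  n <- grid$n_pixels
  list(x = matrix(grid$x, n, n, byrow = TRUE),
       y = matrix(grid$y, n, n, byrow = FALSE))
}
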