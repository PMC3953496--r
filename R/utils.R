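#' Round half away from zero
#'
#' Decimal rounding where exact halves round up (e.g. 96.25 -> 96.3 at one
#' decimal), as used in the package's accuracy reports. Base \code{round()}
#' rounds halves to even, which gives 96.2 for the same input.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # nudge by an epsilon scaled to x so values stored as 96.249999... (binary
  # representation of 96.25) still round up
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# Validate an 8-bit grey image: integer-valued matrix in [0, 255].
# Pixel P(x, y) with x = column (0-based), y = row (0-based) lives at
# img[y + 1, x + 1]; width M = ncol, height N = nrow.
check_grey_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("image must be a numeric matrix of grey levels")
  if (nrow(img) < 1L || ncol(img) < 1L)
    stop("image must have at least one pixel")
  if (anyNA(img) || any(img < 0 | img > 255))
    stop("grey levels must lie in [0, 255]")
  if (any(img != round(img)))
    stop("grey levels must be integer-valued (8-bit)")
  invisible(img)
}

# Linear index helpers for (row, col) grids used by the region growers.
rc_to_idx <- function(r, c, nr) (c - 1L) * nr + r
idx_to_rc <- function(i, nr) cbind(((i - 1L) %% nr) + 1L, ((i - 1L) %/% nr) + 1L)

# 8-connected neighbour offsets in fixed enqueue order:
# E, SE, S, SW, W, NW, N, NE as (drow, dcol) with x = col, y = row.
neighbour_offsets_8 <- function() {
  cbind(dr = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L),
        dc = c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L))
}
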