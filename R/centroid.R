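# Vectorized 8-connected flood fill over a logical condition grid.
# `cond` marks pixels that may be absorbed; `seeds` are linear indices
# (column-major) assumed already members. Returns a logical matrix of the
# reachable member set. Frontier-at-a-time breadth-first; the result is
# order-independent because membership depends only on `cond`.
flood_fill <- function(cond, seeds) {
  nr <- nrow(cond); nc <- ncol(cond)
  member <- matrix(FALSE, nr, nc)
  member[seeds] <- TRUE
  frontier <- seeds
  off <- neighbour_offsets_8()
  while (length(frontier)) {
    rc <- idx_to_rc(frontier, nr)
    cand <- integer(0)
    for (k in seq_len(nrow(off))) {
      r <- rc[, 1] + off[k, 1]; c <- rc[, 2] + off[k, 2]
      ok <- r >= 1L & r <= nr & c >= 1L & c <= nc
      cand <- c(cand, rc_to_idx(r[ok], c[ok], nr))
    }
    cand <- unique(cand)
    cand <- cand[!member[cand] & cond[cand]]
    member[cand] <- TRUE
    frontier <- cand
  }
  member
}

#' Isolate the candidate nucleus by subclustering
#'
#' Removes the background and cytoplasm by seed-based region growing from
#' the image corner (0, 0), which lies in the background of a single-cell
#' image: first all 8-connected pixels brighter than the
#' cytoplasm-background threshold are absorbed (background), then remaining
#' connected pixels brighter than the nucleus-cytoplasm threshold
#' (cytoplasm). What is left — dark pixels not connected away — is the
#' candidate nucleus.
#'
#' @param img grey image matrix.
#' @param beta_CB,beta_NC thresholds from [compute_thresholds()].
#' @return logical matrix; TRUE marks candidate-nucleus pixels.
#' @export
subcluster_nucleus <- function(img, beta_CB, beta_NC) {
  check_grey_image(img)
  if (beta_NC > beta_CB) stop("beta_NC must not exceed beta_CB")
  if (img[1, 1] <= beta_NC)
    stop("seed pixel (0,0) is not background (grey level <= beta_NC); ",
         "cannot subcluster")
  bg <- flood_fill(img > beta_CB, 1L)
  grown <- flood_fill(img > beta_NC, which(bg))
  grown[!bg & !(img > beta_NC)] <- grown[!bg & !(img > beta_NC)]  # no-op, clarity
  (!grown) & (img <= beta_NC)
}

#' Centroid of a binary mask from raw image moments
#'
#' Computes the zeroth- and first-order raw moments of the mask
#' (\eqn{m_{pq} = \sum x^p y^q} over TRUE pixels) and returns the rounded
#' centre \eqn{(m_{10}/m_{00}, m_{01}/m_{00})}. If the rounded point does
#' not itself lie on a TRUE pixel (e.g. for a crescent), it is snapped to
#' the nearest TRUE pixel (Euclidean distance, ties broken in row-major
#' scan order).
#'
#' @param mask logical matrix (row = y, col = x).
#' @return named integer vector \code{c(x, y)} in 0-based pixel coordinates.
#' @export
moment_centroid <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask)) stop("mask must be a logical matrix")
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask: no candidate-nucleus pixels")
  ys <- idx[, 1] - 1L; xs <- idx[, 2] - 1L
  m00 <- nrow(idx)
  cx <- round_half_up(sum(xs) / m00)
  cy <- round_half_up(sum(ys) / m00)
  if (!mask[cy + 1L, cx + 1L]) {
    d2 <- (xs - cx)^2 + (ys - cy)^2
    best <- d2 == min(d2)
    ord <- order(ys[best], xs[best])[1]   # row-major tie-break
    cx <- xs[best][ord]; cy <- ys[best][ord]
  }
  c(x = as.integer(cx), y = as.integer(cy))
}

#' Locate the nucleus seed of a cell image
#'
#' Subclustering followed by the moment centroid; the returned point lies
#' inside the nucleus and seeds the segmentation pass.
#'
#' @param img grey image matrix.
#' @param thresholds named vector with \code{beta_NC} and \code{beta_CB}.
#' @return named integer vector \code{c(x, y)}, 0-based.
#' @export
nucleus_centroid <- function(img, thresholds) {
  mask <- subcluster_nucleus(img, thresholds[["beta_CB"]], thresholds[["beta_NC"]])
  if (!any(mask))
    stop("subclustering removed every pixel; no nucleus found")
  moment_centroid(mask)
}
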