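#' Median filter with edge replication
#'
#' Replaces every pixel by the median of its \code{window} x \code{window}
#' neighbourhood; pixels outside the image are taken as the nearest edge
#' pixel (edge replication).
#'
#' @param img grey image matrix.
#' @param window odd neighbourhood width in pixels, default 3.
#' @return filtered image matrix.
#' @export
median_filter <- function(img, window = 3L) {
  check_grey_image(img)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be an odd positive integer")
  if (window == 1L) return(img)
  k <- (window - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  # pad by edge replication
  ri <- pmin(pmax(seq_len(nr + 2L * k) - k, 1L), nr)
  ci <- pmin(pmax(seq_len(nc + 2L * k) - k, 1L), nc)
  pad <- img[ri, ci, drop = FALSE]
  shifts <- expand.grid(dr = 0:(window - 1L), dc = 0:(window - 1L))
  stack <- vapply(seq_len(nrow(shifts)), function(s) {
    as.vector(pad[shifts$dr[s] + seq_len(nr), shifts$dc[s] + seq_len(nc), drop = FALSE])
  }, numeric(nr * nc))
  out <- apply(stack, 1L, stats::median)
  matrix(out, nr, nc)
}

#' Histogram equalization
#'
#' Standard cumulative-distribution grey-level remap:
#' \eqn{g \mapsto \mathrm{round}(255\,\mathrm{cdf}(g))}. Monotone
#' non-decreasing in the input grey level; a constant image maps to 255.
#'
#' @param img grey image matrix.
#' @return equalized image matrix.
#' @export
histogram_equalize <- function(img) {
  h <- grey_histogram(img)
  cdf <- cumsum(h) / sum(h)
  lut <- round_half_up(255 * cdf)
  matrix(lut[as.integer(img) + 1L], nrow(img), ncol(img))
}

#' Region-growing acceptance rule
#'
#' A neighbour pixel joins the growing region if either
#' \enumerate{
#'   \item the gradient between its original grey level and its
#'     histogram-equalized grey level is below the cutoff (default 95\%)
#'     AND the original grey level does not exceed the pass threshold
#'     \code{beta} (dark pixels belong to the region being grown), or
#'   \item the gradient is at or above the cutoff AND the original grey
#'     level is at least \eqn{\bar{x} - \sigma}, the running mean minus the
#'     running standard deviation of the pixels accepted so far.
#' }
#' The gradient is \eqn{|g_{eq} - g_{orig}| / 255 \times 100}, a bounded
#' percentage.
#'
#' @param gl_orig original grey level(s).
#' @param gl_eq equalized grey level(s).
#' @param beta pass threshold (beta_NC for the nucleus pass, beta_CB for
#'   the cytoplasm pass).
#' @param xbar,sigma running mean and standard deviation of accepted grey
#'   levels.
#' @param cutoff gradient cutoff in percent, default 95.
#' @return logical vector of accept decisions.
#' @export
growing_condition <- function(gl_orig, gl_eq, beta, xbar, sigma, cutoff = 95) {
  gradient <- abs(gl_eq - gl_orig) / 255 * 100
  (gradient < cutoff & gl_orig <= beta) |
    (gradient >= cutoff & gl_orig >= (xbar - sigma))
}

# Border of a member set: member pixels with at least one 8-neighbour that
# is not a member, or lying on the image edge.
member_border <- function(member) {
  nr <- nrow(member); nc <- ncol(member)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- member
  all_nb <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    all_nb <- all_nb & pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  member & !all_nb
}

#' Seeded region growing with running feature accumulation
#'
#' Breadth-first 8-connected growth from the seed. The seed is always
#' accepted (it is the nucleus centroid, known to lie in the region). Each
#' untested neighbour of the frontier is examined exactly once, in the
#' fixed enqueue order E, SE, S, SW, W, NW, N, NE, against
#' [growing_condition()] evaluated with the running mean and standard
#' deviation of the grey levels accepted so far (sample standard deviation,
#' defined as 0 for a single pixel). Accepted pixels update the size
#' counter and the grey-level sum. Because the running statistics evolve
#' with the visit order, the grown set can depend on that order; the fixed
#' BFS order makes runs deterministic.
#'
#' @param img original grey image (grey levels summed into the features).
#' @param eq_img equalized image used by the gradient test.
#' @param seed named vector \code{c(x, y)}, 0-based.
#' @param beta pass threshold.
#' @param cutoff gradient cutoff in percent.
#' @return list: \code{member} and \code{border} logical matrices,
#'   \code{size}, \code{grey_sum}, \code{mean}, \code{sd},
#'   \code{border_count}.
#' @export
region_grow <- function(img, eq_img, seed, beta, cutoff = 95) {
  check_grey_image(img)
  nr <- nrow(img); nc <- ncol(img)
  sx <- as.integer(seed[["x"]]); sy <- as.integer(seed[["y"]])
  if (sx < 0L || sx >= nc || sy < 0L || sy >= nr) stop("seed outside image")
  off <- neighbour_offsets_8()
  member <- matrix(FALSE, nr, nc)
  visited <- matrix(FALSE, nr, nc)

  queue <- integer(nr * nc)
  head <- 1L; tail <- 0L
  push <- function(i) { tail <<- tail + 1L; queue[tail] <<- i }

  # Welford running statistics over accepted original grey levels
  n <- 0L; mean_gl <- 0; m2 <- 0; grey_sum <- 0
  accept_px <- function(i) {
    gl <- img[i]
    n <<- n + 1L
    grey_sum <<- grey_sum + gl
    d <- gl - mean_gl
    mean_gl <<- mean_gl + d / n
    m2 <<- m2 + d * (gl - mean_gl)
    member[i] <<- TRUE
    push(i)
  }

  seed_i <- rc_to_idx(sy + 1L, sx + 1L, nr)
  visited[seed_i] <- TRUE
  accept_px(seed_i)

  while (head <= tail) {
    i <- queue[head]; head <- head + 1L
    r0 <- ((i - 1L) %% nr) + 1L
    c0 <- ((i - 1L) %/% nr) + 1L
    for (k in 1:8) {
      r <- r0 + off[k, 1L]; c <- c0 + off[k, 2L]
      if (r < 1L || r > nr || c < 1L || c > nc) next
      j <- (c - 1L) * nr + r
      if (visited[j]) next
      visited[j] <- TRUE
      sdev <- if (n > 1L) sqrt(m2 / (n - 1L)) else 0
      if (growing_condition(img[j], eq_img[j], beta, mean_gl, sdev, cutoff))
        accept_px(j)
    }
  }

  border <- member_border(member)
  list(member = member, border = border, size = n, grey_sum = grey_sum,
       mean = grey_sum / n, sd = if (n > 1L) sqrt(m2 / (n - 1L)) else 0,
       border_count = sum(border))
}

#' Segment a cell image and extract its six features
#'
#' The modified seeded-region-growing pass: the image is median-filtered
#' and histogram-equalized (the equalized values feed the gradient test;
#' grey-level sums use the original values), then two growths run from the
#' same nucleus-centroid seed — first with the nucleus-cytoplasm threshold,
#' then with the cytoplasm-background threshold. The tri-level mask labels
#' nucleus pixels 0, additional cytoplasm growth 127, and everything
#' untouched 255. Features: nucleus size \code{n} and perimeter (count of
#' nucleus border pixels), nucleus mean grey level; cytoplasm actual size
#' \code{c = cytoplasm_size - n} (the cytoplasm pass starts from the same
#' seed and regrows the nucleus, so its raw size includes the nucleus),
#' cytoplasm perimeter, and cytoplasm mean grey level
#' \eqn{(\sum GL_C - \sum GL_N)/c}.
#'
#' @param img grey image matrix.
#' @param thresholds named vector with \code{beta_NC}, \code{beta_CB}.
#' @param seed nucleus centroid \code{c(x, y)}, 0-based.
#' @param window median-filter window (odd), default 3.
#' @param cutoff gradient cutoff percent, default 95.
#' @return list with \code{mask} (integer matrix of 0/127/255),
#'   \code{features} (named numeric of the six features), and the two
#'   pass results \code{nucleus}, \code{cytoplasm}.
#' @export
segment_and_extract <- function(img, thresholds, seed, window = 3L, cutoff = 95) {
  filt <- median_filter(img, window)
  eq <- histogram_equalize(filt)
  nuc <- region_grow(img, eq, seed, thresholds[["beta_NC"]], cutoff)
  cyt <- region_grow(img, eq, seed, thresholds[["beta_CB"]], cutoff)

  mask <- matrix(255L, nrow(img), ncol(img))
  mask[cyt$member & !nuc$member] <- 127L
  mask[nuc$member] <- 0L

  n <- nuc$size
  c_size <- cyt$size - n
  if (c_size <= 0L)
    stop("degenerate cytoplasm: the cytoplasm pass grew no pixels beyond ",
         "the nucleus; cytoplasm mean grey level is undefined")
  feats <- c(n, nuc$border_count, nuc$grey_sum / n,
             c_size, cyt$border_count, (cyt$grey_sum - nuc$grey_sum) / c_size)
  names(feats) <- feature_names()
  list(mask = mask, features = feats, nucleus = nuc, cytoplasm = cyt)
}
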