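#' Grey-level histogram of an image
#'
#' @param img integer matrix of grey levels in [0, 255].
#' @return integer vector of length 256; element \code{g + 1} is the number
#'   of pixels with grey level \code{g}.
#' @export
grey_histogram <- function(img) {
  check_grey_image(img)
  tabulate(as.integer(img) + 1L, nbins = 256L)
}

#' Initial cluster centres from a grey-level histogram
#'
#' Deterministic histogram analysis yielding three strictly increasing
#' initial centres for the nucleus, cytoplasm and background grey-level
#' clusters. The primary rule takes the median grey level of each of the
#' three equal-mass segments of the cumulative histogram. When the region
#' masses are very unequal (e.g. a dominant background) those medians can
#' coincide; the method then falls back to mass-weighted medians of the
#' three equal-width segments of the occupied grey-level range, and finally
#' to the segment midpoints.
#'
#' @param hist 256-bin histogram from [grey_histogram()].
#' @return numeric vector \code{c(C_No, C_Co, C_Bo)}, strictly increasing.
#' @export
initial_centres <- function(hist) {
  if (length(hist) != 256L || any(hist < 0) || sum(hist) == 0)
    stop("hist must be a non-empty 256-bin histogram")
  occupied <- which(hist > 0) - 1L
  if (length(occupied) < 3L)
    stop("degenerate histogram: fewer than 3 distinct grey levels")

  seg_median <- function(lo, hi) {
    # mass-weighted median grey level of bins lo..hi (0-based grey levels)
    cnt <- hist[(lo:hi) + 1L]
    tot <- sum(cnt)
    if (tot == 0) return(NA_real_)
    (lo:hi)[which(cumsum(cnt) >= tot / 2)[1]]
  }

  total <- sum(hist)
  cum <- cumsum(hist)
  b1 <- which(cum >= total / 3)[1] - 1L
  b2 <- which(cum >= 2 * total / 3)[1] - 1L
  centres <- c(seg_median(0L, b1),
               if (b1 + 1L <= b2) seg_median(b1 + 1L, b2) else NA_real_,
               if (b2 + 1L <= 255L) seg_median(b2 + 1L, 255L) else NA_real_)

  if (anyNA(centres) || any(diff(centres) <= 0)) {
    gmin <- min(occupied); gmax <- max(occupied)
    cuts <- round(gmin + (gmax - gmin) * c(1, 2) / 3)
    lo <- c(gmin, cuts[1] + 1L, cuts[2] + 1L)
    hi <- c(cuts[1], cuts[2], gmax)
    centres <- vapply(1:3, function(k) {
      m <- if (lo[k] <= hi[k]) seg_median(lo[k], hi[k]) else NA_real_
      if (is.na(m)) (lo[k] + hi[k]) / 2 else m
    }, numeric(1))
    if (any(diff(centres) <= 0)) centres <- (lo + hi) / 2
  }
  if (any(diff(centres) <= 0))
    stop("degenerate histogram: could not derive increasing initial centres")
  as.numeric(centres)
}

#' Moving k-means clustering of grey levels
#'
#' Clusters the grey levels of an image into three groups (nucleus,
#' cytoplasm, background) with the moving k-means scheme: ordinary k-means
#' assignment/update passes interleaved with a cluster-repopulation step
#' that keeps every cluster alive. After each pass the within-cluster
#' fitness (sum of squared distances of member grey values to the centre,
#' weighted by pixel counts) is compared across clusters; while the
#' smallest fitness falls below \code{alpha_a} times the largest, the
#' smallest-fitness cluster abandons its members and moves to take over
#' the members of the largest-fitness cluster whose grey values lie below
#' its centre; both centres are recomputed from their new member sets, all
#' pixels are reassigned to the nearest centre, and both alpha values
#' shrink by a third (\eqn{\alpha \leftarrow \alpha - \alpha/n_c},
#' \eqn{n_c = 3}). A final verification with \code{alpha_b} repeats the
#' move step after convergence.
#' Clustering operates on the 256-bin histogram, which is equivalent to
#' clustering the raw pixel list for one-dimensional grey data.
#'
#' @param img grey image matrix, or a 256-bin histogram.
#' @param initial three strictly increasing initial centres; defaults to
#'   [initial_centres()] of the image histogram.
#' @param alpha_a,alpha_b moving thresholds in (0, 1), default 0.3.
#' @param tol convergence tolerance on centre movement (grey levels).
#' @param max_iter maximum assignment/update passes.
#' @return list with \code{centres} (final, sorted ascending),
#'   \code{initial}, \code{iterations}, \code{converged}, and \code{sizes}
#'   (pixel count per cluster; all positive).
#' @export
moving_k_means <- function(img, initial = NULL, alpha_a = 0.3, alpha_b = 0.3,
                           tol = 1e-3, max_iter = 100L) {
  hist <- if (is.matrix(img)) grey_histogram(img) else {
    if (length(img) != 256L) stop("img must be an image matrix or 256-bin histogram")
    as.numeric(img)
  }
  if (sum(hist) == 0) stop("empty image")
  if (is.null(initial)) initial <- initial_centres(hist)
  if (length(initial) != 3L || any(diff(initial) <= 0))
    stop("need 3 strictly increasing initial centres")
  if (alpha_a <= 0 || alpha_a >= 1 || alpha_b <= 0 || alpha_b >= 1)
    stop("alpha values must lie in (0, 1)")

  g <- 0:255
  w <- hist
  centres <- as.numeric(initial)
  n_c <- 3L

  assign_fitness <- function(centres) {
    d <- abs(outer(g, centres, "-"))
    cl <- max.col(-d, ties.method = "first")   # nearest centre, low index on ties
    fit <- vapply(1:n_c, function(j) {
      m <- cl == j
      sum(w[m] * (g[m] - centres[j])^2)
    }, numeric(1))
    list(cl = cl, fit = fit)
  }
  centre_of <- function(cl, j, fallback) {
    m <- cl == j & w > 0
    if (!any(m)) return(fallback)
    sum(w[m] * g[m]) / sum(w[m])
  }

  # While the smallest within-cluster fitness is below alpha times the
  # largest, relocate the smallest-fitness cluster: it abandons its own
  # members and takes over the members of the largest-fitness cluster that
  # lie below that cluster's centre; then everything is reassigned to the
  # nearest centre. alpha shrinks by a third per move, so this terminates.
  move_clusters <- function(centres, alpha) {
    repeat {
      af <- assign_fitness(centres)
      fit <- af$fit
      if (min(fit) >= alpha * max(fit)) break
      js <- which.min(fit); jl <- which.max(fit)
      take <- af$cl == jl & g < centres[jl] & w > 0
      keep <- af$cl == jl & !take & w > 0
      if (any(take) && any(keep)) {
        centres[js] <- sum(w[take] * g[take]) / sum(w[take])
        centres[jl] <- sum(w[keep] * g[keep]) / sum(w[keep])
      }
      alpha <- alpha - alpha / n_c
      if (alpha < 1e-6) break
    }
    list(centres = centres, alpha = alpha)
  }

  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    af <- assign_fitness(centres)
    new_centres <- vapply(1:n_c, function(j) centre_of(af$cl, j, centres[j]),
                          numeric(1))
    mv <- move_clusters(new_centres, alpha_a)
    new_centres <- mv$centres
    alpha_a <- mv$alpha
    moved <- max(abs(new_centres - centres))
    centres <- new_centres
    if (moved <= tol) { converged <- TRUE; break }
  }
  if (converged) {
    # post-convergence verification pass with alpha_b
    mv <- move_clusters(centres, alpha_b)
    if (max(abs(mv$centres - centres)) > tol) {
      centres <- mv$centres
      for (i in seq_len(max_iter)) {
        af <- assign_fitness(centres)
        new_centres <- vapply(1:n_c, function(j) centre_of(af$cl, j, centres[j]),
                              numeric(1))
        moved <- max(abs(new_centres - centres))
        centres <- new_centres
        if (moved <= tol) break
      }
    }
  } else {
    warning("moving k-means did not converge within max_iter; returning current centres")
  }

  centres <- sort(centres)
  af <- assign_fitness(centres)
  sizes <- vapply(1:n_c, function(j) sum(w[af$cl == j]), numeric(1))
  if (any(sizes == 0)) {
    # final guard: repopulate an empty cluster with the grey level nearest
    # to its centre (keeps the non-emptiness contract on pathological input)
    for (j in which(sizes == 0)) {
      gj <- g[w > 0][which.min(abs(g[w > 0] - centres[j]))]
      centres[j] <- gj
    }
    centres <- sort(centres)
    af <- assign_fitness(centres)
    sizes <- vapply(1:n_c, function(j) sum(w[af$cl == j]), numeric(1))
  }
  list(centres = centres, initial = as.numeric(initial), iterations = iter,
       converged = converged, sizes = sizes)
}

#' Segmentation thresholds from cluster centres
#'
#' The nucleus-cytoplasm threshold is the midpoint of the nucleus and
#' cytoplasm centres, and the cytoplasm-background threshold the midpoint
#' of the cytoplasm and background centres, each truncated to an integer
#' grey level (e.g. centres 153/190 give threshold floor(171.5) = 171).
#'
#' @param centres numeric \code{c(C_N, C_C, C_B)}, strictly increasing.
#' @return named numeric \code{c(beta_NC, beta_CB)}.
#' @examples
#' compute_thresholds(c(153, 190, 227))  # 171, 208
#' @export
compute_thresholds <- function(centres) {
  if (is.list(centres)) centres <- centres$centres
  if (length(centres) != 3L || any(diff(centres) <= 0))
    stop("centres must be 3 strictly increasing grey levels (C_N < C_C < C_B)")
  c(beta_NC = floor((centres[1] + centres[2]) / 2),
    beta_CB = floor((centres[2] + centres[3]) / 2))
}

#' Cluster centres and thresholds for an image
#'
#' Convenience wrapper: histogram analysis, moving k-means, and threshold
#' computation in one call.
#'
#' @param img grey image matrix.
#' @param ... passed to [moving_k_means()].
#' @return list with \code{centres}, \code{initial}, \code{thresholds}.
#' @export
afe_thresholds <- function(img, ...) {
  mkm <- moving_k_means(img, ...)
  list(centres = mkm$centres, initial = mkm$initial,
       thresholds = compute_thresholds(mkm$centres))
}
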