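#' Class labels used throughout the package
#'
#' Normal, low-grade squamous intraepithelial lesion (LSIL) and high-grade
#' squamous intraepithelial lesion (HSIL), in the fixed order used for
#' tie-breaking and reports.
#' @export
cell_classes <- function() c("normal", "LSIL", "HSIL")

# Table of per-class defaults for the synthetic generators: grey-level
# centres of the three regions and the six feature means
# (nucleus size/perimeter/grey, cytoplasm size/perimeter/grey).
class_presets <- function() {
  list(
    normal = list(grey = c(153, 190, 227),
                  feat = c(337, 89, 145.875, 8859, 1282, 187.512)),
    LSIL   = list(grey = c(161, 194, 234),
                  feat = c(1155, 307, 160.565, 6239, 550, 186.131)),
    HSIL   = list(grey = c(152, 187, 235),
                  feat = c(1327, 320, 151.455, 3675, 373, 173.084))
  )
}

feature_names <- function() {
  c("nucleus_size", "nucleus_perimeter", "nucleus_grey",
    "cytoplasm_size", "cytoplasm_perimeter", "cytoplasm_grey")
}

# Run expr with a temporary RNG state seeded by `seed`; restores the
# caller's RNG afterwards so generators do not perturb user code.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic single-cell image
#'
#' Describes a synthetic cervical cell as two concentric (optionally offset)
#' disks on a bright background: a dark nucleus disk inside a mid-grey
#' cytoplasm disk. The default grey-level centres (153/190/227) are typical
#' of a normal cell; nucleus is always the darkest region.
#'
#' @param width,height image size in pixels (default 160 x 120).
#' @param centre nucleus disk centre as \code{c(x, y)} in 0-based pixel
#'   coordinates (x = column, y = row); defaults to the image centre.
#' @param nucleus_radius,cytoplasm_radius disk radii in pixels; the nucleus
#'   must be strictly smaller and both disks must fit inside the image.
#'   Defaults (10 and 54) give nucleus/cytoplasm pixel areas close to a
#'   typical normal cell, with the cell filling roughly half the frame.
#' @param cytoplasm_centre optional \code{c(x, y)} centre for the cytoplasm
#'   disk, defaulting to \code{centre}; an offset makes the cell asymmetric.
#' @param grey_nucleus,grey_cytoplasm,grey_background region grey levels in
#'   [0, 255]; must be strictly increasing (nucleus darkest).
#' @param noise_sd standard deviation of the per-pixel Gaussian grey-level
#'   noise (default 5).
#' @param seed integer RNG seed for the noise, or NULL.
#' @return an object of class \code{cell_spec}.
#' @seealso [generate_cell_image()]
#' @export
cell_spec <- function(width = 160L, height = 120L,
                      centre = c(floor(width / 2), floor(height / 2)),
                      nucleus_radius = 10, cytoplasm_radius = 54,
                      cytoplasm_centre = centre,
                      grey_nucleus = 153, grey_cytoplasm = 190,
                      grey_background = 227,
                      noise_sd = 5, seed = NULL) {
  width <- as.integer(width); height <- as.integer(height)
  if (nucleus_radius >= cytoplasm_radius)
    stop("nucleus_radius must be smaller than cytoplasm_radius")
  if (!(grey_nucleus < grey_cytoplasm && grey_cytoplasm < grey_background))
    stop("grey levels must satisfy nucleus < cytoplasm < background")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  fits <- function(ctr, r)
    ctr[1] - r >= 0 && ctr[1] + r <= width - 1 &&
    ctr[2] - r >= 0 && ctr[2] + r <= height - 1
  if (!fits(centre, nucleus_radius) || !fits(cytoplasm_centre, cytoplasm_radius))
    stop("cell disks must fit entirely within the image bounds")
  structure(list(width = width, height = height, centre = centre,
                 nucleus_radius = nucleus_radius,
                 cytoplasm_radius = cytoplasm_radius,
                 cytoplasm_centre = cytoplasm_centre,
                 grey_nucleus = grey_nucleus, grey_cytoplasm = grey_cytoplasm,
                 grey_background = grey_background,
                 noise_sd = noise_sd, seed = seed),
            class = "cell_spec")
}

#' Preset cell geometry for a class
#'
#' Convenience wrapper around [cell_spec()] with per-class grey levels and
#' disk radii chosen so nucleus/cytoplasm pixel areas approximate the
#' typical morphology: normal cells have a small nucleus and a very large
#' cytoplasm, HSIL cells a large nucleus and a shrunken cytoplasm.
#'
#' @param class one of \code{"normal"}, \code{"LSIL"}, \code{"HSIL"}.
#' @param ... overrides passed on to [cell_spec()].
#' @export
cell_spec_preset <- function(class = cell_classes(), ...) {
  class <- match.arg(class)
  p <- class_presets()[[class]]
  # radii from the class's typical areas: r = sqrt(area / pi), cytoplasm
  # radius from the combined nucleus + cytoplasm area
  r_n <- sqrt(p$feat[1] / pi)
  r_c <- sqrt((p$feat[1] + p$feat[4]) / pi)
  args <- list(nucleus_radius = r_n, cytoplasm_radius = r_c,
               grey_nucleus = p$grey[1], grey_cytoplasm = p$grey[2],
               grey_background = p$grey[3])
  args[names(list(...))] <- list(...)
  do.call(cell_spec, args)
}

#' Generate a synthetic single-cell image with ground truth
#'
#' Rasterizes the cell described by a [cell_spec()]: pixels inside the
#' nucleus disk (squared distance \eqn{\le r^2}) take the nucleus grey
#' level, pixels inside the cytoplasm disk but not the nucleus the cytoplasm
#' grey level, all others the background level. Independent Gaussian noise
#' is then added per pixel, rounded and clipped to [0, 255]. The ground
#' truth records the exact rasterized mask (labels 0 = nucleus,
#' 127 = cytoplasm, 255 = background), region pixel counts, the rounded
#' moment centroid of the nucleus and the per-region mean grey level of the
#' generated (noisy) image.
#'
#' @param spec a [cell_spec()].
#' @return list with elements \code{image} (integer matrix, row = y,
#'   col = x) and \code{truth} (list: \code{mask}, \code{nucleus_size},
#'   \code{cytoplasm_size}, \code{centroid}, \code{mean_grey}).
#' @examples
#' cell <- generate_cell_image(cell_spec(noise_sd = 0))
#' table(cell$image)   # exactly the three configured grey levels
#' @export
generate_cell_image <- function(spec) {
  stopifnot(inherits(spec, "cell_spec"))
  M <- spec$width; N <- spec$height
  x <- matrix(rep(0:(M - 1), each = N), nrow = N)   # column coordinate
  y <- matrix(rep(0:(N - 1), times = M), nrow = N)  # row coordinate
  d2n <- (x - spec$centre[1])^2 + (y - spec$centre[2])^2
  d2c <- (x - spec$cytoplasm_centre[1])^2 + (y - spec$cytoplasm_centre[2])^2
  in_nuc <- d2n <= spec$nucleus_radius^2
  in_cyt <- d2c <= spec$cytoplasm_radius^2 & !in_nuc
  img <- matrix(spec$grey_background, nrow = N, ncol = M)
  img[in_cyt] <- spec$grey_cytoplasm
  img[in_nuc] <- spec$grey_nucleus
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed, stats::rnorm(N * M, 0, spec$noise_sd))
    img <- pmin(pmax(round(img + noise), 0), 255)
  }
  img <- round(img)
  storage.mode(img) <- "integer"
  mask <- matrix(255L, nrow = N, ncol = M)
  mask[in_cyt] <- 127L
  mask[in_nuc] <- 0L
  truth <- list(
    mask = mask,
    nucleus_size = sum(in_nuc),
    cytoplasm_size = sum(in_cyt),
    centroid = c(x = round(sum(x[in_nuc]) / sum(in_nuc)),
                 y = round(sum(y[in_nuc]) / sum(in_nuc))),
    mean_grey = c(nucleus = mean(img[in_nuc]),
                  cytoplasm = mean(img[in_cyt]),
                  background = mean(img[!in_nuc & !in_cyt]))
  )
  list(image = img, truth = truth)
}

#' Generate a synthetic labelled feature table
#'
#' Draws six-feature vectors per class from independent Gaussians around
#' configurable class means. Default means are typical measured values for
#' normal/LSIL/HSIL cells; default spreads are 10\% of each mean. Default
#' class sizes are 376 normal, 79 LSIL and 45 HSIL (a realistic screening
#' population, heavily skewed towards normal cells).
#'
#' @param n_per_class integer vector of 3 counts (normal, LSIL, HSIL).
#' @param class_means 3 x 6 matrix of feature means (rows = classes).
#' @param class_sds 3 x 6 matrix of feature standard deviations.
#' @param seed RNG seed.
#' @return data.frame with columns \code{nucleus_size, nucleus_perimeter,
#'   nucleus_grey, cytoplasm_size, cytoplasm_perimeter, cytoplasm_grey,
#'   label} (factor with levels normal/LSIL/HSIL).
#' @export
generate_feature_dataset <- function(n_per_class = c(376L, 79L, 45L),
                                     class_means = NULL, class_sds = NULL,
                                     seed = NULL) {
  if (length(n_per_class) != 3L || any(n_per_class < 1))
    stop("n_per_class must give a positive count for each of the 3 classes")
  presets <- class_presets()
  if (is.null(class_means))
    class_means <- do.call(rbind, lapply(presets, `[[`, "feat"))
  class_means <- matrix(as.numeric(class_means), nrow = 3, ncol = 6)
  if (is.null(class_sds)) class_sds <- 0.10 * class_means
  class_sds <- matrix(as.numeric(class_sds), nrow = 3, ncol = 6)
  if (any(class_sds < 0)) stop("class_sds must be non-negative")
  with_seed(seed, {
    rows <- lapply(1:3, function(k) {
      n <- n_per_class[k]
      f <- vapply(1:6, function(j) stats::rnorm(n, class_means[k, j],
                                                class_sds[k, j]),
                  numeric(n))
      f <- matrix(f, nrow = n)
      df <- as.data.frame(f)
      names(df) <- feature_names()
      df$label <- cell_classes()[k]
      df
    })
    out <- do.call(rbind, rows)
    out$label <- factor(out$label, levels = cell_classes())
    rownames(out) <- NULL
    out
  })
}
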