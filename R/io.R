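#' Read an 8-bit grayscale image
#'
#' Reads a PNG or TIFF file and returns the grey-level matrix (values
#' 0-255, row = y, col = x). Colour images are rejected: the pipeline is
#' defined on single-channel grey-level data.
#'
#' @param path image file path (.png, .tif/.tiff).
#' @return integer matrix of grey levels.
#' @export
read_grey_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format '", ext, "' for ", path,
                     " (need 8-bit grayscale PNG or TIFF)"))
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] == 2L) arr <- arr[, , 1L]   # grey + alpha
    else stop("image is not grayscale (", dim(arr)[3], " channels): ", path)
  }
  img <- round(arr * 255)
  storage.mode(img) <- "integer"
  check_grey_image(img)
  img
}

#' Write a grey image or tri-level mask as PNG
#'
#' Values are written bit-exactly: a mask of 0/127/255 round-trips to the
#' same three values.
#'
#' @param img integer matrix of grey levels 0-255.
#' @param path output .png path.
#' @export
write_grey_image <- function(img, path) {
  check_grey_image(img)
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Read and write labelled feature tables
#'
#' CSV schema: the six feature columns \code{nucleus_size,
#' nucleus_perimeter, nucleus_grey, cytoplasm_size, cytoplasm_perimeter,
#' cytoplasm_grey} followed by \code{label} (normal/LSIL/HSIL). Unknown or
#' missing columns and unknown labels are rejected.
#'
#' @param path CSV file path.
#' @return data.frame with the declared schema.
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  want <- c(feature_names(), "label")
  missing <- setdiff(want, names(df))
  if (length(missing))
    stop("feature CSV is missing columns: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(df), want)
  if (length(extra))
    stop("feature CSV has unknown columns: ", paste(extra, collapse = ", "))
  df <- df[, want]
  for (cn in feature_names())
    if (!is.numeric(df[[cn]])) stop("non-numeric feature column: ", cn)
  bad <- setdiff(unique(df$label), cell_classes())
  if (length(bad))
    stop("unknown labels: ", paste(bad, collapse = ", "),
         " (allowed: ", paste(cell_classes(), collapse = ", "), ")")
  df$label <- factor(df$label, levels = cell_classes())
  df
}

#' @rdname read_feature_csv
#' @param features data.frame to write.
#' @export
write_feature_csv <- function(features, path) {
  utils::write.csv(features[, c(feature_names(), "label")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a fitted MANFIS model to JSON
#'
#' All membership-function and consequent parameters, normalization
#' bounds, class order and the training configuration are written at full
#' double precision; [read_model_json()] restores an equivalent model.
#'
#' @param model fitted [manfis()] object.
#' @param path output .json path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "manfis"))
  sm <- lapply(model$submodels, function(m)
    list(d = m$d, n_mf = m$n_mf, a = m$a, b = m$b, c = m$c,
         rules = m$rules, P = m$P, sse = m$sse))
  payload <- list(type = "manfis", levels = model$levels,
                  features = model$features,
                  bounds = model$bounds, config = model$config,
                  train_accuracy = model$train_accuracy,
                  submodels = sm)
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$type) || p$type != "manfis") stop("not a MANFIS model file: ", path)
  fix <- function(m) { m <- as.matrix(m); dimnames(m) <- NULL; m }
  submodels <- lapply(p$submodels, function(m) {
    rules <- fix(m$rules)
    storage.mode(rules) <- "integer"
    list(d = as.integer(m$d), n_mf = as.integer(m$n_mf),
         a = fix(m$a), b = fix(m$b), c = fix(m$c),
         rules = rules, P = fix(m$P), sse = m$sse)
  })
  structure(list(submodels = submodels, levels = p$levels,
                 features = p$features,
                 bounds = list(lo = unlist(p$bounds$lo),
                               hi = unlist(p$bounds$hi)),
                 config = p$config, train_accuracy = p$train_accuracy),
            class = "manfis")
}

#' Run the full feature-extraction pipeline on one image
#'
#' Executes, in order: grey-level clustering (moving k-means) and
#' threshold computation, nucleus subclustering and moment-centroid seed
#' location, and the segmentation/feature-extraction growing pass. Any
#' stage failure is re-signalled with the stage name (and image path,
#' when the input was a file).
#'
#' @param img grey image matrix or path to an 8-bit grayscale PNG/TIFF.
#' @param window median-filter window, default 3.
#' @param cutoff gradient cutoff percent, default 95.
#' @param ... passed to [moving_k_means()].
#' @return list with \code{centres}, \code{thresholds}, \code{centroid},
#'   \code{mask} and \code{features}.
#' @export
run_afe_pipeline <- function(img, window = 3L, cutoff = 95, ...) {
  src <- if (is.character(img)) img else "<matrix>"
  if (is.character(img)) img <- read_grey_image(img)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("AFE stage '", name, "' failed for ", src, ": ", conditionMessage(e),
         call. = FALSE))
  thr <- stage("clustering", afe_thresholds(img, ...))
  seed <- stage("centroid", nucleus_centroid(img, thr$thresholds))
  seg <- stage("segmentation",
               segment_and_extract(img, thr$thresholds, seed,
                                   window = window, cutoff = cutoff))
  list(centres = thr$centres, initial = thr$initial,
       thresholds = thr$thresholds, centroid = seed,
       mask = seg$mask, features = seg$features)
}
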