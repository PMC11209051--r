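#' Construct an ultrasound frame object
#'
#' An `ultrasound_frame` bundles an 8-bit grayscale pixel grid with its
#' spatial calibration and named binary region masks. Pixels use a row-major
#' grid (origin top-left); masks are logical matrices of identical shape.
#' The parenchyma and mediastinum masks must be disjoint (the parenchymal
#' outline excludes the mediastinum testis by construction).
#'
#' @param pixels integer matrix, grayscale values 0-255.
#' @param mm_per_pixel spatial calibration, mm per pixel (> 0).
#' @param masks named list of logical matrices; recognised names are
#'   `parenchyma`, `mediastinum`, `capsule` and optionally `doppler`.
#' @param week,dog_id,side exam metadata (optional).
#' @return an object of class `ultrasound_frame`.
#' @export
ultrasound_frame <- function(pixels, mm_per_pixel, masks,
                             week = NA_real_, dog_id = NA_character_,
                             side = NA_character_) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (any(pixels < 0 | pixels > 255, na.rm = TRUE)) {
    stop("grayscale values must lie in [0, 255]")
  }
  if (mm_per_pixel <= 0) stop("mm_per_pixel must be positive")
  storage.mode(pixels) <- "integer"
  if (!is.list(masks) || is.null(names(masks))) {
    stop("masks must be a named list of logical matrices")
  }
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.matrix(m) || !identical(dim(m), dim(pixels))) {
      stop("mask '", nm, "' must be a matrix with the same shape as pixels")
    }
    storage.mode(masks[[nm]]) <- "logical"
  }
  if (!is.null(masks$parenchyma) && !is.null(masks$mediastinum) &&
      any(masks$parenchyma & masks$mediastinum)) {
    stop("parenchyma and mediastinum masks must be disjoint")
  }
  structure(list(pixels = pixels, mm_per_pixel = mm_per_pixel,
                 masks = masks, week = week, dog_id = dog_id, side = side),
            class = "ultrasound_frame")
}

#' @export
print.ultrasound_frame <- function(x, ...) {
  cat(sprintf("<ultrasound_frame> %dx%d px @ %.2f mm/px", nrow(x$pixels),
              ncol(x$pixels), x$mm_per_pixel))
  if (!is.na(x$week)) cat(sprintf(" | %s %s wk%g", x$dog_id, x$side, x$week))
  cat("\n  masks:", paste(names(x$masks), sapply(x$masks, sum),
                          collapse = ", "), "\n")
  invisible(x)
}
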