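# CSV cohort I/O and PNG frame I/O with plain-text sidecar metadata.

cohort_columns <- function() {
  c("dog_id", "testis_side", "week", "weight", "height",
    "scrotal_l", "scrotal_w", "scrotal_h",
    "testis_l", "testis_w", "testis_h",
    "us_l", "us_w", "us_h",
    "ejaculate_volume", "motility", "viability", "concentration",
    "total_sperm", "doppler_score", "frame_path")
}

#' Write a cohort table to CSV
#'
#' One header row, missing semen values encoded as empty strings.
#'
#' @param cohort cohort table.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Validates that the documented exam-record columns are present (naming any
#' that are missing), maps empty semen cells to `NA`, and preserves any
#' extra columns untouched.
#'
#' @param path CSV file.
#' @return data.frame of class `exam_cohort`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  missing <- setdiff(cohort_columns(), names(d))
  if (length(missing) > 0) {
    stop("cohort file is missing column(s): ", paste(missing, collapse = ", "))
  }
  num_cols <- setdiff(cohort_columns(), c("dog_id", "testis_side",
                                          "frame_path"))
  for (nm in num_cols) {
    if (!is.numeric(d[[nm]])) {
      suppressWarnings(v <- as.numeric(d[[nm]]))
      if (any(is.na(v) & !is.na(d[[nm]]))) {
        stop("non-numeric values in column ", nm)
      }
      d[[nm]] <- v
    }
  }
  d$frame_path[is.na(d$frame_path)] <- ""
  class(d) <- c("exam_cohort", "data.frame")
  d
}

#' Write a frame (and its masks) as PNG with sidecar metadata
#'
#' The pixel grid is written as an 8-bit grayscale PNG, each mask as a 0/255
#' single-channel PNG (`<stem>_mask_<name>.png`), and a plain-text sidecar
#' (`<stem>.txt`) records `mm_per_pixel`, `week`, `dog_id`, `side` and the
#' rendering seed as `key: value` lines.
#'
#' @param frame an [ultrasound_frame()].
#' @param path PNG path for the pixel grid.
#' @param seed optional rendering seed recorded in the sidecar.
#' @return the path, invisibly.
#' @export
write_frame_png <- function(frame, path, seed = NA) {
  png::writePNG(frame$pixels / 255, path)
  stem <- sub("\\.png$", "", path)
  for (nm in names(frame$masks)) {
    png::writePNG(frame$masks[[nm]] * 1, paste0(stem, "_mask_", nm, ".png"))
  }
  meta <- c(mm_per_pixel = frame$mm_per_pixel, week = frame$week,
            dog_id = frame$dog_id, side = frame$side, seed = seed)
  writeLines(paste0(names(meta), ": ", unlist(meta)), paste0(stem, ".txt"))
  invisible(path)
}

#' Read a frame written by [write_frame_png()]
#'
#' @param path PNG path of the pixel grid.
#' @return an [ultrasound_frame()].
#' @export
read_frame_png <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  px <- round(px * 255)
  stem <- sub("\\.png$", "", path)
  mask_files <- Sys.glob(paste0(stem, "_mask_*.png"))
  masks <- list()
  for (f in mask_files) {
    nm <- sub(".*_mask_(.*)\\.png$", "\\1", f)
    m <- png::readPNG(f)
    if (length(dim(m)) == 3) m <- m[, , 1]
    masks[[nm]] <- m > 0.5
  }
  meta <- list(mm_per_pixel = NA_real_, week = NA_real_,
               dog_id = NA_character_, side = NA_character_)
  sidecar <- paste0(stem, ".txt")
  if (file.exists(sidecar)) {
    for (ln in readLines(sidecar)) {
      kv <- strsplit(ln, ": ", fixed = TRUE)[[1]]
      if (length(kv) == 2 && kv[1] %in% names(meta)) meta[[kv[1]]] <- kv[2]
    }
  }
  ultrasound_frame(px, as.numeric(meta$mm_per_pixel), masks,
                   week = as.numeric(meta$week),
                   dog_id = as.character(meta$dog_id),
                   side = as.character(meta$side))
}

#' Write a colour-Doppler overlay as an RGB PNG
#'
#' Flow pixels are painted red over the grayscale frame; non-flow pixels stay
#' grey (equal channels), so flow is recoverable as any non-grey pixel.
#'
#' @param overlay logical flow matrix.
#' @param frame the underlying [ultrasound_frame()] (for the B-mode
#'   background).
#' @param path output PNG.
#' @return the path, invisibly.
#' @export
write_overlay_png <- function(overlay, frame, path) {
  g <- frame$pixels / 255
  rgb <- array(rep(g, 3), dim = c(nrow(g), ncol(g), 3))
  rgb[, , 1][overlay] <- 1
  rgb[, , 2][overlay] <- 0.15
  rgb[, , 3][overlay] <- 0.15
  png::writePNG(rgb, path)
  invisible(path)
}

#' Read a flow overlay from an RGB PNG
#'
#' @param path PNG written by [write_overlay_png()] (or any RGB overlay
#'   where non-grey pixels mark flow).
#' @return logical flow matrix.
#' @export
read_overlay_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) return(a > 0.5)
  abs(a[, , 1] - a[, , 2]) > 0.02 | abs(a[, , 1] - a[, , 3]) > 0.02
}
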