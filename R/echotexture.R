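# Echotexture quantification: spot-meter and region-area techniques,
# standardization ratios, echogenicity categories.

effective_parenchyma <- function(frame) {
  m <- frame$masks$parenchyma
  if (is.null(m)) stop("frame has no parenchyma mask")
  if (!is.null(frame$masks$mediastinum)) m <- m & !frame$masks$mediastinum
  m
}

#' Place spot-meter regions of interest
#'
#' Places `n_spots` non-overlapping square spots (default nine spots of
#' 2 mm^2) fully inside the parenchyma mask and fully outside the mediastinum
#' mask. Placement is deterministic: target centres form a 3x3 grid over the
#' bounding box of the effective mask and each spot snaps to the nearest
#' fully-contained, non-overlapping position (row-major order). Spots of a
#' standard area may not fit within very small (young) testes, in which case
#' placement fails.
#'
#' @param frame an [ultrasound_frame()].
#' @param n_spots number of spots.
#' @param spot_area_mm2 spot area in mm^2; the pixel side is
#'   `round(sqrt(spot_area_mm2) / mm_per_pixel)`.
#' @return data.frame with one row per spot: `row`, `col` (top-left corner),
#'   `side`, `center_row`, `center_col`.
#' @export
place_spots <- function(frame, n_spots = 9, spot_area_mm2 = 2) {
  eff <- effective_parenchyma(frame)
  if (!any(eff)) stop("spot-meter infeasible: empty parenchyma mask")
  side <- max(1L, as.integer(round(sqrt(spot_area_mm2) / frame$mm_per_pixel)))

  nr <- nrow(eff); nc <- ncol(eff)
  if (side > nr || side > nc) stop("spot-meter infeasible: spots exceed frame")
  # summed-area table: a top-left (r, c) is valid iff the side x side box sum
  # equals side^2 (box entirely inside the effective mask)
  sat <- apply(apply(eff, 2, cumsum), 1, cumsum)   # sat[c, r] after transpose
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))
  box_sum <- sat[(side + 1):(nr + 1), (side + 1):(nc + 1)] -
    sat[1:(nr - side + 1), (side + 1):(nc + 1)] -
    sat[(side + 1):(nr + 1), 1:(nc - side + 1)] +
    sat[1:(nr - side + 1), 1:(nc - side + 1)]
  valid <- which(box_sum == side^2, arr.ind = TRUE)
  if (nrow(valid) < n_spots) stop("spot-meter infeasible")

  bb <- which(eff, arr.ind = TRUE)
  r1 <- min(bb[, 1]); r2 <- max(bb[, 1])
  c1 <- min(bb[, 2]); c2 <- max(bb[, 2])
  g <- ceiling(sqrt(n_spots))
  centers <- expand.grid(
    cc = c1 + (2 * seq_len(g) - 1) / (2 * g) * (c2 - c1),
    rr = r1 + (2 * seq_len(g) - 1) / (2 * g) * (r2 - r1)
  )[seq_len(n_spots), c("rr", "cc")]

  placed <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n_spots)) {
    want_r <- centers$rr[i] - (side - 1) / 2
    want_c <- centers$cc[i] - (side - 1) / 2
    d2 <- (valid[, 1] - want_r)^2 + (valid[, 2] - want_c)^2
    found <- FALSE
    for (j in order(d2)) {
      cand <- valid[j, ]
      if (nrow(placed) == 0 ||
          all(abs(placed[, 1] - cand[1]) >= side |
              abs(placed[, 2] - cand[2]) >= side)) {
        placed <- rbind(placed, cand)
        found <- TRUE
        break
      }
    }
    if (!found) stop("spot-meter infeasible")
  }
  data.frame(spot = seq_len(n_spots),
             row = placed[, 1], col = placed[, 2], side = side,
             center_row = placed[, 1] + (side - 1) / 2,
             center_col = placed[, 2] + (side - 1) / 2,
             row.names = NULL)
}

#' Spot-meter grayscale statistics
#'
#' Mean grayscale intensity is the mean of the per-spot means; heterogeneity
#' is the standard deviation (n - 1 denominator) of the per-spot means, the
#' spot-meter convention for textural variability.
#'
#' @param frame an [ultrasound_frame()].
#' @param spots spot table from [place_spots()].
#' @return list with `mean_gi`, `heterogeneity` and the vector `spot_means`.
#' @export
spot_meter_stats <- function(frame, spots) {
  if (nrow(spots) < 2) stop("at least 2 spots are required")
  m <- vapply(seq_len(nrow(spots)), function(i) {
    r <- spots$row[i]; c <- spots$col[i]; s <- spots$side[i]
    vals <- frame$pixels[r:(r + s - 1), c:(c + s - 1)]
    if (length(vals) == 0) stop("empty spot")
    mean(vals)
  }, numeric(1))
  list(mean_gi = mean(m), heterogeneity = sd(m), spot_means = m)
}

#' Region-area grayscale statistics
#'
#' Mean and standard deviation (n - 1 denominator) of all pixel values in the
#' parenchyma mask with the mediastinum testis excluded. The pixel SD is the
#' region-area heterogeneity measure.
#'
#' @param frame an [ultrasound_frame()].
#' @return list with `mean_gi`, `heterogeneity`, `n_pixels`.
#' @export
region_area_stats <- function(frame) {
  eff <- effective_parenchyma(frame)
  if (!any(eff)) stop("empty effective parenchyma mask")
  px <- frame$pixels[eff]
  list(mean_gi = mean(px), heterogeneity = sd(px), n_pixels = length(px))
}

#' Mean grayscale intensity of a reference structure
#'
#' @param frame an [ultrasound_frame()].
#' @param structure `"mediastinum"` or `"capsule"`.
#' @return mean grayscale intensity over the structure mask, or `NA` ("not
#'   imaged") when the mask is empty — e.g. the mediastinum before its onset
#'   week. An empty mask is never reported as intensity zero.
#' @export
structure_gi <- function(frame, structure = c("mediastinum", "capsule")) {
  structure <- match.arg(structure)
  m <- frame$masks[[structure]]
  if (is.null(m) || !any(m)) {
    out <- NA_real_
    attr(out, "not_imaged") <- TRUE
    return(out)
  }
  mean(frame$pixels[m])
}

#' Percent echogenicity standardization ratio
#'
#' `reference_gi / parenchyma_gi * 100`, with the capsule (tunica albuginea)
#' as the standard reference and the mediastinum testis as the modified
#' variant.
#'
#' @param reference_gi mean grayscale intensity of the reference structure.
#' @param parenchyma_gi mean grayscale intensity of the parenchyma (> 0).
#' @return ratio in percent; `NA` inputs propagate.
#' @export
#' @examples
#' percent_echogenicity(215, 115)
percent_echogenicity <- function(reference_gi, parenchyma_gi) {
  if (anyNA(c(reference_gi, parenchyma_gi))) return(NA_real_)
  if (any(parenchyma_gi == 0)) {
    stop("percent echogenicity undefined: parenchyma GI is zero")
  }
  reference_gi / parenchyma_gi * 100
}

#' Categorize echogenicity
#'
#' Allocates a mean grayscale intensity to low (0-85), moderate (86-170) or
#' high (171-255) echogenicity. Non-integer values are rounded half-up before
#' classification.
#'
#' @param gi grayscale intensity values in `[0, 255]` (vectorized).
#' @return factor with levels `low`, `moderate`, `high`.
#' @export
#' @examples
#' categorize_echogenicity(c(85, 86, 170, 171))
categorize_echogenicity <- function(gi) {
  if (any(is.na(gi)) || any(gi < 0 | gi > 255)) {
    stop("grayscale intensity must lie in [0, 255]")
  }
  r <- floor(gi + 0.5)   # round half-up
  factor(ifelse(r <= 85, "low", ifelse(r <= 170, "moderate", "high")),
         levels = c("low", "moderate", "high"))
}

#' Measure one frame
#'
#' Runs both echotexture techniques, the structure intensities and the
#' standardization ratios on a frame. Spot-meter values are `NA` when nine
#' spots do not fit (small testes).
#'
#' @param frame an [ultrasound_frame()].
#' @return one-row data.frame: `gi_spot`, `het_spot`, `gi_region`,
#'   `het_region`, `gi_mt`, `gi_capsule`, `ratio_cap`, `ratio_mt`,
#'   `category`, `spot_feasible`.
#' @export
measure_frame <- function(frame) {
  reg <- region_area_stats(frame)
  spots <- try(place_spots(frame), silent = TRUE)
  if (inherits(spots, "try-error")) {
    sp <- list(mean_gi = NA_real_, heterogeneity = NA_real_)
    feasible <- FALSE
  } else {
    sp <- spot_meter_stats(frame, spots)
    feasible <- TRUE
  }
  gi_mt <- as.numeric(structure_gi(frame, "mediastinum"))
  gi_cap <- as.numeric(structure_gi(frame, "capsule"))
  data.frame(
    gi_spot = sp$mean_gi, het_spot = sp$heterogeneity,
    gi_region = reg$mean_gi, het_region = reg$heterogeneity,
    gi_mt = gi_mt, gi_capsule = gi_cap,
    ratio_cap = percent_echogenicity(gi_cap, reg$mean_gi),
    ratio_mt = percent_echogenicity(gi_mt, reg$mean_gi),
    category = as.character(categorize_echogenicity(reg$mean_gi)),
    spot_feasible = feasible
  )
}

#' Measure every exam of a synthetic cohort
#'
#' Renders the B-mode frame and colour-Doppler overlay for each record of a
#' [generate_cohort()] table (deterministically, from seeds derived from the
#' cohort's master seed), measures echotexture, and re-scores the Doppler
#' overlay with [detect_vessels()] + [score_doppler()].
#'
#' @param cohort a cohort table from [generate_cohort()] (must carry its
#'   `profiles` and `config` attributes).
#' @param frames_dir optional directory; when given, frames and masks are
#'   written as PNGs with sidecar metadata and `frame_path` is filled in.
#' @return the cohort with measurement columns appended, including
#'   `doppler_score_detected`.
#' @export
measure_cohort <- function(cohort, frames_dir = NULL) {
  profiles <- attr(cohort, "profiles")
  config <- attr(cohort, "config")
  if (is.null(profiles) || is.null(config)) {
    stop("cohort must carry its generator attributes (profiles, config)")
  }
  if (!is.null(frames_dir) && !dir.exists(frames_dir)) {
    dir.create(frames_dir, recursive = TRUE)
  }
  res <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    dog <- cohort$dog_id[i]
    wk <- cohort$week[i]
    side <- cohort$testis_side[i]
    fseed <- sub_seed(config$master_seed, dog, wk, side, 3)
    fr <- render_bmode_frame(profiles[[dog]], wk,
                             size = config$image_size,
                             mm_per_pixel = config$mm_per_pixel,
                             seed = fseed)
    fr$side <- side
    row <- measure_frame(fr)
    sc <- cohort$doppler_score[i]
    if (!is.na(sc)) {
      ov <- render_doppler_overlay(sc, sub_seed(config$master_seed, dog,
                                                wk, side, 4),
                                   fr$masks$parenchyma)
      comps <- detect_vessels(ov, fr$masks$parenchyma)
      row$doppler_score_detected <- score_doppler(comps)$score
    } else {
      row$doppler_score_detected <- NA_integer_
    }
    if (!is.null(frames_dir)) {
      path <- file.path(frames_dir,
                        sprintf("%s_%s_wk%02d.png", dog, side, wk))
      write_frame_png(fr, path, seed = fseed)
      cohort$frame_path[i] <- path
    }
    res[[i]] <- row
  }
  out <- cbind(cohort, do.call(rbind, res))
  attr(out, "profiles") <- profiles
  attr(out, "config") <- config
  out
}
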