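#' Per-dog maturation profile
#'
#' A maturation profile holds the trajectory parameters that drive the
#' synthetic generator for one dog: grayscale-intensity (GI) anchors for the
#' testicular parenchyma, mediastinum testis and capsule (all on the 0-255
#' pixel scale), somatometric asymptotes, puberty milestone weeks and noise
#' levels.
#'
#' Defaults encode the study conditions the generator emulates: parenchymal
#' GI starts at 55 at week 6 (with a 3-unit dip from week 4), rises at
#' 2.525 GI units/week until the plateau week (30), then drifts by
#' 0.45 units/week (an approximate plateau: successive biweekly medians move
#' less than 1 unit, below the plateau-detection tolerance); the mediastinum
#' appears at week 8 at GI 80 and rises at 4.251 units/week, exceeding 190 at
#' the fertile milestone; the capsule plateaus at 215 after week 32;
#' parenchymal heterogeneity (pixel SD) rises from 8 to 22 by week 36.
#' Milestones are first ejaculate at week 28, first spermatozoa at week 30,
#' fertile ejaculates (total sperm > 200 million) from week 36.
#'
#' @param dog_id identifier.
#' @param adult_weight,adult_height,adult_testis_volume asymptotic bodyweight
#'   (kg), withers height (cm) and ultrasonographic testis volume (cm^3).
#' @param gi_start parenchymal GI at week 6.
#' @param gi_slope parenchymal GI rise, units/week, weeks 6 to plateau.
#' @param gi_plateau_week week at which the parenchymal rise ends.
#' @param gi_dip GI units lost between weeks 4 and 6 (early hypoechoic dip).
#' @param gi_late_slope residual GI drift per week after the plateau week.
#' @param mt_onset_week first week the mediastinum is imaged.
#' @param mt_start,mt_slope mediastinum GI at onset and rise per week (the
#'   mediastinum trajectory levels off at the fertile milestone).
#' @param capsule_start,capsule_plateau,capsule_plateau_week capsule GI at
#'   week 4, its plateau value, and the week the plateau is reached.
#' @param het_start,het_end,het_end_week parenchymal heterogeneity (pixel SD)
#'   at week 4 and its terminal value/week.
#' @param milestone_weeks named numeric triple
#'   `c(first_ejaculate, first_sperm, fertile)`, strictly increasing.
#' @param noise_sd exam-level GI noise scale (grayscale units). `0` is the
#'   analytic zero-noise limit: frames are rendered without speckle and all
#'   trajectories are hit exactly.
#' @param seed integer seed for this dog's latent draws.
#' @return an object of class `maturation_profile` (a validated list).
#' @seealso [cohort_config()], [generate_cohort()], [render_bmode_frame()]
#' @export
#' @examples
#' maturation_profile(dog_id = "dog1")
maturation_profile <- function(dog_id = "dog1",
                               adult_weight = 12,
                               adult_height = 38,
                               adult_testis_volume = 9.5,
                               gi_start = 55,
                               gi_slope = 2.525,
                               gi_plateau_week = 30,
                               gi_dip = 3,
                               gi_late_slope = 0.45,
                               mt_onset_week = 8,
                               mt_start = 80,
                               mt_slope = 4.251,
                               capsule_start = 140,
                               capsule_plateau = 215,
                               capsule_plateau_week = 32,
                               het_start = 8,
                               het_end = 22,
                               het_end_week = 36,
                               milestone_weeks = c(first_ejaculate = 28,
                                                   first_sperm = 30,
                                                   fertile = 36),
                               noise_sd = 1.5,
                               seed = 1L) {
  p <- list(dog_id = as.character(dog_id),
            adult_weight = adult_weight, adult_height = adult_height,
            adult_testis_volume = adult_testis_volume,
            gi_start = gi_start, gi_slope = gi_slope,
            gi_plateau_week = gi_plateau_week, gi_dip = gi_dip,
            gi_late_slope = gi_late_slope,
            mt_onset_week = mt_onset_week, mt_start = mt_start,
            mt_slope = mt_slope,
            capsule_start = capsule_start,
            capsule_plateau = capsule_plateau,
            capsule_plateau_week = capsule_plateau_week,
            het_start = het_start, het_end = het_end,
            het_end_week = het_end_week,
            milestone_weeks = milestone_weeks,
            noise_sd = noise_sd, seed = as.integer(seed))
  validate_profile(p)
  class(p) <- "maturation_profile"
  p
}

validate_profile <- function(p) {
  gs <- c(p$gi_start, p$mt_start, p$capsule_start, p$capsule_plateau)
  if (any(gs < 0 | gs > 255)) {
    stop("grayscale parameters must lie in [0, 255]")
  }
  mw <- p$milestone_weeks
  if (length(mw) != 3 || any(diff(mw) <= 0)) {
    stop("milestone_weeks must be a strictly increasing triple")
  }
  if (p$gi_plateau_week < 4 || p$gi_plateau_week > 40) {
    stop("gi_plateau_week must lie within the study window (weeks 4-40)")
  }
  if (p$noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(c(p$adult_weight, p$adult_height, p$adult_testis_volume) <= 0)) {
    stop("adult somatometric parameters must be positive")
  }
  invisible(p)
}

#' @export
print.maturation_profile <- function(x, ...) {
  cat("<maturation_profile>", x$dog_id, "\n")
  cat(sprintf("  parenchyma GI: %.1f @wk6, +%.3f/wk to wk%d (then +%.2f/wk)\n",
              x$gi_start, x$gi_slope, x$gi_plateau_week, x$gi_late_slope))
  cat(sprintf("  mediastinum: onset wk%d @%.0f, +%.3f/wk; capsule plateau %.0f\n",
              x$mt_onset_week, x$mt_start, x$mt_slope, x$capsule_plateau))
  cat(sprintf("  milestones (first ejaculate / first sperm / fertile): %s\n",
              paste(x$milestone_weeks, collapse = " / ")))
  invisible(x)
}

#' Cohort-level simulation configuration
#'
#' @param n_dogs number of dogs (>= 1).
#' @param weeks ordered vector of exam weeks of age; the default biweekly
#'   grid runs from week 4 to week 40.
#' @param testes_per_dog testes examined per dog.
#' @param master_seed integer master seed; every per-dog and per-frame seed
#'   is derived from it with [sub_seed()].
#' @param image_size rendered frame side, pixels.
#' @param mm_per_pixel spatial calibration, mm per pixel.
#' @return an object of class `cohort_config`.
#' @export
#' @examples
#' cohort_config(n_dogs = 8, master_seed = 1)
cohort_config <- function(n_dogs = 8,
                          weeks = seq(4, 40, by = 2),
                          testes_per_dog = 2,
                          master_seed = 1,
                          image_size = 192,
                          mm_per_pixel = 0.2) {
  if (length(n_dogs) != 1 || is.na(n_dogs) || n_dogs < 1) {
    stop("n_dogs must be a positive count")
  }
  if (length(weeks) < 1 || anyNA(weeks) || is.unsorted(weeks, strictly = TRUE)) {
    stop("weeks must be a non-empty strictly ascending grid")
  }
  if (any(weeks < 4 | weeks > 40)) {
    stop("exam weeks must lie within the study window (weeks 4-40)")
  }
  if (mm_per_pixel <= 0) stop("mm_per_pixel must be positive")
  structure(list(n_dogs = as.integer(n_dogs), weeks = as.numeric(weeks),
                 testes_per_dog = as.integer(testes_per_dog),
                 master_seed = as.integer(master_seed),
                 image_size = as.integer(image_size),
                 mm_per_pixel = mm_per_pixel),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> %d dogs x %d testes, weeks %s-%s (%d exams), seed %d\n",
              x$n_dogs, x$testes_per_dog, min(x$weeks), max(x$weeks),
              length(x$weeks), x$master_seed))
  invisible(x)
}
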