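# Synthetic longitudinal cohort generation.
#
# One latent maturation curve per dog (persistent factor u, AR(1) exam latent
# z); left and right testes are exchangeable draws around it. The same (u, z)
# pair feeds the parenchymal grayscale intensity used for frame rendering and
# (scaled) the log10 total sperm count, giving the monotone GI-sperm coupling
# the correlation analyses assume. Doppler scores are stratified to the
# reference week-specific proportions rather than drawn i.i.d.

# log10 total sperm loadings on the shared latents (frozen design constants).
SPERM_U_LOADING <- 0.05
SPERM_Z_LOADING <- 0.18
SPERM_RESID_SD <- 0.05

#' Generate a synthetic longitudinal cohort
#'
#' Produces one exam record per dog x testis x week with somatometrics,
#' calliper and ultrasonographic testis dimensions, semen parameters and a
#' stratified colour-Doppler score. Semen fields are missing before each
#' dog's first-ejaculate milestone; total sperm is zero at the first
#' ejaculate, low with zero motility at the first-sperm week, and the cohort
#' median exceeds the 200-million fertility threshold from the fertile week.
#'
#' @param config a [cohort_config()].
#' @param profile_overrides optional named list of [maturation_profile()]
#'   fields applied to every dog (e.g. `list(noise_sd = 0)`), or a list of
#'   such lists keyed by dog id.
#' @return data.frame of exam records (class `exam_cohort`), carrying the
#'   per-dog profiles and the config as attributes for downstream frame
#'   rendering.
#' @seealso [measure_cohort()], [write_cohort()]
#' @export
#' @examples
#' co <- generate_cohort(cohort_config(n_dogs = 2, master_seed = 1))
#' head(co)
generate_cohort <- function(config, profile_overrides = NULL) {
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config")
  profiles <- make_profiles(config, profile_overrides)
  rows <- list()
  for (dog in names(profiles)) {
    p <- profiles[[dog]]
    rows[[dog]] <- generate_dog(p, config)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$doppler_score <- assign_doppler_scores(out, config)
  attr(out, "profiles") <- profiles
  attr(out, "config") <- config
  class(out) <- c("exam_cohort", "data.frame")
  out
}

make_profiles <- function(config, overrides) {
  global <- NULL
  per_dog <- NULL
  if (!is.null(overrides)) {
    proto <- maturation_profile()
    if (all(names(overrides) %in% names(proto))) {
      global <- overrides
    } else {
      per_dog <- overrides
    }
  }
  profiles <- list()
  for (d in seq_len(config$n_dogs)) {
    dog <- paste0("dog", d)
    jit <- with_seed(sub_seed(config$master_seed, d, 1), rnorm(3))
    args <- list(dog_id = dog,
                 adult_weight = 12 * exp(0.06 * jit[1]),
                 adult_height = 38 * exp(0.04 * jit[2]),
                 adult_testis_volume = 9.5 * exp(0.10 * jit[3]),
                 seed = sub_seed(config$master_seed, d, 2))
    for (nm in names(global)) args[[nm]] <- global[[nm]]
    for (nm in names(per_dog[[dog]])) args[[nm]] <- per_dog[[dog]][[nm]]
    profiles[[dog]] <- do.call(maturation_profile, args)
  }
  profiles
}

generate_dog <- function(p, config) {
  weeks <- config$weeks
  ns <- p$noise_sd
  lat <- if (ns > 0) exam_latents(p, weeks) else
    list(u = 0, z = rep(0, length(weeks)))
  mw <- p$milestone_weeks
  fe <- mw[["first_ejaculate"]]; fs <- mw[["first_sperm"]]

  per_dog <- with_seed(sub_seed(p$seed, 31), {
    nweek <- length(weeks)
    m_noise <- function(sdv) if (ns > 0) rnorm(nweek, 0, sdv) else rep(0, nweek)
    weight <- p$adult_weight * growth_fraction(weeks, "weight") *
      exp(m_noise(0.015))
    height <- p$adult_height * growth_fraction(weeks, "height") *
      exp(m_noise(0.01))
    vol_latent <- p$adult_testis_volume * growth_fraction(weeks, "volume") *
      exp(m_noise(0.04))

    semen <- weeks >= fe
    tot <- rep(NA_real_, nweek)
    med <- traj_sperm_median(p, weeks)
    tot[semen] <- ifelse(med[semen] <= 0, 0,
                         10^(log10(pmax(med[semen], 1)) +
                             SPERM_U_LOADING * lat$u +
                             SPERM_Z_LOADING * lat$z[semen] +
                             SPERM_RESID_SD * m_noise(1)[semen]))
    ej_vol <- ifelse(semen, pmax(traj_ejaculate_volume(weeks) *
                                   exp(m_noise(0.08)), 0.1), NA_real_)
    motility <- ifelse(semen & weeks >= fs,
                       pmin(pmax(traj_motility(p, weeks) + m_noise(4), 0),
                            100), ifelse(semen, 0, NA_real_))
    motility[semen & weeks == fs] <- 0
    viability <- ifelse(semen & weeks >= fs + 2,
                        pmin(pmax(rnorm(nweek, 87, 3), 70), 98), NA_real_)
    list(weight = weight, height = height, vol_latent = vol_latent,
         tot = tot, ej_vol = ej_vol, motility = motility,
         viability = viability)
  })

  sides <- c("left", "right")[seq_len(config$testes_per_dog)]
  out <- list()
  for (s_i in seq_along(sides)) {
    dims <- with_seed(sub_seed(p$seed, 41, s_i), {
      n <- length(weeks)
      d_noise <- function(sdv) if (ns > 0) rnorm(n, 0, sdv) else rep(0, n)
      us_l <- (per_dog$vol_latent / (0.71 * 0.36))^(1 / 3) * exp(d_noise(0.02))
      us_w <- 0.6 * us_l * exp(d_noise(0.02))
      us_h <- 0.6 * us_l * exp(d_noise(0.02))
      t_l <- us_l * 1.25 * exp(d_noise(0.015))
      t_w <- us_w * 1.25 * exp(d_noise(0.015))
      t_h <- us_h * 1.25 * exp(d_noise(0.015))
      list(us_l = us_l, us_w = us_w, us_h = us_h,
           testis_l = t_l, testis_w = t_w, testis_h = t_h,
           scrotal_l = t_l * 1.12, scrotal_w = t_w * 1.12,
           scrotal_h = t_h * 1.12)
    })
    conc <- ifelse(is.na(per_dog$tot) | is.na(per_dog$ej_vol), NA_real_,
                   per_dog$tot / per_dog$ej_vol)
    out[[s_i]] <- data.frame(
      dog_id = p$dog_id, testis_side = sides[s_i], week = weeks,
      weight = per_dog$weight, height = per_dog$height,
      scrotal_l = dims$scrotal_l, scrotal_w = dims$scrotal_w,
      scrotal_h = dims$scrotal_h,
      testis_l = dims$testis_l, testis_w = dims$testis_w,
      testis_h = dims$testis_h,
      us_l = dims$us_l, us_w = dims$us_w, us_h = dims$us_h,
      ejaculate_volume = per_dog$ej_vol, motility = per_dog$motility,
      viability = per_dog$viability, concentration = conc,
      total_sperm = per_dog$tot,
      doppler_score = NA_integer_, frame_path = "",
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

# Stratified week-wise Doppler class assignment: the reference percentages
# are apportioned to the n testes examined that week by largest remainder,
# then shuffled deterministically across testes.
assign_doppler_scores <- function(cohort, config) {
  tab <- doppler_score_table()
  scores <- rep(NA_integer_, nrow(cohort))
  for (w in unique(cohort$week)) {
    idx <- which(cohort$week == w)
    ref_w <- max(tab$week[tab$week <= w])   # nearest tabulated week at or below
    pr <- tab[tab$week == ref_w, -1]
    counts <- apportion_scores(as.numeric(pr[1, ]), length(idx))
    pool <- rep(0:4, counts)
    perm <- with_seed(sub_seed(config$master_seed, w, 5),
                      sample(length(pool)))
    scores[idx] <- pool[perm]
  }
  scores
}
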