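# Noise-free trajectory targets for one profile. These are the quantities a
# perfect measurement would recover; the generator adds exam-level latents and
# speckle sampling noise on top.

#' Evaluate a profile's noise-free trajectories
#'
#' Returns the expected grayscale-intensity, heterogeneity, growth-fraction
#' and semen trajectories of a [maturation_profile()] on a week grid. Useful
#' for plotting the programmed study conditions and as the oracle in
#' parameter-recovery checks.
#'
#' @param profile a [maturation_profile()].
#' @param weeks numeric vector of weeks of age.
#' @return a data.frame with one row per week: `gi_parenchyma`, `het`,
#'   `gi_mediastinum` (NA before onset), `gi_capsule`, `frac_weight`,
#'   `frac_height`, `frac_volume`, `total_sperm_median` (NA before the first
#'   ejaculate milestone).
#' @export
#' @examples
#' trajectory_targets(maturation_profile(), c(4, 20, 36))
trajectory_targets <- function(profile, weeks) {
  data.frame(
    week = weeks,
    gi_parenchyma = traj_parenchyma(profile, weeks),
    het = traj_het(profile, weeks),
    gi_mediastinum = traj_mediastinum(profile, weeks),
    gi_capsule = traj_capsule(profile, weeks),
    frac_weight = growth_fraction(weeks, "weight"),
    frac_height = growth_fraction(weeks, "height"),
    frac_volume = growth_fraction(weeks, "volume"),
    total_sperm_median = traj_sperm_median(profile, weeks)
  )
}

traj_parenchyma <- function(profile, week) {
  plateau <- profile$gi_start +
    profile$gi_slope * (profile$gi_plateau_week - 6)
  out <- ifelse(week < 6,
                profile$gi_start + profile$gi_dip,
                ifelse(week <= profile$gi_plateau_week,
                       profile$gi_start + profile$gi_slope * (week - 6),
                       plateau + profile$gi_late_slope *
                         (week - profile$gi_plateau_week)))
  pmin(pmax(out, 0), 255)
}

traj_mediastinum <- function(profile, week) {
  cap_week <- profile$milestone_weeks[["fertile"]]
  out <- profile$mt_start +
    profile$mt_slope * (pmin(week, cap_week) - profile$mt_onset_week)
  out[week < profile$mt_onset_week] <- NA_real_
  pmin(pmax(out, 0), 255)
}

traj_capsule <- function(profile, week) {
  frac <- (pmin(week, profile$capsule_plateau_week) - 4) /
    (profile$capsule_plateau_week - 4)
  out <- profile$capsule_start +
    (profile$capsule_plateau - profile$capsule_start) * pmax(frac, 0)
  pmin(pmax(out, 0), 255)
}

traj_het <- function(profile, week) {
  frac <- (pmin(week, profile$het_end_week) - 4) / (profile$het_end_week - 4)
  pmax(profile$het_start +
         (profile$het_end - profile$het_start) * pmax(frac, 0), 1)
}

# Growth fractions (share of the adult value). Logistic anchors reproduce the
# percent-of-maturity milestones: weight 86%/95% and height 95%/99% at the
# first-sperm and fertile weeks, testis volume 0.2 cm^3 at week 4 (about 2%
# of adult) and 96% of adult at the fertile week.
growth_fraction <- function(week, what = c("weight", "height", "volume")) {
  what <- match.arg(what)
  switch(what,
         weight = 0.15 + 0.85 * plogis((week - 21.5) / 5.2),
         height = 0.35 + 0.65 * plogis((week - 21.2) / 3.56),
         volume = 0.02 + 0.98 * plogis((week - 28) / 2.5))
}

# Median total sperm count trajectory, anchored to the puberty milestones:
# zero at the first-ejaculate week, 10 million at the first-sperm week,
# crossing the 200-million fertility threshold at the fertile week.
traj_sperm_median <- function(profile, week) {
  mw <- profile$milestone_weeks
  fe <- mw[["first_ejaculate"]]; fs <- mw[["first_sperm"]]
  ft <- mw[["fertile"]]
  anchor_w <- c(fs, fs + (ft - fs) / 3, fs + 2 * (ft - fs) / 3,
                ft, ft + 2, ft + 4)
  anchor_v <- c(10e6, 45e6, 90e6, 330e6, 380e6, 420e6)
  out <- rep(NA_real_, length(week))
  out[week >= fe] <- 0
  past <- week >= fs
  if (any(past)) {
    lv <- approx(anchor_w, log10(anchor_v), xout = pmin(week[past],
                                                        max(anchor_w)),
                 rule = 2)$y
    out[past] <- 10^lv
  }
  out
}

# Motility (%) trajectory: no forward movement at the first-sperm week, 50-80%
# two weeks later, settling in the 80s after the fertile milestone.
traj_motility <- function(profile, week) {
  mw <- profile$milestone_weeks
  fs <- mw[["first_sperm"]]; ft <- mw[["fertile"]]
  anchor_w <- c(fs, fs + 2, fs + 4, ft, ft + 2, ft + 4)
  anchor_v <- c(0, 65, 75, 82, 85, 87)
  out <- rep(NA_real_, length(week))
  past <- week >= fs
  out[past] <- approx(anchor_w, anchor_v, xout = pmin(week[past],
                                                      max(anchor_w)),
                      rule = 2)$y
  out
}

# Ejaculate volume (mL), rising towards the adult mean of about 1.9 mL.
traj_ejaculate_volume <- function(week) {
  1.9 * (0.2 + 0.8 * plogis((week - 31) / 2.5))
}
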