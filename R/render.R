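# Synthetic B-mode frame and colour-Doppler overlay rendering.
#
# The speckle model is multiplicative gamma texture: each region is filled
# with i.i.d. Gamma draws whose mean and SD equal the region's trajectory
# targets, then clipped to [0, 255]. The upper clip would bias bright regions
# slightly dark, so the pre-clip mean is moment-matched (closed-form clipped
# mean of the gamma) before drawing.

# Exam-level GI noise decomposition. noise_sd = 1.5 splits into a persistent
# dog factor (sd 1.0), an AR(1) exam latent (sd 1.2) and per-testis noise
# (sd 0.8); the first two are shared with the log total sperm count by the
# cohort generator, which is what couples echotexture to semen output.
noise_components <- function(noise_sd) {
  list(u = noise_sd * 2 / 3, z = noise_sd * 0.8, t = noise_sd * 8 / 15)
}

# E[min(X, 255)] for X ~ Gamma with given mean and sd.
clipped_gamma_mean <- function(mean, sd, cap = 255) {
  k <- (mean / sd)^2
  theta <- mean / k
  mean * pgamma(cap, shape = k + 1, scale = theta) +
    cap * (1 - pgamma(cap, shape = k, scale = theta))
}

# Gamma speckle draws whose clipped mean matches `mean` and SD ~ `sd`.
speckle_fill <- function(n, mean, sd, cap = 255) {
  if (n == 0) return(numeric(0))
  if (sd <= 0) return(rep(mean, n))
  m <- mean
  for (i in 1:4) m <- m + (mean - clipped_gamma_mean(m, sd, cap))
  k <- (m / sd)^2
  pmin(rgamma(n, shape = k, scale = m / k), cap)
}

# Ellipse geometry for a testis of `volume` cm^3 rendered at `mm_per_pixel`.
# Long axis horizontal; width/height taken as 0.6 of length (prolate shape),
# so volume = 0.71 * l * (0.6 l)^2.
testis_geometry <- function(volume, size, mm_per_pixel) {
  l_cm <- (volume / (0.71 * 0.36))^(1 / 3)
  a <- l_cm * 10 / mm_per_pixel / 2      # semi-axis along columns
  b <- 0.6 * a                           # semi-axis along rows
  max_a <- size / 2 - 4
  if (a > max_a) {
    b <- b * max_a / a
    a <- max_a
  }
  list(a = a, b = b, cx = (size + 1) / 2, cy = (size + 1) / 2)
}

#' Render a synthetic B-mode testicular frame
#'
#' Draws an elliptical testis on a dark background: parenchyma filled with
#' multiplicative gamma speckle whose mask mean and SD follow the profile's
#' grayscale-intensity and heterogeneity trajectories, a central bright
#' mediastinum band (present from the profile's onset week), and a 3-pixel
#' hyperechoic capsule rim. All masks are returned with the frame; the
#' parenchyma mask excludes the mediastinum.
#'
#' @param profile a [maturation_profile()].
#' @param week week of age (within the study window, 4-40).
#' @param size frame side in pixels.
#' @param mm_per_pixel spatial calibration.
#' @param seed integer seed for the per-frame noise draws.
#' @return an [ultrasound_frame()]; attribute `targets` records the noise-free
#'   region targets actually used (after exam-level noise), and attribute
#'   `spot_meter_feasible` flags whether nine 2 mm^2 spots fit in the
#'   parenchyma (they do not in very young, small testes).
#' @export
#' @examples
#' fr <- render_bmode_frame(maturation_profile(), week = 36, seed = 1)
#' region_area_stats(fr)
render_bmode_frame <- function(profile, week, size = 192,
                               mm_per_pixel = 0.2, seed = 1L) {
  if (week < 4 || week > 40) {
    stop("week must lie within the study window (weeks 4-40)")
  }
  ns <- profile$noise_sd
  comp <- noise_components(ns)
  lat <- if (ns > 0) exam_latents(profile, week) else list(u = 0, z = 0)

  vol <- profile$adult_testis_volume * growth_fraction(week, "volume")
  geo <- testis_geometry(vol, size, mm_per_pixel)

  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  er2 <- function(a, b) ((rows - geo$cy) / b)^2 + ((cols - geo$cx) / a)^2
  testis <- er2(geo$a, geo$b) <= 1
  cap_th <- 3
  inner <- er2(max(geo$a - cap_th, 1), max(geo$b - cap_th, 1)) <= 1
  capsule <- testis & !inner

  mediastinum <- matrix(FALSE, size, size)
  if (week >= profile$mt_onset_week) {
    bt <- min(max(round(geo$b * 0.1), 2), 5)
    band <- abs(rows - geo$cy) <= bt / 2 &
      ((cols - geo$cx) / (0.75 * geo$a))^2 <= 1
    mediastinum <- band & inner
  }
  parenchyma <- inner & !mediastinum

  out <- with_seed(seed, {
    t_par <- if (ns > 0) rnorm(1, 0, comp$t) else 0
    t_mt <- if (ns > 0) rnorm(1, 0, 0.5 * ns) else 0
    t_cap <- if (ns > 0) rnorm(1, 0, 0.5 * ns) else 0
    targets <- list(
      parenchyma = traj_parenchyma(profile, week) +
        comp$u * lat$u + comp$z * lat$z + t_par,
      het = traj_het(profile, week),
      mediastinum = if (any(mediastinum)) {
        traj_mediastinum(profile, week) + t_mt
      } else NA_real_,
      capsule = traj_capsule(profile, week) + t_cap
    )
    px <- matrix(0, size, size)
    if (ns > 0) {
      px[!testis] <- speckle_fill(sum(!testis), 10, 4)
      px[parenchyma] <- speckle_fill(sum(parenchyma),
                                     targets$parenchyma, targets$het)
      if (any(mediastinum)) {
        px[mediastinum] <- speckle_fill(sum(mediastinum),
                                        targets$mediastinum, 10)
      }
      px[capsule] <- speckle_fill(sum(capsule), targets$capsule, 8)
    } else {
      px[!testis] <- 10
      px[parenchyma] <- round(targets$parenchyma)
      if (any(mediastinum)) px[mediastinum] <- round(targets$mediastinum)
      px[capsule] <- round(targets$capsule)
    }
    list(px = pmin(pmax(round(px), 0), 255), targets = targets)
  })

  fr <- ultrasound_frame(out$px, mm_per_pixel,
                         masks = list(parenchyma = parenchyma,
                                      mediastinum = mediastinum,
                                      capsule = capsule),
                         week = week, dog_id = profile$dog_id)
  attr(fr, "targets") <- out$targets
  attr(fr, "spot_meter_feasible") <-
    !inherits(try(place_spots(fr), silent = TRUE), "try-error")
  fr
}

disk_offsets <- function(r) {
  ri <- ceiling(r)
  g <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  as.matrix(g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE])
}

# TRUE if a disk of radius r centred at (r0, c0) lies fully inside mask and
# at least `gap` away from any already-painted overlay pixel.
disk_fits <- function(mask, painted, r0, c0, r, gap = 3) {
  off <- disk_offsets(r + gap)
  rr <- r0 + off[, 1]; cc <- c0 + off[, 2]
  if (any(rr < 1 | rr > nrow(mask) | cc < 1 | cc > ncol(mask))) return(FALSE)
  core <- off[, 1]^2 + off[, 2]^2 <= r^2
  all(mask[cbind(rr[core], cc[core])]) && !any(painted[cbind(rr, cc)])
}

paint_disk <- function(painted, r0, c0, r) {
  off <- disk_offsets(r)
  painted[cbind(r0 + off[, 1], c0 + off[, 2])] <- TRUE
  painted
}

place_blobs <- function(mask, painted, n, r, min_required = n,
                        max_tries = 400) {
  coords <- which(mask, arr.ind = TRUE)
  placed <- 0
  radius <- r
  tries <- 0
  while (placed < n && tries < max_tries) {
    tries <- tries + 1
    i <- sample.int(nrow(coords), 1)
    if (disk_fits(mask, painted, coords[i, 1], coords[i, 2], radius)) {
      painted <- paint_disk(painted, coords[i, 1], coords[i, 2], radius)
      placed <- placed + 1
    }
    if (tries %% 150 == 0 && placed < min_required) {
      radius <- max(radius - 0.4, 1)   # shrink for small testes
    }
  }
  if (placed < min_required) {
    stop("doppler overlay infeasible: parenchyma region too small")
  }
  painted
}

# A gently curved vessel path spanning the upper parenchyma (avoids the
# central mediastinum band so the course stays in one connected component).
paint_vessel <- function(mask, painted) {
  coords <- which(mask, arr.ind = TRUE)
  r_base <- quantile(coords[, 1], 0.32, names = FALSE)
  c1 <- quantile(coords[, 2], 0.15, names = FALSE)
  c2 <- quantile(coords[, 2], 0.85, names = FALSE)
  for (try in 1:20) {
    amp <- runif(1, 2, 6)
    phase <- runif(1, 0, pi)
    drift <- runif(1, -4, 4)
    trial <- matrix(FALSE, nrow(mask), ncol(mask))
    ts <- seq(0, 1, length.out = 200)
    for (t in ts) {
      cc <- round(c1 + t * (c2 - c1))
      rr <- round(r_base + drift * t + amp * sin(2 * pi * t * 0.8 + phase))
      off <- disk_offsets(1.2)
      prr <- rr + off[, 1]; pcc <- cc + off[, 2]
      ok <- prr >= 1 & prr <= nrow(mask) & pcc >= 1 & pcc <= ncol(mask)
      sel <- cbind(prr[ok], pcc[ok])
      sel <- sel[mask[sel], , drop = FALSE]
      trial[sel] <- TRUE
    }
    comps <- detect_vessels(trial, mask, min_pixels = 5)
    if (length(comps) > 0 &&
        any(vapply(comps, function(x) x$elongation >= 4 ||
                     x$skeleton_length >= 30, logical(1)))) {
      return(painted | trial)
    }
  }
  stop("doppler overlay infeasible: cannot trace a vessel course")
}

#' Render a class-conditional colour-Doppler overlay
#'
#' Produces a binary flow overlay matching a modified Gumbsch vascularity
#' score: score 0 is empty; score 1 paints 1-3 sub-threshold (small) blobs;
#' score 2 paints 1-3 distinct blobs (above the distinct-size threshold);
#' score 3 paints at least 4 distinct blobs; score 4 traces an elongated
#' vessel course. All flow pixels lie inside the parenchyma mask, so
#' classification round-trips through [detect_vessels()] and
#' [score_doppler()].
#'
#' @param score_class integer 0-4.
#' @param seed integer seed.
#' @param parenchyma_mask logical matrix.
#' @return logical matrix of flow pixels, same shape as the mask.
#' @export
render_doppler_overlay <- function(score_class, seed, parenchyma_mask) {
  if (length(score_class) != 1 || is.na(score_class) ||
      !score_class %in% 0:4) {
    stop("score_class must be a single integer in 0..4")
  }
  painted <- matrix(FALSE, nrow(parenchyma_mask), ncol(parenchyma_mask))
  if (score_class == 0) return(painted)
  with_seed(seed, {
    switch(as.character(score_class),
           "1" = place_blobs(parenchyma_mask, painted,
                             n = sample(1:3, 1), r = 1.2, min_required = 1),
           "2" = place_blobs(parenchyma_mask, painted,
                             n = sample(1:3, 1), r = 2.2, min_required = 1),
           "3" = place_blobs(parenchyma_mask, painted,
                             n = sample(4:6, 1), r = 2.2, min_required = 4),
           "4" = paint_vessel(parenchyma_mask, painted))
  })
}
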