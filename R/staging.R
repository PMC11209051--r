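# Period staging and the rank-based statistical battery.

#' Assign age periods from puberty milestones
#'
#' Labels each exam as pre-pubertal (through the first-ejaculate week),
#' pubertal (after the first ejaculate, before the fertile week) or
#' post-pubertal (from the fertile week onward). With the default cohort
#' milestones (28/30/36) this yields the periods weeks 4-28, 30-34 and
#' 36-40.
#'
#' @param cohort cohort table with a `week` column.
#' @param source `"cohort-default"` uses `milestones`; `"per-dog"` reads each
#'   dog's milestones from the cohort's generator profiles.
#' @param milestones named triple `c(first_ejaculate, first_sperm, fertile)`.
#' @return the cohort with a `period` factor column appended.
#' @export
#' @examples
#' assign_periods(data.frame(week = c(4, 30, 40)))$period
assign_periods <- function(cohort,
                           source = c("cohort-default", "per-dog"),
                           milestones = c(first_ejaculate = 28,
                                          first_sperm = 30, fertile = 36)) {
  source <- match.arg(source)
  lv <- c("pre-pubertal", "pubertal", "post-pubertal")
  label <- function(week, mw) {
    ifelse(week <= mw[["first_ejaculate"]], lv[1],
           ifelse(week < mw[["fertile"]], lv[2], lv[3]))
  }
  if (source == "cohort-default") {
    cohort$period <- factor(label(cohort$week, milestones), levels = lv)
  } else {
    profiles <- attr(cohort, "profiles")
    if (is.null(profiles)) stop("per-dog staging requires generator profiles")
    cohort$period <- factor(vapply(seq_len(nrow(cohort)), function(i) {
      p <- profiles[[cohort$dog_id[i]]]
      if (is.null(p)) stop("missing milestones for ", cohort$dog_id[i])
      label(cohort$week[i], p$milestone_weeks)
    }, character(1)), levels = lv)
  }
  cohort
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' t-distribution approximation. Pairs with missing values are dropped.
#'
#' @param x,y numeric vectors of equal length (at least 3 complete pairs).
#' @return list with `rho`, `p`, `n`.
#' @export
#' @examples
#' spearman_rank(1:5, c(2, 1, 4, 3, 5))
spearman_rank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("at least 3 complete pairs are required")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with the chi-square approximation. When every
#' value is identical the statistic is 0 and p is 1.
#'
#' @param groups list of numeric vectors (two or more groups, total n >= 3).
#' @return list with `statistic`, `p`, `df`.
#' @export
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9))
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("groups must be a list of at least two vectors")
  }
  if (any(lengths(groups) < 1) || sum(lengths(groups)) < 3) {
    stop("each group needs >= 1 value and >= 3 values in total")
  }
  all_vals <- unlist(groups)
  if (length(unique(all_vals)) == 1) {
    return(list(statistic = 0, p = 1, df = length(groups) - 1))
  }
  kt <- kruskal.test(groups)
  list(statistic = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Left-right paired comparison
#'
#' Wilcoxon signed-rank test of left against right testis values, paired by
#' dog and week, for each parameter. Identical sides give p = 1.
#'
#' @param cohort cohort table with `dog_id`, `testis_side`, `week`.
#' @param parameters columns to compare; defaults to the per-testis numeric
#'   measurement columns present.
#' @return data.frame with `parameter`, `n_pairs`, `p`.
#' @export
left_right_compare <- function(cohort, parameters = NULL) {
  if (!all(c("left", "right") %in% cohort$testis_side)) {
    stop("cohort must contain paired left/right records")
  }
  if (is.null(parameters)) {
    candidates <- c("testis_l", "testis_w", "testis_h", "us_l", "us_w",
                    "us_h", "scrotal_l", "scrotal_w", "scrotal_h",
                    "gi_spot", "gi_region", "het_region", "gi_mt",
                    "gi_capsule", "ratio_cap", "ratio_mt")
    parameters <- intersect(candidates, names(cohort))
  }
  l <- cohort[cohort$testis_side == "left", ]
  r <- cohort[cohort$testis_side == "right", ]
  key_l <- paste(l$dog_id, l$week)
  key_r <- paste(r$dog_id, r$week)
  m <- match(key_l, key_r)
  if (anyNA(m)) stop("unpaired left/right records")
  out <- lapply(parameters, function(pm) {
    xl <- l[[pm]]; xr <- r[[pm]][m]
    ok <- complete.cases(xl, xr)
    d <- xl[ok] - xr[ok]
    p <- if (length(d) == 0) {
      NA_real_
    } else if (all(d == 0)) {
      1
    } else {
      suppressWarnings(wilcox.test(xl[ok], xr[ok], paired = TRUE,
                                   exact = FALSE)$p.value)
    }
    data.frame(parameter = pm, n_pairs = sum(ok), p = p)
  })
  do.call(rbind, out)
}

#' Lagged correlation of echogenicity with total sperm count
#'
#' Spearman correlation between the parenchymal grayscale intensity at week
#' w and the total sperm count at week w + lag, pooled over dogs, testes and
#' the semen-bearing weeks.
#'
#' @param measured measured cohort (from [measure_cohort()], or any table
#'   with the needed columns).
#' @param lags lags in weeks.
#' @param gi_col grayscale-intensity column.
#' @param sperm_col total-sperm column.
#' @param min_week first exam week included (default: first week with any
#'   non-missing sperm count).
#' @return data.frame with `lag`, `rho`, `p`, `n`.
#' @export
lagged_correlation <- function(measured, lags = c(0, 2, 4),
                               gi_col = "gi_region",
                               sperm_col = "total_sperm",
                               min_week = NULL) {
  if (!all(c(gi_col, sperm_col, "dog_id", "week") %in% names(measured))) {
    stop("missing required columns")
  }
  sem_weeks <- measured$week[!is.na(measured[[sperm_col]])]
  if (length(sem_weeks) == 0) stop("no semen-bearing weeks present")
  if (is.null(min_week)) min_week <- min(sem_weeks)
  max_week <- max(sem_weeks)
  out <- lapply(lags, function(lag) {
    x <- measured[measured$week >= min_week &
                    measured$week + lag <= max_week, ]
    tgt <- paste(measured$dog_id, measured$week)
    y <- measured[[sperm_col]][match(paste(x$dog_id, x$week + lag), tgt)]
    ok <- complete.cases(x[[gi_col]], y)
    if (sum(ok) < 3) {
      stop("no overlapping exams at lag ", lag, " weeks")
    }
    s <- spearman_rank(x[[gi_col]][ok], y[ok])
    data.frame(lag = lag, rho = s$rho, p = s$p, n = s$n)
  })
  do.call(rbind, out)
}

#' Fit the grayscale-intensity slope over the rising phase
#'
#' Ordinary least squares of grayscale intensity on age in weeks, over the
#' rising phase of the chosen structure (defaults: weeks 6-30 for the
#' parenchyma, 8-36 for the mediastinum), pooling all testis-level points.
#'
#' Because the points are repeated measures (two testes per dog, biweekly),
#' the reported `se` is a dog-clustered sandwich (CR1) standard error
#' whenever a `dog_id` column is present; the i.i.d. OLS standard error is
#' returned alongside as `se_ols`. The slope estimate itself is plain OLS.
#'
#' @param measured measured cohort table.
#' @param structure `"parenchyma"` or `"mediastinum"`.
#' @param weeks optional numeric range `c(from, to)` overriding the default
#'   rising phase.
#' @param gi_col optional column override.
#' @return list with `slope`, `se` (cluster-robust when possible), `se_ols`,
#'   `n`, `p` and the underlying `fit`.
#' @export
fit_gi_slope <- function(measured,
                         structure = c("parenchyma", "mediastinum"),
                         weeks = NULL, gi_col = NULL) {
  structure <- match.arg(structure)
  if (is.null(gi_col)) {
    gi_col <- if (structure == "parenchyma") "gi_region" else "gi_mt"
  }
  if (is.null(weeks)) {
    weeks <- if (structure == "parenchyma") c(6, 30) else c(8, 36)
  }
  d <- measured[measured$week >= weeks[1] & measured$week <= weeks[2], ]
  d <- d[!is.na(d[[gi_col]]), ]
  if (length(unique(d$week)) < 3) {
    stop("at least 3 distinct weeks are required in the fitting range")
  }
  fit <- lm(d[[gi_col]] ~ d$week)
  sm <- suppressWarnings(summary(fit))$coefficients
  se_ols <- sm[2, 2]
  se <- se_ols
  if ("dog_id" %in% names(d) && length(unique(d$dog_id)) > 1) {
    xc <- d$week - mean(d$week)
    e <- stats::resid(fit)
    cl <- tapply(xc * e, d$dog_id, sum)
    g <- length(cl)
    se <- sqrt(g / (g - 1) * sum(cl^2)) / sum(xc^2)
  }
  list(slope = sm[2, 1], se = se, se_ols = se_ols, n = nrow(d),
       p = sm[2, 4], fit = fit)
}

#' Detect the plateau week of a longitudinal series
#'
#' Returns the earliest week from which every successive change in the
#' weekly medians stays within the tolerance (absolute grayscale units, or a
#' relative fraction for volumes). Returns `NA` when the series never
#' settles.
#'
#' @param weeks sorted week grid.
#' @param values per-week medians, same length.
#' @param tolerance maximum successive change (absolute, or fraction when
#'   `relative = TRUE`).
#' @param relative compare successive changes relative to the current level.
#' @return the plateau week, or `NA`.
#' @export
#' @examples
#' detect_plateau(seq(4, 16, 2), c(10, 20, 30, 40, 41, 41.5, 42), tolerance = 2)
detect_plateau <- function(weeks, values, tolerance = 2, relative = FALSE) {
  if (length(weeks) != length(values)) stop("weeks and values lengths differ")
  if (length(weeks) < 4) stop("at least 4 points are required")
  d <- abs(diff(values))
  if (relative) d <- d / pmax(abs(values[-length(values)]), 1e-12)
  ok <- d <= tolerance
  # earliest index i such that every later successive change is within tol
  run <- rev(cumprod(rev(ok)))
  i <- which(run == 1)[1]
  if (is.na(i)) return(NA_real_)
  weeks[i]
}

#' Maturity-indicator panel
#'
#' Evaluates the six printed maturity indicators on cohort medians at a
#' query week: region-area heterogeneity > 19; capsule/parenchyma percent
#' echogenicity < 200; mediastinum grayscale intensity > 190; capsule
#' intensity at its plateau (>= 210); more than 80 percent of testes scored
#' 4 on colour Doppler; and a plateaued ultrasonographic testis volume (5
#' percent successive-median tolerance, judged on the full series). The
#' verdict is `mature` when at least `mature_rule` indicators hold,
#' `immature` when at most one does, and `peripubertal` otherwise.
#'
#' @param measured measured cohort table (echotexture and Doppler columns).
#' @param week query week of age.
#' @param mature_rule indicators required for a `mature` verdict.
#' @return object of class `maturity_panel`.
#' @export
maturity_panel <- function(measured, week, mature_rule = 4) {
  slice <- measured[measured$week == week, ]
  if (nrow(slice) == 0) stop("no exams at week ", week)
  need <- c("het_region", "ratio_cap", "gi_mt", "gi_capsule")
  if (!all(need %in% names(measured))) {
    stop("missing echotexture columns: ",
         paste(setdiff(need, names(measured)), collapse = ", "))
  }
  score_col <- if ("doppler_score_detected" %in% names(slice)) {
    "doppler_score_detected"
  } else "doppler_score"
  vol <- volume_us(measured$us_l, measured$us_w, measured$us_h)
  med_vol <- tapply(vol, measured$week, median, na.rm = TRUE)
  vol_weeks <- as.numeric(names(med_vol))
  plateau_wk <- if (length(vol_weeks) >= 4) {
    detect_plateau(vol_weeks, as.numeric(med_vol), tolerance = 0.05,
                   relative = TRUE)
  } else NA_real_

  ind <- c(
    het_gt_19 = median(slice$het_region, na.rm = TRUE) > 19,
    ratio_lt_200 = median(slice$ratio_cap, na.rm = TRUE) < 200,
    mt_gt_190 = isTRUE(median(slice$gi_mt, na.rm = TRUE) > 190),
    capsule_in_plateau = median(slice$gi_capsule, na.rm = TRUE) >= 210,
    doppler4_gt_80pct =
      unname(score_cohort(slice[[score_col]])["score4"]) > 80,
    volume_plateaued = isTRUE(plateau_wk <= week)
  )
  ind[is.na(ind)] <- FALSE
  n_true <- sum(ind)
  verdict <- if (n_true >= mature_rule) "mature" else
    if (n_true <= 1) "immature" else "peripubertal"
  structure(list(week = week, indicators = ind, n_true = n_true,
                 verdict = verdict), class = "maturity_panel")
}

#' @export
print.maturity_panel <- function(x, ...) {
  cat(sprintf("<maturity_panel> week %g: %s (%d/6 indicators)\n",
              x$week, x$verdict, x$n_true))
  for (nm in names(x$indicators)) {
    cat(sprintf("  %-20s %s\n", nm, x$indicators[[nm]]))
  }
  invisible(x)
}
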