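# Period staging, rank statistics, lag structure, slope fits, plateaus and
# the maturity panel.

test_that("age periods partition the week grid at the milestones", {
  d <- assign_periods(data.frame(week = c(4, 28, 30, 34, 36, 40)))
  expect_equal(as.character(d$period),
               c("pre-pubertal", "pre-pubertal", "pubertal", "pubertal",
                 "post-pubertal", "post-pubertal"))
  co <- generate_cohort(cohort_config(n_dogs = 1, weeks = c(4, 30, 40),
                                      master_seed = 1))
  pd <- assign_periods(co, source = "per-dog")
  expect_equal(as.character(pd$period[pd$week == 30]),
               rep("pubertal", 2))
  expect_error(assign_periods(data.frame(week = 4), source = "per-dog"),
               "profiles")
})

test_that("Spearman correlation matches the brute-force rank formula", {
  expect_equal(spearman_rank(1:7, (1:7)^3)$rho, 1)
  expect_equal(spearman_rank(1:7, -(1:7))$rho, -1)
  # d^2 = (1,1,1,1,0): rho = 1 - 6*4 / (5*24) = 0.8
  s <- spearman_rank(1:5, c(2, 1, 4, 3, 5))
  expect_equal(s$rho, 0.8)
  expect_warning(out <- spearman_rank(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out$rho))
  expect_error(spearman_rank(1:2, 1:2), "3 complete pairs")
})

test_that("Kruskal-Wallis H matches the direct rank computation", {
  # no ties: H = 12/(N(N+1)) * sum n_i (Rbar_i - Rbar)^2 = 7.2
  kw <- kruskal_wallis(list(1:3, 4:6, 7:9))
  expect_equal(kw$statistic, 7.2)
  same <- kruskal_wallis(list(c(5, 5), c(5, 5), c(5, 5)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(kruskal_wallis(list(1:3)), "two")
})

test_that("rank statistics are invariant under strictly increasing transforms", {
  set.seed(11)
  x <- rnorm(30); y <- x + rnorm(30)
  g <- list(rnorm(10), rnorm(10, 1), rnorm(10, 2))
  f <- function(v) exp(v) + v^3
  expect_equal(spearman_rank(x, y)$rho, spearman_rank(f(x), f(y))$rho)
  expect_equal(kruskal_wallis(g)$statistic,
               kruskal_wallis(lapply(g, f))$statistic)
})

test_that("left-right comparison detects a shifted side and passes identical sides", {
  d <- expand.grid(dog_id = paste0("dog", 1:8), week = seq(20, 36, 4),
                   testis_side = c("left", "right"),
                   stringsAsFactors = FALSE)
  set.seed(5)
  base <- rnorm(nrow(d) / 2, 100, 5)
  d$gi_region <- rep(base, 2)
  lr <- left_right_compare(d, parameters = "gi_region")
  expect_equal(lr$p, 1)
  d2 <- d
  d2$gi_region[d2$testis_side == "left"] <-
    d2$gi_region[d2$testis_side == "left"] + 50
  expect_lt(left_right_compare(d2, parameters = "gi_region")$p, 0.01)
  expect_error(left_right_compare(d[d$testis_side == "left", ]), "paired")
})

test_that("lagged correlation is exact on a noiseless coupled toy cohort", {
  d <- expand.grid(dog_id = c("a", "b"), week = seq(28, 40, 2),
                   stringsAsFactors = FALSE)
  d$gi_region <- d$week + ifelse(d$dog_id == "a", 0, 0.5)
  d$total_sperm <- d$gi_region^2          # strictly monotone coupling
  lc <- lagged_correlation(d, lags = c(0, 2, 4))
  expect_equal(lc$rho, rep(1, 3))
  expect_equal(lc$n, c(14, 12, 10))
  expect_error(lagged_correlation(d, lags = 20), "lag 20")
  expect_error(lagged_correlation(d[0, ], lags = 0), "semen-bearing")
})

test_that("the slope fit is exact on a noiseless line and zero on a constant", {
  d <- expand.grid(dog_id = paste0("dog", 1:4), week = seq(6, 30, 2),
                   stringsAsFactors = FALSE)
  d$gi_region <- 55 + 2.525 * (d$week - 6)
  f <- fit_gi_slope(d, "parenchyma")
  expect_equal(f$slope, 2.525)
  expect_lt(f$se, 1e-10)
  d$gi_region <- 100
  expect_equal(fit_gi_slope(d, "parenchyma")$slope, 0)
  expect_error(fit_gi_slope(d[d$week == 6, ], "parenchyma"), "3 distinct")
})

test_that("slope recovery across seeds stays within 3 cluster-robust SE", {
  hits <- vapply(1:5, function(s) {
    co <- generate_cohort(cohort_config(n_dogs = 8, weeks = seq(6, 30, 4),
                                        master_seed = s + 20))
    # regression on the exam-level targets (render-free parameter recovery)
    profs <- attr(co, "profiles")
    co$gi_region <- vapply(seq_len(nrow(co)), function(i) {
      p <- profs[[co$dog_id[i]]]
      lat <- echotestis:::exam_latents(p, co$week[i])
      traj <- echotestis:::traj_parenchyma(p, co$week[i])
      comp <- echotestis:::noise_components(p$noise_sd)
      traj + comp$u * lat$u + comp$z * lat$z
    }, numeric(1))
    f <- fit_gi_slope(co, "parenchyma")
    abs(f$slope - 2.525) <= 3 * f$se
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("plateau detection finds the earliest settled week", {
  wk <- seq(4, 16, 2)
  expect_true(is.na(detect_plateau(wk, seq(10, 70, 10), tolerance = 2)))
  expect_equal(detect_plateau(wk, rep(5, 7), tolerance = 2), 4)
  expect_equal(detect_plateau(wk, c(10, 20, 30, 40, 41, 41.5, 42),
                              tolerance = 2), 10)
  # relative tolerance flavour (volumes)
  expect_equal(detect_plateau(wk, c(1, 2, 4, 8, 8.2, 8.3, 8.35),
                              tolerance = 0.05, relative = TRUE), 10)
  expect_error(detect_plateau(1:3, 1:3), "4 points")
})

test_that("the maturity panel turns on its indicators at the printed thresholds", {
  mk <- function(week, het, ratio, mt, capsule, score, us_l) {
    data.frame(dog_id = paste0("dog", 1:4), testis_side = "left",
               week = week, het_region = het, ratio_cap = ratio,
               gi_mt = mt, gi_capsule = capsule,
               doppler_score_detected = score,
               us_l = us_l, us_w = 0.6 * us_l, us_h = 0.6 * us_l)
  }
  mature <- do.call(rbind, lapply(seq(30, 40, 2), function(w) {
    mk(w, het = 22, ratio = 185, mt = 199, capsule = 215, score = 4,
       us_l = 3)   # constant volume -> plateaued
  }))
  pan <- maturity_panel(mature, 36)
  expect_true(all(pan$indicators))
  expect_equal(pan$verdict, "mature")
  young <- do.call(rbind, lapply(seq(8, 18, 2), function(w) {
    mk(w, het = 10, ratio = 230, mt = NA, capsule = 160, score = 0,
       us_l = 1 + w / 10)
  }))
  pan2 <- maturity_panel(young, 12)
  expect_false(any(pan2$indicators))
  expect_equal(pan2$verdict, "immature")
  expect_error(maturity_panel(mature, 20), "no exams")
})
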