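# Spot-meter and region-area techniques, ratios and categories.

test_that("nine 2 mm^2 spots tile a large parenchyma without overlap", {
  px <- matrix(100L, 300, 300)
  fr <- ultrasound_frame(px, 0.1, masks = list(parenchyma = px == 100))
  spots <- place_spots(fr)
  expect_equal(nrow(spots), 9)
  expect_true(all(spots$side == 14))          # round(sqrt(2)/0.1)
  # pairwise disjoint squares
  for (i in 1:8) for (j in (i + 1):9) {
    expect_true(abs(spots$row[i] - spots$row[j]) >= 14 ||
                  abs(spots$col[i] - spots$col[j]) >= 14)
  }
})

test_that("spot placement fails on a tiny parenchyma", {
  px <- matrix(0L, 10, 10)
  mask <- matrix(FALSE, 10, 10)
  mask[5:6, 5:6] <- TRUE
  fr <- ultrasound_frame(px, 0.5, masks = list(parenchyma = mask))
  expect_error(place_spots(fr), "infeasible")
})

test_that("spots never intersect a central mediastinum band", {
  fr <- uniform_frame(100, size = 60, mm_per_pixel = 0.5,
                      band_rows = 29:31, band_value = 240)
  spots <- place_spots(fr)
  mt <- fr$masks$mediastinum
  for (i in seq_len(nrow(spots))) {
    r <- spots$row[i]; c <- spots$col[i]; s <- spots$side[i]
    expect_false(any(mt[r:(r + s - 1), c:(c + s - 1)]))
  }
})

test_that("spot-meter statistics are the mean and SD of the nine spot means", {
  fr <- uniform_frame(90, size = 30, mm_per_pixel = 0.5)
  spots <- place_spots(fr)
  st <- spot_meter_stats(fr, spots)
  expect_equal(st$mean_gi, 90)
  expect_equal(st$heterogeneity, 0)
  # overwrite the last spot with 108: means {90 x8, 108} -> mean 92, SD 6
  i <- 9
  r <- spots$row[i]; c <- spots$col[i]; s <- spots$side[i]
  fr$pixels[r:(r + s - 1), c:(c + s - 1)] <- 108L
  st <- spot_meter_stats(fr, spots)
  expect_equal(st$mean_gi, 92)
  expect_equal(st$heterogeneity, 6)
  expect_error(spot_meter_stats(fr, spots[1, , drop = FALSE]), "2 spots")
})

test_that("region-area statistics match closed forms and exclude the mediastinum", {
  fr <- uniform_frame(100, size = 64)
  expect_equal(region_area_stats(fr)[c("mean_gi", "heterogeneity")],
               list(mean_gi = 100, heterogeneity = 0))
  # half 0 / half 255 two-point distribution
  fr2 <- uniform_frame(0, size = 64)
  fr2$pixels[, 33:64] <- 255L
  reg <- region_area_stats(fr2)
  n <- 64 * 64
  expect_equal(reg$mean_gi, 127.5)
  expect_equal(reg$heterogeneity, sqrt(n / (n - 1)) * 127.5, tolerance = 1e-10)
  # a bright mediastinum band does not move the parenchymal statistics
  fr3 <- uniform_frame(100, size = 64, band_rows = 31:33, band_value = 240)
  expect_equal(region_area_stats(fr3)$mean_gi, 100)
  fr_empty <- uniform_frame(100, size = 8)
  fr_empty$masks$parenchyma[] <- FALSE
  expect_error(region_area_stats(fr_empty), "empty")
})

test_that("region-area statistics equal brute-force accumulation on small frames", {
  set.seed(42)
  px <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32)
  mask <- matrix(runif(32 * 32) < 0.6, 32, 32)
  mask[1, 1] <- TRUE
  fr <- ultrasound_frame(px, 0.2, masks = list(parenchyma = mask))
  reg <- region_area_stats(fr)
  acc <- c()
  for (i in 1:32) for (j in 1:32) if (mask[i, j]) acc <- c(acc, px[i, j])
  expect_identical(reg$mean_gi, mean(acc))
  expect_identical(reg$heterogeneity, sd(acc))
})

test_that("adding a constant shifts means and leaves SDs unchanged", {
  set.seed(7)
  px <- matrix(as.integer(pmin(pmax(rnorm(40 * 40, 100, 15), 0), 200)), 40, 40)
  fr <- ultrasound_frame(px, 0.5, masks = list(parenchyma = px > -1))
  shifted <- fr
  shifted$pixels <- fr$pixels + 30L
  r1 <- region_area_stats(fr); r2 <- region_area_stats(shifted)
  expect_equal(r2$mean_gi, r1$mean_gi + 30)
  expect_equal(r2$heterogeneity, r1$heterogeneity)
  s1 <- spot_meter_stats(fr, place_spots(fr))
  s2 <- spot_meter_stats(shifted, place_spots(shifted))
  expect_equal(s2$mean_gi, s1$mean_gi + 30)
  expect_equal(s2$heterogeneity, s1$heterogeneity)
})

test_that("the two techniques agree on homogeneous speckle frames", {
  agree <- vapply(1:60, function(s) {
    fr <- render_bmode_frame(maturation_profile(seed = s), week = 30,
                             seed = s)
    abs(spot_meter_stats(fr, place_spots(fr))$mean_gi -
          region_area_stats(fr)$mean_gi) < 2
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})

test_that("structure intensities and 'not imaged' are handled", {
  fr <- uniform_frame(100, size = 30, capsule_value = 215)
  expect_equal(as.numeric(structure_gi(fr, "capsule")), 215)
  gi <- structure_gi(fr, "mediastinum")   # empty mask
  expect_true(is.na(gi) && isTRUE(attr(gi, "not_imaged")))
})

test_that("percent echogenicity follows reference/parenchyma x 100", {
  expect_equal(percent_echogenicity(215, 115), 186.9565, tolerance = 1e-4)
  expect_equal(percent_echogenicity(123, 123), 100)
  expect_error(percent_echogenicity(190, 0), "zero")
  expect_true(is.na(percent_echogenicity(NA, 100)))
})

test_that("echogenicity categories have exactly the printed boundaries", {
  expect_equal(as.character(categorize_echogenicity(c(0, 85, 86, 170, 171, 255))),
               c("low", "low", "moderate", "moderate", "high", "high"))
  # rounding half-up before classification
  expect_equal(as.character(categorize_echogenicity(c(85.4, 85.5))),
               c("low", "moderate"))
  expect_error(categorize_echogenicity(-1), "\\[0, 255\\]")
  expect_error(categorize_echogenicity(256), "\\[0, 255\\]")
  # total and monotone over the whole range with two boundary pairs
  g <- seq(0, 255, by = 0.5)
  lev <- as.integer(categorize_echogenicity(g))
  expect_true(all(diff(lev) >= 0))
  expect_equal(sum(diff(lev) > 0), 2)
})
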