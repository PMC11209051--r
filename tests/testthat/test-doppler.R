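# Vessel detection, scoring and class-conditional round-trips.

test_that("component detection matches simple constructions", {
  m <- matrix(FALSE, 40, 40)
  full <- matrix(TRUE, 40, 40)
  expect_length(detect_vessels(m, full), 0)
  m2 <- paint_rect(m, 5, 8, 5, 9)       # 4x5 = 20 px
  m2 <- paint_rect(m2, 25, 28, 25, 29)
  comps <- detect_vessels(m2, full, min_pixels = 5)
  expect_length(comps, 2)
  expect_equal(sapply(comps, `[[`, "pixel_count"), c(20, 20))
  m3 <- matrix(FALSE, 40, 40)
  m3[10, 10:12] <- TRUE                 # 3-px speck
  expect_length(detect_vessels(m3, full, min_pixels = 5), 0)
  expect_error(detect_vessels(matrix(FALSE, 3, 3), full), "shapes differ")
})

test_that("8-connected labelling agrees with a graph-components oracle", {
  skip_if_not_installed("igraph")
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(runif(45 * 45) < 0.12, 45, 45)
    comps <- detect_vessels(m, matrix(TRUE, 45, 45), min_pixels = 1)
    sizes <- sort(sapply(comps, `[[`, "pixel_count"))
    idx <- which(m)
    coord <- cbind(((idx - 1) %% 45) + 1, ((idx - 1) %/% 45) + 1)
    edges <- matrix(numeric(0), ncol = 2)
    for (a in seq_along(idx)) {
      nb <- which(abs(coord[, 1] - coord[a, 1]) <= 1 &
                    abs(coord[, 2] - coord[a, 2]) <= 1)
      nb <- nb[nb > a]
      if (length(nb)) edges <- rbind(edges, cbind(a, nb))
    }
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    g <- igraph::add_edges(g, t(edges))
    oracle_sizes <- sort(as.numeric(table(igraph::components(g)$membership)))
    expect_equal(sizes, oracle_sizes)
  }
})

test_that("component features capture elongation and chord length", {
  m <- matrix(FALSE, 50, 50)
  m[25, 5:44] <- TRUE                    # 1 x 40 line
  comp <- detect_vessels(m, matrix(TRUE, 50, 50))[[1]]
  expect_gte(comp$elongation, 4)
  expect_gte(comp$skeleton_length, 39)
  m2 <- matrix(FALSE, 50, 50)
  m2 <- paint_rect(m2, 20, 24, 20, 24)   # 5x5 compact blob
  comp2 <- detect_vessels(m2, matrix(TRUE, 50, 50))[[1]]
  expect_lt(comp2$elongation, 1.5)
})

test_that("scores follow the modified Gumbsch legend", {
  full <- matrix(TRUE, 60, 60)
  expect_equal(score_doppler(list())$score, 0)
  blobs <- function(n, w = 4) {
    m <- matrix(FALSE, 60, 60)
    for (i in seq_len(n)) {
      m <- paint_rect(m, i * 9, i * 9 + w - 1, i * 9, i * 9 + w - 1)
    }
    detect_vessels(m, full)
  }
  expect_equal(score_doppler(blobs(5))$score, 3)      # over three distinct
  expect_equal(score_doppler(blobs(2))$score, 2)      # distinct, up to three
  small <- blobs(2, w = 2)                            # 4-px specks kept?
  m1 <- matrix(FALSE, 60, 60)
  m1 <- paint_rect(m1, 10, 12, 10, 12)                # 9 px < distinct 10
  expect_equal(score_doppler(detect_vessels(m1, full))$score, 1)
  line <- matrix(FALSE, 60, 60)
  line[30, 10:50] <- TRUE
  sc <- score_doppler(detect_vessels(line, full))
  expect_equal(sc$score, 4)                           # course visible
  expect_true(sc$course_visible)
  expect_error(score_doppler(blobs(2), distinct_pixels = 0), "positive")
})

test_that("adding distinct components never lowers the score", {
  full <- matrix(TRUE, 80, 80)
  prev <- -Inf
  m <- matrix(FALSE, 80, 80)
  for (i in 1:6) {
    m <- paint_rect(m, i * 12, i * 12 + 3, i * 12, i * 12 + 3)
    sc <- score_doppler(detect_vessels(m, full))$score
    expect_gte(sc, prev)
    prev <- sc
  }
})

test_that("cohort score proportions round half-up and sum to ~100", {
  expect_equal(unname(score_cohort(rep(0, 16))["score0"]), 100)
  expect_equal(unname(score_cohort(c(rep(4, 13), rep(3, 3)))["score4"]), 81)
  expect_equal(unname(score_cohort(2)["score2"]), 100)
  set.seed(1)
  for (i in 1:10) {
    pct <- score_cohort(sample(0:4, 16, replace = TRUE))
    expect_lte(abs(sum(pct) - 100), 1)
  }
  expect_error(score_cohort(integer(0)), "at least one")
  expect_error(score_cohort(5), "0..4")
})

test_that("class-conditional overlays round-trip through the scorer", {
  mask <- default_parenchyma_mask()
  for (cls in 0:4) {
    hits <- vapply(1:30, function(s) {
      ov <- render_doppler_overlay(cls, sub_seed(cls, s), mask)
      expect_true(all(mask[ov]))         # flow stays inside the parenchyma
      score_doppler(detect_vessels(ov, mask))$score == cls
    }, logical(1))
    expect_gte(mean(hits), 0.95)
  }
  expect_error(render_doppler_overlay(5, 1, mask), "0..4")
})

test_that("the score depends only on the overlay, not the grayscale background", {
  mask <- default_parenchyma_mask()
  ov <- render_doppler_overlay(3, 42, mask)
  s1 <- score_doppler(detect_vessels(ov, mask))$score
  s2 <- score_doppler(detect_vessels(ov, mask))$score
  expect_identical(s1, s2)
  expect_equal(s1, 3)
})
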