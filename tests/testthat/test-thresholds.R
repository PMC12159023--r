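test_that("loess reproduces constants and lines exactly", {
  x <- seq(0, 10, length.out = 40)
  fit_lin <- loess_fit(x, 2 * x + 1, degree = 1)
  expect_equal(fit_lin$fitted, 2 * fit_lin$grid + 1, tolerance = 1e-8)
  fit_const <- loess_fit(x, rep(3.5, 40), degree = 2)
  expect_equal(fit_const$fitted, rep(3.5, 512), tolerance = 1e-8)
})

test_that("local quadratic fits reproduce a noiseless parabola", {
  x <- seq(0, 10, length.out = 50)
  y <- -(x - 5)^2 + 25
  fit <- loess_fit(x, y, degree = 2)
  expect_equal(fit$fitted, -(fit$grid - 5)^2 + 25, tolerance = 1e-6)
  pk <- find_peak(fit)
  expect_lt(abs(pk$peak - 5), diff(range(x)) / 511 + 1e-9)
  expect_false(pk$at_boundary)
})

test_that("loess preconditions are enforced", {
  expect_error(loess_fit(1:3, 1:4), "lengths differ")
  expect_error(loess_fit(c(1, 1, 2), c(1, 2, 3), degree = 2), "distinct x")
  expect_error(loess_fit(1:10, rnorm(10), span = 0.1, degree = 2), "span")
  expect_error(loess_fit(1:10, rnorm(10), degree = 3), "degree")
})

test_that("monotone responses peak at the boundary, humps in the interior", {
  x <- seq(0, 1200, length.out = 56)
  fit_dec <- loess_fit(x, 100 * exp(-x / 300))
  pk <- find_peak(fit_dec)
  expect_equal(pk$peak, min(x))
  expect_true(pk$at_boundary)
  set.seed(2)
  for (rep in 1:5) {
    b <- runif(1, 0, 2); a <- runif(1, 0.5, 2)
    y <- hump_response(x, b, a, 500, 200) + rnorm(56, 0, 0.02 * a)
    expect_false(find_peak(loess_fit(x, y))$at_boundary)
  }
})

test_that("threshold adoption takes the protective minimum", {
  as_dec <- adopt_threshold(c(SW = 217, SR = 307))
  expect_equal(as_dec$adopted, 217)
  expect_equal(as_dec$principle, "conservative")
  am_dec <- adopt_threshold(c(SW = 680, SR = 683))
  expect_equal(am_dec$adopted, 680)
  expect_equal(am_dec$principle, "negligible-difference")
  tie <- adopt_threshold(c(SW = 500, SR = 500))
  expect_equal(tie$adopted, 500)
  expect_equal(tie$principle, "negligible-difference")
  expect_error(adopt_threshold(numeric(0)), "nonempty")
  expect_error(adopt_threshold(c(SW = -2, SR = 300)), "positive")
})

test_that("adoption is permutation-invariant and never exceeds a candidate", {
  set.seed(7)
  for (i in 1:25) {
    cand <- runif(sample(1:5, 1), 10, 1000)
    names(cand) <- paste0("m", seq_along(cand))
    d1 <- adopt_threshold(cand)
    d2 <- adopt_threshold(cand[sample(seq_along(cand))])
    expect_equal(d1$adopted, d2$adopted)
    expect_identical(d1$principle, d2$principle)
    expect_true(all(d1$adopted <= cand))
  }
})

test_that("relative change rates are plain percent changes", {
  expect_equal(relative_change_rate(10, 10), 0)
  expect_equal(relative_change_rate(10, 5), -50)
  expect_equal(relative_change_rate(2.0, 4.03), 101.5)
  expect_error(relative_change_rate(0, 5), "baseline is zero")
})

test_that("the change-rate table matches a spreadsheet oracle", {
  ind <- data.frame(
    plot_id = paste0("P", 1:6), type = "AM",
    shannon = c(1.0, 1.2, 2.0, 2.2, 0.5, 0.6),
    richness = c(10, 12, 15, 16, 6, 7),
    biomass = c(100, 110, 200, 190, 40, 50),
    height = c(10, 12, 8, 9, 4, 5),
    cover = c(.8, .9, .7, .6, .3, .2),
    edible_proportion = c(.5, .6, .4, .5, .2, .3),
    effective_holes = c(10, 20, 500, 550, 1100, 1150))
  lv <- factor(c("I", "I", "III", "III", "IV", "IV"),
               levels = c("I", "II", "III", "IV"))
  tab <- change_table(ind, lv, top_quantile = 0.8)
  # baselines are level-I means; top stratum is the two densest plots
  expect_equal(tab$SW, 100 * (0.55 - 1.1) / 1.1)
  expect_equal(tab$AB, 100 * (45 - 105) / 105)
  expect_equal(tab$CH, 100 * (4.5 - 11) / 11)
  # doubling every metric in the top group adds exactly 100 points of change
  ind2 <- ind
  top <- 5:6
  for (cc in c("shannon", "richness", "biomass", "height", "cover",
               "edible_proportion")) {
    ind2[top, cc] <- 2 * colMeans(ind[1:2, cc, drop = FALSE])
  }
  tab2 <- change_table(ind2, lv, top_quantile = 0.8)
  expect_equal(unlist(tab2[-1]), rep(100, 6), ignore_attr = TRUE)
  expect_error(change_table(ind, factor(rep("II", 6),
                                        levels = levels(lv))), "empty group")
})

test_that("random polynomials up to the fit degree are reproduced", {
  set.seed(42)
  x <- sort(runif(60, 0, 10))
  for (i in 1:5) {
    co <- rnorm(3)
    y1 <- co[1] + co[2] * x
    f1 <- loess_fit(x, y1, degree = 1)
    expect_equal(f1$fitted, co[1] + co[2] * f1$grid, tolerance = 1e-6)
    y2 <- co[1] + co[2] * x + co[3] * x^2
    f2 <- loess_fit(x, y2, degree = 2)
    expect_equal(f2$fitted, co[1] + co[2] * f2$grid + co[3] * f2$grid^2,
                 tolerance = 1e-6)
  }
})

test_that("peak recovery improves with more plots and less noise", {
  grid_cases <- expand.grid(n = c(30, 56, 120), noise = c(0.02, 0.1, 0.25))
  bias <- mapply(function(n, noise) {
    errs <- vapply(1:12, function(s) {
      set.seed(s)
      x <- (seq_len(n) - runif(n)) / n * 1200
      y <- hump_response(x, 0.5, 1, 400, 150) + rnorm(n, 0, noise)
      find_peak(loess_fit(x, y))$peak - 400
    }, numeric(1))
    mean(abs(errs))
  }, grid_cases$n, grid_cases$noise)
  # low-noise large-n corner is much tighter than the worst corner
  expect_lt(bias[grid_cases$n == 120 & grid_cases$noise == 0.02], 30)
  expect_lt(min(bias), max(bias))
  expect_true(all(bias < 0.25 * 400))
})
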