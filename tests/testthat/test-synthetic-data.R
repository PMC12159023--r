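test_that("hump response has its maximum at the peak and degenerates sanely", {
  expect_equal(hump_response(300, baseline = 1, amplitude = 2, peak = 300,
                             width = 120), 3)
  expect_equal(hump_response(c(0, 400, 999), baseline = 5, amplitude = 0,
                             peak = 200, width = 50), rep(5, 3))
  expect_equal(hump_response(300 + 120, 0, 1, 300, 120), exp(-0.5))
  expect_equal(hump_response(300 - 120, 0, 1, 300, 120), exp(-0.5))
  d <- seq(0, 1200, by = 1)
  v <- hump_response(d, 0.3, 1.7, 480, 90)
  expect_equal(d[which.max(v)], 480)
  expect_error(hump_response(10, 0, 1, 5, width = 0), "width")
})

test_that("coordinate sampling respects spacing and is seed-deterministic", {
  a <- generate_coordinates(20, extent_km = 10, min_spacing = 1, seed = 11)
  b <- generate_coordinates(20, extent_km = 10, min_spacing = 1, seed = 11)
  expect_identical(a, b)
  D <- geodesic_distance_matrix(a$lat, a$lon)
  expect_true(min(D[upper.tri(D)]) >= 1)
  one <- generate_coordinates(1, extent_km = 5, min_spacing = 1, seed = 3)
  expect_equal(nrow(one), 1L)
  expect_error(generate_coordinates(200, extent_km = 2, min_spacing = 1),
               "cannot place")
})

test_that("default survey matches the field design and is reproducible", {
  s1 <- generate_survey(generator_config(seed = 42))
  s2 <- generate_survey(generator_config(seed = 42))
  expect_identical(s1$plots, s2$plots)
  expect_identical(s1$quadrats, s2$quadrats)
  expect_equal(sum(s1$plots$type == "AM"), 30)
  expect_equal(sum(s1$plots$type == "AS"), 26)
  counts <- table(unique(s1$quadrats[c("plot_id", "quadrat_id")])$plot_id)
  expect_true(all(counts == 3))
  # physicality
  expect_true(all(s1$quadrats$cover >= 0 & s1$quadrats$cover <= 1))
  expect_true(all(s1$quadrats$abundance > 0))
  expect_true(all(s1$quadrats$biomass_g_m2 >= 0))
  expect_true(all(s1$quadrats$height_cm >= 0))
  expect_true(all(s1$plots$effective_holes >= 0))
  # within-type spacing
  for (ty in c("AM", "AS")) {
    p <- s1$plots[s1$plots$type == ty, ]
    D <- geodesic_distance_matrix(p$lat, p$lon)
    expect_gte(min(D[upper.tri(D)]), 1)
  }
})

test_that("flat noiseless responses collapse to their baselines", {
  rs <- default_responses()
  for (ty in c("AM", "AS")) for (m in names(rs[[ty]])) {
    rs[[ty]][[m]]$amplitude <- 0
    rs[[ty]][[m]]$noise_sd <- 0
  }
  s <- generate_survey(generator_config(responses = rs, seed = 5))
  ind <- plot_indicators(s)
  for (ty in c("AM", "AS")) {
    i <- ind[ind$type == ty, ]
    expect_equal(unique(round(i$biomass, 9)), rs[[ty]]$biomass$baseline)
    expect_equal(unique(round(i$cover, 9)),
                 min(1, rs[[ty]]$cover$baseline + rs[[ty]]$cover$amplitude * 0))
    # count-based metrics agree with the baseline up to discretization
    expect_lt(abs(mean(i$shannon) - rs[[ty]]$shannon$baseline), 0.15)
    expect_lt(abs(mean(i$richness) / rs[[ty]]$richness$baseline - 1), 0.25)
  }
})

test_that("noiseless continuous metrics trace the configured hump exactly", {
  rs <- default_responses()
  rs$AM$biomass$noise_sd <- 0
  s <- generate_survey(generator_config(n_plots_AS = 2L, responses = rs,
                                        seed = 9))
  ind <- plot_indicators(s)
  am <- ind[ind$type == "AM", ]
  expect_equal(am$biomass,
               hump_response(am$effective_holes, rs$AM$biomass$baseline,
                             rs$AM$biomass$amplitude, rs$AM$biomass$peak,
                             rs$AM$biomass$width))
})

test_that("a configured Shannon peak is recovered downstream", {
  rs <- default_responses()
  rs$AM$shannon <- list(baseline = 1.2, amplitude = 0.8, peak = 200,
                        width = 150, noise_sd = 0.02,
                        direction = "rise-then-fall")
  # flat, generous richness keeps Shannon clear of its ln(S) ceiling so the
  # evenness channel alone carries the configured hump
  rs$AM$richness <- list(baseline = 20, amplitude = 0, peak = 683,
                         width = 250, noise_sd = 0,
                         direction = "rise-then-fall")
  est <- vapply(1:20, function(s) {
    cfg <- generator_config(n_plots_AM = 60L, n_plots_AS = 2L,
                            responses = rs, seed = s)
    ind <- plot_indicators(generate_survey(cfg))
    am <- ind[ind$type == "AM", ]
    # span chosen so the smoothing window can resolve a 150-wide bump low on
    # a 0-1200 gradient; the package default (0.75) is tuned to mid-gradient
    # features and oversmooths this one
    find_peak(loess_fit(am$effective_holes, am$shannon, span = 0.5))$peak
  }, numeric(1))
  expect_lt(abs(mean(est) - 200) / 200, 0.15)
})

test_that("surveys round-trip through the CSV serialization", {
  dir <- withr::local_tempdir()
  s <- generate_survey(tiny_config(seed = 2))
  write_survey(s, dir)
  expect_true(all(file.exists(file.path(dir,
    c("plots.csv", "quadrats.csv", "provenance.json")))))
  s2 <- read_survey(dir)
  expect_equal(s2$plots$effective_holes, s$plots$effective_holes)
  expect_equal(s2$quadrats$abundance, s$quadrats$abundance)
  expect_equal(s2$config$seed, 2)
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(density_range = c(5, 2)), "ordered")
  expect_error(generator_config(edible_fraction = 1.4), "edible_fraction")
  expect_error(generator_config(min_spacing = 0), "min_spacing")
  rs <- default_responses(); rs$AM$shannon$width <- -1
  expect_error(generator_config(responses = rs), "invalid response")
  expect_error(generate_survey(list()), "generator_config")
})
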