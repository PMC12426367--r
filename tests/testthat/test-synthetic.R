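test_that("compound Poisson-gamma draws match Tweedie moments", {
  set.seed(21)
  x <- rtweedie_cpg(50000, mu = 5, p = 1.5, phi = 2)
  expect_lt(abs(mean(x) / 5 - 1), 0.03)
  expect_lt(abs(var(x) / (2 * 5^1.5) - 1), 0.05)
  expect_true(any(x == 0))      # zero-inflated
  expect_true(all(x >= 0))
  expect_equal(rtweedie_cpg(100, 0, 1.5, 2), rep(0, 100))
  # dispersion -> 0: mass concentrates at the mean
  set.seed(22)
  y <- rtweedie_cpg(1000, 5, 1.5, 0.005)
  expect_lt(sd(y) / mean(y), 0.05)
})

test_that("community generator follows the seasonal-trend mean structure", {
  sp <- data.frame(name = c("a", "b"), baseline = c(100, 100),
                   amplitude = c(0, 0.5), phase = c(3, 3), trend = c(1, 0.9),
                   catchability = 1e-4, price = 1, stringsAsFactors = FALSE)
  cfg <- scenario_config("XX", sp, years = 3,
                         calendar = closure_calendar(NULL))
  B <- gen_community(cfg)
  expect_equal(unname(B["a", , 1]), rep(100, 12))          # amplitude 0: flat
  expect_equal(B["b", 6, 1], 100 * (1 + 0.5 * sin(2 * pi * 3 / 12)))
  expect_equal(B["b", , 3], 0.81 * B["b", , 1])    # trend recursion

  # equal species phase-shifted by 6 months: monthly sum constant
  sp2 <- data.frame(name = c("a", "b"), baseline = 100, amplitude = 0.6,
                    phase = c(2, 8), trend = 1, catchability = 1e-4,
                    price = 1, stringsAsFactors = FALSE)
  cfg2 <- scenario_config("XX", sp2, years = 1,
                          calendar = closure_calendar(NULL))
  B2 <- gen_community(cfg2)
  expect_equal(unname(colSums(B2[, , 1])), rep(200, 12))
})

test_that("deterministic trend recursion hits the target period declines", {
  targets <- c(0.92, 0.77, 0.51)
  cfg <- scenario_preset("va_decline")
  B <- gen_community(cfg)                      # no year effects
  annual <- apply(B, c(1, 3), sum)
  realized <- 1 - rowMeans(annual[, 10:17]) / rowMeans(annual[, 1:9])
  expect_true(all(abs(realized - targets) / targets < 0.02))
})

test_that("closures mask harvests and effort renormalizes among open stocks", {
  sim <- simulate_scenario("md_closure", 6)
  h <- sim$records[sim$records$quantity_kind == "harvest_kg", ]
  sb_closed <- h[h$species == "striped_bass" & h$month %in% 3:5, ]
  expect_true(all(sb_closed$value == 0))
  sb_open <- h[h$species == "striped_bass" & h$month %in% 7:11, ]
  expect_true(all(sb_open$value > 0))
  t <- sim$records[sim$records$quantity_kind == "trips", ]
  expect_true(all(t$value[t$species == "striped_bass" & t$month %in% 3:5] == 0))

  # single open species receives all effort
  sp <- data.frame(name = c("a", "b"), baseline = 100, amplitude = 0,
                   phase = 3, trend = 1, catchability = 1e-2, price = 1,
                   stringsAsFactors = FALSE)
  cal <- closure_calendar(data.frame(region = "XX", species = "b",
                                     start = "01-01", end = "12-31"))
  cfg <- scenario_config("XX", sp, years = 1, calendar = cal, obs_sd = 0,
                         trips_jitter_sd = 0, effort_power = 0)
  set.seed(1)
  B <- gen_community(cfg)
  rec <- gen_harvest(B, cfg)
  hh <- rec[rec$quantity_kind == "harvest_kg", ]
  expect_true(all(hh$value[hh$species == "b"] == 0))
  expect_true(all(hh$value[hh$species == "a"] > 0))
  # all effort on a: harvest = q * 1 * E * B
  expect_equal(unique(round(hh$value[hh$species == "a"], 6)),
               round(1e-2 * cfg$base_effort * 100, 6))
})

test_that("zero elasticity splits effort evenly among open species", {
  sp <- data.frame(name = c("a", "b", "c"), baseline = c(100, 900, 500),
                   amplitude = 0, phase = 3, trend = 1,
                   catchability = 1e-2, price = c(1, 5, 2),
                   stringsAsFactors = FALSE)
  cfg <- scenario_config("XX", sp, years = 1, elasticity = 0, obs_sd = 0,
                         trips_jitter_sd = 0, effort_power = 0,
                         calendar = closure_calendar(NULL))
  set.seed(2)
  B <- gen_community(cfg)
  rec <- gen_harvest(B, cfg)
  hh <- rec[rec$quantity_kind == "harvest_kg" & rec$month == 1, ]
  # equal shares: harvest ratios equal biomass ratios
  expect_equal(hh$value[hh$species == "b"] / hh$value[hh$species == "a"], 9)
})

test_that("generators are pure functions of config and seed", {
  s1 <- simulate_scenario("va_compensation", 99)
  s2 <- simulate_scenario("va_compensation", 99)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$hauls, s2$hauls)
  s3 <- simulate_scenario("va_compensation", 100)
  expect_false(identical(s1$records$value, s3$records$value))
})

test_that("mean species compensation increases with pairwise phase offset", {
  offsets_mo <- c(0, pi / 4, pi / 2, pi) / (2 * pi) * 12
  mean_cpe <- sapply(offsets_mo, function(delta) {
    vals <- sapply(1:200, function(s) {
      sp <- data.frame(name = c("a", "b"), baseline = 100, amplitude = 0.6,
                       phase = c(3, 3 + delta), trend = 1,
                       catchability = 1e-4, price = 1,
                       stringsAsFactors = FALSE)
      cfg <- scenario_config("XX", sp, years = 1,
                             calendar = closure_calendar(NULL))
      set.seed(s)
      ye <- gen_year_effects(cfg)
      B <- gen_community(cfg, ye)
      tryCatch(cpe(temporal_stats(B[, c(3, 5, 7, 9, 11), 1])),
               finstab_degeneracy_error = function(e) NA)
    })
    mean(vals, na.rm = TRUE)
  })
  expect_true(all(diff(mean_cpe) > 0))
})

test_that("variance skew drives SAE toward 1, evenness toward sqrt(n)", {
  set.seed(44)
  dominant <- replicate(200, {
    x <- rbind(matrix(exp(rnorm(5, 5)), 1), matrix(exp(rnorm(15)), 3))
    sae(temporal_stats(x))
  })
  even <- replicate(200, {
    x <- matrix(exp(rnorm(120)), 4)   # T = 30: sample SDs concentrate
    sae(temporal_stats(x))
  })
  expect_lt(mean(dominant), 1.35)
  expect_gt(mean(even), 1.75)
  expect_gt(mean(even), mean(dominant))
})
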