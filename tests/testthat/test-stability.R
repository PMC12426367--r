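two_species <- function() {
  x <- rbind(A = c(4, 6), B = c(5, 4))
  colnames(x) <- 1:2
  x
}

test_that("temporal statistics match hand-evaluated sample formulas", {
  st <- temporal_stats(two_species())
  expect_equal(st$sigma_i, c(A = sqrt(2), B = sqrt(0.5)))
  expect_equal(st$mu_R, 9.5)
  expect_equal(st$sigma_R, sqrt(0.5))

  st1 <- temporal_stats(matrix(c(2, 4, 6), 1))
  expect_equal(st1$mu_R, 4)
  expect_equal(st1$sigma_R, 2)

  # homogeneity: scaling the panel scales all mus and sigmas
  st_c <- temporal_stats(3.5 * two_species())
  expect_equal(st_c$sigma_i, 3.5 * st$sigma_i)
  expect_equal(st_c$mu_R, 3.5 * st$mu_R)
})

test_that("the six partitioned quantities match direct formula evaluation", {
  d <- partition_stability(two_species(), layer = "harvest")
  expect_equal(d$S_agg, 9.5 / sqrt(0.5))            # ~13.435
  expect_equal(d$S_bar, 9.5 / (sqrt(2) + sqrt(0.5)))  # ~4.4783
  expect_equal(d$phi, 3.0)
  expect_equal(d$SAE, (sqrt(2) + sqrt(0.5)) / sqrt(2.5))  # ~1.3416
  expect_equal(d$CPE, sqrt(2.5) / sqrt(0.5))        # ~2.2361
  expect_equal(d$layer, "harvest")

  # n = 1 collapse: S_bar equals the species' own inverse CV
  one <- matrix(c(2, 4, 6), 1)
  expect_equal(species_stability(temporal_stats(one)),
               portfolio_stability(c(2, 4, 6)))
  expect_equal(portfolio_stability(c(2, 4, 6)), 2.0)
})

test_that("perfect synchrony gives phi of exactly one", {
  base <- c(2, 5, 9, 6, 3)
  m <- rbind(base, 2 * base, 0.5 * base)
  d <- partition_stability(m)
  expect_equal(d$phi, 1.0)
  expect_equal(d$S_agg, d$S_bar)
  # equal copies of one series: S_bar = S_agg as well
  expect_equal(partition_stability(rbind(base, base))$phi, 1.0)
  # two identical copies: CPE = 1/sqrt(2)
  expect_equal(partition_stability(rbind(base, base))$CPE, 1 / sqrt(2))
})

test_that("degenerate panels raise typed errors, not infinities", {
  const <- matrix(5, 3, 4)
  err <- expect_error(temporal_stats(const),
                      class = "finstab_degeneracy_error")
  expect_equal(err$code, "all_constant")

  zero <- matrix(0, 2, 3)
  expect_error(temporal_stats(zero), class = "finstab_degeneracy_error")

  # constant column sums: perfect compensation
  comp <- rbind(c(1, 2, 3), c(3, 2, 1))
  err <- expect_error(partition_stability(comp),
                      class = "finstab_degeneracy_error")
  expect_equal(err$code, "perfect_compensation")
  expect_match(conditionMessage(err), "layer")

  expect_error(portfolio_stability(rep(4, 5)),
               class = "finstab_degeneracy_error")
})

test_that("species with zero variance are retained in the mean, not the SDs", {
  x <- rbind(c(4, 6), c(7, 7))
  colnames(x) <- 1:2
  st <- temporal_stats(x)
  expect_equal(st$mu_R, 12)
  expect_equal(sum(st$sigma_i), sqrt(2))
  expect_equal(species_stability(st), 12 / sqrt(2))
})

test_that("multiplicative identities and bounds hold on a random ensemble", {
  set.seed(101)
  for (i in 1:2000) {
    n <- sample(2:6, 1)
    x <- rand_panel(n)
    d <- tryCatch(partition_stability(x),
                  finstab_degeneracy_error = function(e) NULL)
    if (is.null(d)) next
    expect_lt(abs(d$S_agg - d$phi * d$S_bar) / d$S_agg, 1e-10)
    expect_lt(abs(d$phi - d$SAE * d$CPE) / d$phi, 1e-10)
    expect_gte(d$phi, 1 - 1e-12)
    expect_gte(d$SAE, 1)
    expect_lte(d$SAE, sqrt(n) + 1e-12)
    # brute-force oracle: var of summed series = sum of covariance matrix
    expect_lt(abs(d$stats$sigma_R^2 - cov_sum_oracle(x)) / d$stats$sigma_R^2,
              1e-10)
  }
})

test_that("dimensionless outputs are scale and permutation invariant", {
  set.seed(7)
  x <- rand_panel(4)
  d <- partition_stability(x)
  d_scaled <- partition_stability(x * 1234.5)
  for (f in c("S_agg", "S_bar", "phi", "SAE", "CPE")) {
    expect_equal(d_scaled[[f]], d[[f]])
  }
  d_perm <- partition_stability(x[c(3, 1, 4, 2), ])
  for (f in c("S_agg", "S_bar", "phi", "SAE", "CPE")) {
    expect_equal(d_perm[[f]], d[[f]])
  }
})

test_that("CPE tends to one for independent equal-variance species", {
  set.seed(202)
  cpes <- replicate(2000, {
    x <- matrix(rnorm(4 * 60, mean = 50, sd = 1), 4, 60)
    cpe(temporal_stats(x))
  })
  expect_gt(mean(cpes), 0.93)
  expect_lt(mean(cpes), 1.07)
})

test_that("batch partitioning flags degenerate years instead of aborting", {
  rec <- make_records()
  # add a second, perfectly compensating year
  base <- data.frame(region = "MD", year = 2011L,
                     month = rep(c(3L, 5L, 7L, 9L, 11L), 2),
                     species = rep(c("alewife", "bluefish"), each = 5),
                     quantity_kind = "harvest_kg",
                     value = c(1, 2, 3, 4, 5, 5, 4, 3, 2, 1),
                     stringsAsFactors = FALSE)
  out <- partition_by_year(rbind(rec, base), "harvest_kg", "harvest")
  expect_equal(nrow(out), 2L)
  expect_equal(out$degenerate_flag[out$year == 2011], "perfect_compensation")
  expect_true(is.na(out$phi[out$year == 2011]))
  expect_false(is.na(out$phi[out$year == 2010]))
})
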