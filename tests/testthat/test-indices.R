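totals_panel <- function(totals, months = c(3L, 5L, 7L, 9L, 11L)) {
  x <- matrix(totals, nrow = 1, dimnames = list("sp", months))
  x
}

test_that("seasonal harvest ratio compares closure to open survey months", {
  p <- totals_panel(c(2, 4, 6, 6, 6))
  expect_equal(seasonal_harvest_ratio(p, closure = 3:5), 0.5)  # 3 / 6
  expect_equal(seasonal_harvest_ratio(totals_panel(rep(5, 5)), 3:5), 1.0)
  expect_equal(seasonal_harvest_ratio(totals_panel(c(0, 0, 4, 5, 6)), 3:5), 0)
  expect_error(seasonal_harvest_ratio(totals_panel(c(1, 1, 0, 0, 0)), 3:5),
               class = "finstab_degeneracy_error")
  # closure must split the survey months
  expect_error(seasonal_harvest_ratio(p, closure = integer(0)),
               class = "finstab_validation_error")
  # scale invariance
  expect_equal(seasonal_harvest_ratio(7 * p, 3:5),
               seasonal_harvest_ratio(p, 3:5))
})

test_that("harvest timing is the harvest-weighted mean month", {
  h <- rep(0, 12); h[7] <- 3
  expect_equal(mean_harvest_month(h, 1:12), 7)
  h2 <- rep(0, 12); h2[c(6, 8)] <- 2
  expect_equal(mean_harvest_month(h2, 1:12), 7)
  expect_equal(mean_harvest_month(c(1, 3), c(3, 11)), 9)  # (3 + 33) / 4
  expect_error(mean_harvest_month(rep(0, 12), 1:12),
               class = "finstab_degeneracy_error")
  # bounded by the months carrying positive harvest
  set.seed(5)
  for (i in 1:50) {
    h <- runif(12) * rbinom(12, 1, 0.5)
    if (sum(h) == 0) next
    m <- mean_harvest_month(h, 1:12)
    expect_gte(m, min(which(h > 0)))
    expect_lte(m, max(which(h > 0)))
  }
})

test_that("effort index averages species trip totals over survey months", {
  x <- rbind(A = c(10, 15, 10, 10, 5), B = c(5, 10, 5, 5, 5))
  colnames(x) <- c(3, 5, 7, 9, 11)
  expect_equal(effort_index(x), mean(c(50, 30)))  # 40
  expect_equal(effort_index(x[1, , drop = FALSE]), 50)
  expect_equal(effort_index(2 * x), 2 * effort_index(x))  # linearity
  expect_equal(effort_index(x, method = "monthly_mean"),
               mean(colMeans(x)))
  x_off <- x; colnames(x_off) <- c(1, 2, 4, 6, 8)
  expect_warning(out <- effort_index(x_off, survey_months = c(3, 5)),
                 "no trip data")
  expect_true(is.na(out))
})

test_that("portfolio totals and stabilities follow their definitions", {
  h <- rbind(A = c(1:6, 6:1), B = rep(2, 12))
  colnames(h) <- 1:12
  v <- h * 3
  expect_equal(portfolio_totals(h, v),
               c(yield = sum(h), value = 3 * sum(h)))
  expect_equal(portfolio_totals(h * 0, v * 0), c(yield = 0, value = 0))

  tot <- colSums(h)
  s <- portfolio_stability_short_long(h)
  expect_equal(s[["S_portfolio_S"]],
               mean(tot[c(3, 5, 7, 9, 11)]) / sd(tot[c(3, 5, 7, 9, 11)]))
  expect_equal(s[["S_portfolio_L"]], mean(tot) / sd(tot))

  # totals varying only outside the survey months: S short degenerate,
  # L finite
  h2 <- rbind(A = c(9, 1, 2, 1, 2, 1, 2, 1, 2, 1, 2, 1))
  colnames(h2) <- 1:12
  expect_error(portfolio_stability_short_long(h2),
               class = "finstab_degeneracy_error")
  expect_equal(portfolio_stability(colSums(h2)),
               mean(colSums(h2)) / sd(colSums(h2)))

  expect_equal(value_stability(v), s[["S_portfolio_L"]])  # scale invariance
  expect_error(value_stability(matrix(4, 1, 12)),
               class = "finstab_degeneracy_error")
})

test_that("top-90% species selection uses inclusive crossing", {
  expect_equal(select_top_species(c(A = 80, B = 15, C = 5)), c("A", "B"))
  expect_equal(select_top_species(c(solo = 12)), "solo")
  eq <- setNames(rep(10, 10), letters[1:10])
  expect_length(select_top_species(eq), 9L)
  # invariant to input order and uniform scaling; alphabetical tie-break
  y <- c(gar = 5, eel = 80, cod = 15)
  expect_equal(select_top_species(y), select_top_species(rev(y)))
  expect_equal(select_top_species(y), select_top_species(y * 1e6))
  expect_equal(select_top_species(c(b = 50, a = 50))[1], "a")
})

test_that("annual indicator table assembles all region-year indices", {
  sim <- simulate_scenario("md_closure", 11)
  cal <- sim$config$calendar
  ind <- annual_indicators(sim$records, "MD", cal)
  expect_equal(nrow(ind), 17L)
  expect_true(all(is.finite(ind$shr)))
  expect_true(all(ind$shr >= 0))
  expect_true(all(is.finite(ind$s_portfolio_l)))
  expect_true(all(is.finite(ind$effort_index)))
  timing_cols <- grep("^timing_", names(ind), value = TRUE)
  expect_gt(length(timing_cols), 0L)
  tm <- as.matrix(ind[timing_cols])
  expect_true(all(tm >= 1 & tm <= 12, na.rm = TRUE))
  # striped bass timing must avoid the March-May closure pull:
  # its harvests are zero there, so the weighted month is > 5
  expect_true(all(ind$timing_striped_bass > 5))
})
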