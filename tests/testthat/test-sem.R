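test_that("path models reject cycles and parse edge strings", {
  expect_error(path_model(c("a -> b", "b -> a")),
               class = "finstab_validation_error")
  expect_error(path_model("a -> a"), class = "finstab_validation_error")
  pm <- path_model(c("x -> y", "y -> z"))
  expect_equal(pm$vars, c("x", "y", "z"))
  expect_equal(pm$topo, c("x", "y", "z"))
})

test_that("Fisher's C matches its closed forms", {
  fc <- fishers_c(c(0.5, 0.5))
  expect_equal(fc$C, 4 * log(2))
  expect_equal(fc$df, 4L)
  expect_equal(fc$p, pchisq(4 * log(2), 4, lower.tail = FALSE))

  expect_equal(fishers_c(numeric(0)), list(C = 0, df = 0L, p = 1))
  fc1 <- fishers_c(c(1, 1, 1))
  expect_equal(fc1$C, 0)
  expect_equal(fc1$p, 1)
  expect_warning(fc0 <- fishers_c(c(0, 0.5)), "clamped")
  expect_true(is.finite(fc0$C))
})

test_that("basis sets match textbook cases", {
  # saturated DAG: no claims
  expect_length(basis_set(path_model(c("a -> b", "a -> c", "b -> c"))), 0L)
  # chain x -> y -> z: single claim z _||_ x | y
  cl <- basis_set(path_model(c("x -> y", "y -> z")))
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$u, "x")
  expect_equal(cl[[1]]$v, "z")
  expect_equal(cl[[1]]$cond, "y")
  # two exogenous parents of a collider: no claim between them
  cl2 <- basis_set(path_model(c("a -> c", "b -> c")))
  expect_length(cl2, 0L)
})

test_that("every emitted claim is a true d-separation (exhaustive <= 4 nodes)", {
  for (n in 2:4) {
    dags <- enumerate_dags(n)
    for (e in dags) {
      pm <- path_model(e)
      for (cl in basis_set(pm)) {
        expect_true(oracle_dsep(e, cl$u, cl$v, cl$cond),
                    info = paste("dag:", paste(e$cause, "->", e$effect,
                                               collapse = "; "),
                                 "claim:", cl$u, "_||_", cl$v, "|",
                                 paste(cl$cond, collapse = ",")))
      }
    }
  }
})

test_that("claims on random 5-node DAGs agree with the graphical oracle", {
  set.seed(55)
  for (i in 1:150) {
    e <- random_dag(5L)
    if (!nrow(e)) next
    pm <- path_model(e)
    for (cl in basis_set(pm)) {
      expect_true(oracle_dsep(e, cl$u, cl$v, cl$cond))
    }
  }
  # five-variable fixture shaped like a two-layer indicator network
  e <- path_model(c("sae_sp -> cpe_sp", "sae_sp -> cpe_h", "cpe_sp -> cpe_h",
                    "sae_sp -> effort", "effort -> sbar_h"))
  cls <- basis_set(e)
  # claims must cover every non-adjacent pair exactly once
  pair_key <- sort(vapply(cls, function(cl)
    paste(sort(c(cl$u, cl$v)), collapse = "~"), ""))
  expect_equal(pair_key,
               sort(c("cpe_h~effort", "cpe_h~sbar_h", "cpe_sp~effort",
                      "cpe_sp~sbar_h", "sae_sp~sbar_h")))
  for (cl in cls) {
    expect_true(oracle_dsep(e$edges, cl$u, cl$v, cl$cond))
  }
})

test_that("sub-model fitting recovers exact and simulated relationships", {
  d <- data.frame(x = 1:10, y = 2 * (1:10))
  fit <- fit_submodel(d, "y", "x", error = "iid")
  ct <- fit$coefficients
  expect_equal(ct$estimate[ct$term == "x"], 2)
  expect_lt(ct$p[ct$term == "x"], 1e-10)

  # AR(1) machinery with rho fixed at zero reproduces OLS
  set.seed(9)
  d2 <- data.frame(x = rnorm(17), y = rnorm(17))
  ols <- fit_submodel(d2, "y", "x", error = "iid")
  gls0 <- fit_submodel(d2, "y", "x", error = "ar1", fixed_rho = 0)
  expect_equal(gls0$coefficients$estimate, ols$coefficients$estimate,
               tolerance = 1e-8)

  # collinear design
  d3 <- data.frame(x = 1:10, x2 = 2 * (1:10), y = rnorm(10))
  err <- expect_error(fit_submodel(d3, "y", c("x", "x2")),
                      class = "finstab_validation_error")
  expect_equal(err$code, "collinear")
  expect_error(fit_submodel(d3[1:3, ], "y", c("x", "x2")),
               class = "finstab_validation_error")
})

test_that("ML AR(1) regression recovers a known slope on short series", {
  set.seed(77)
  slopes <- replicate(500, {
    n <- 17
    e <- as.numeric(arima.sim(list(ar = 0.6), n, sd = 1))
    x <- rnorm(n)
    d <- data.frame(x = x, y = 1.5 * x + e)
    fit <- fit_submodel(d, "y", "x", error = "ar1")
    fit$coefficients$estimate[fit$coefficients$term == "x"]
  })
  expect_lt(abs(mean(slopes) / 1.5 - 1), 0.05)
})

test_that("standardized coefficients reduce to Pearson correlation", {
  set.seed(12)
  d <- data.frame(x = rnorm(17, sd = 3), y = rnorm(17, sd = 0.2))
  fit <- fit_submodel(d, "y", "x")
  b_std <- fit$coefficients$std_estimate[fit$coefficients$term == "x"]
  expect_equal(b_std, cor(d$x, d$y), tolerance = 1e-10)
  # pre-scaled data: std coefficient equals the raw one
  ds <- data.frame(x = as.numeric(scale(d$x)), y = as.numeric(scale(d$y)))
  fs <- fit_submodel(ds, "y", "x")
  expect_equal(fs$coefficients$std_estimate[2], fs$coefficients$estimate[2],
               tolerance = 1e-8)
})

test_that("two-predictor standardization matches the normal-equations oracle", {
  set.seed(13)
  n <- 200
  x1 <- rnorm(n); x2 <- 0.6 * x1 + rnorm(n, sd = 0.8)
  y <- 1.2 * x1 - 0.7 * x2 + rnorm(n)
  d <- data.frame(x1 = x1, x2 = x2, y = y)
  fit <- fit_submodel(d, "y", c("x1", "x2"))
  # oracle: beta = solve(cov(X)) %*% cov(X, y), standardized by sds
  X <- cbind(x1, x2)
  beta <- solve(cov(X), cov(X, y))
  b_std_oracle <- as.numeric(beta) * apply(X, 2, sd) / sd(y)
  ct <- fit$coefficients
  expect_equal(ct$std_estimate[match(c("x1", "x2"), ct$term)],
               unname(b_std_oracle), tolerance = 1e-10)
})

test_that("log transform fits and standardizes on the log scale", {
  set.seed(14)
  d <- data.frame(x = rnorm(30), y = exp(rnorm(30)))
  fit <- fit_submodel(d, "y", "x", transform = "log")
  direct <- lm(log(y) ~ x, data = d)
  expect_equal(fit$coefficients$estimate, unname(coef(direct)),
               tolerance = 1e-10)
  d$y[1] <- -1
  expect_error(fit_submodel(d, "y", "x", transform = "log"),
               class = "finstab_validation_error")
})

test_that("a single-edge model is saturated: one path, C = 0, p = 1", {
  set.seed(15)
  d <- data.frame(x = rnorm(17), y = rnorm(17))
  fit <- fit_psem(path_model("x -> y"), d)
  expect_equal(nrow(fit$paths), 1L)
  expect_equal(nrow(fit$claims), 0L)
  expect_equal(fit$C, 0)
  expect_equal(fit$p, 1)
})

test_that("directed-separation test detects an omitted strong path", {
  set.seed(16)
  pm <- path_model(c("x -> y", "y -> z"))
  hits <- replicate(200, {
    x <- rnorm(17)
    y <- 0.8 * x + rnorm(17, sd = 0.6)
    z <- 0.8 * y + 1.2 * x + rnorm(17, sd = 0.6)  # strong direct x -> z
    fit <- fit_psem(pm, data.frame(x = x, y = y, z = z))
    fit$p < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("incomplete years are dropped and reported", {
  set.seed(17)
  d <- data.frame(year = 2002:2018, x = rnorm(17), y = rnorm(17))
  d$x[1:3] <- NA
  fit <- fit_psem(path_model("x -> y"), d)
  expect_equal(fit$dropped_years, 2002:2004)
  expect_equal(fit$submodels$y$n, 14L)
})
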