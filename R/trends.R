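# Interannual trend models with autocorrelation-robust errors.
#
# Linear or quadratic trends in an annual indicator series, fitted by
# maximum likelihood with iid, AR(1) or AR(2) residuals.  The AR order is
# config-driven (residual inspection is not reproducible); trend terms are
# flagged for display when p < 0.1.

#' Fit an interannual trend model
#'
#' @param year integer years (need not be consecutive, but AR structures
#'   assume roughly even spacing).
#' @param y annual values (NAs dropped pairwise with their years).
#' @param form `"linear"` or `"quadratic"` (the quadratic approximates a
#'   smoother-shaped trend).
#' @param ar_order residual autoregressive order: 0 (OLS), 1 or 2.
#' @param alpha flagging level for trend inclusion (default 0.1).
#' @return object of class `trend_fit`: coefficient table (`estimate`,
#'   `se`, `t`, `p`), AR coefficients `rho`, fitted values with 95% CI
#'   half-widths, the `included` flag (any trend term with p < `alpha`),
#'   `n`, `df`.
#' @examples
#' set.seed(2)
#' y <- 0.3 * (1:17) + arima.sim(list(ar = 0.5), 17)
#' fit_trend(2002:2018, as.numeric(y), ar_order = 1)
#' @importFrom stats arima.sim
#' @export
fit_trend <- function(year, y, form = c("linear", "quadratic"),
                      ar_order = 1L, alpha = 0.1) {
  form <- match.arg(form)
  ar_order <- as.integer(ar_order)
  stopifnot(ar_order %in% 0:2, length(year) == length(y))
  keep <- complete.cases(year, y)
  d <- data.frame(year = year[keep], y = y[keep])
  d <- d[order(d$year), , drop = FALSE]
  n <- nrow(d)
  d$t1 <- d$year - mean(d$year)
  p <- if (form == "linear") 2L else 3L
  if (n < p + ar_order + 2L) {
    stop_validation(paste0("need at least ", p + ar_order + 2L,
                           " years for ", form, " trend with AR(",
                           ar_order, ") errors; got ", n),
                    code = "insufficient_years")
  }
  f <- if (form == "linear") y ~ t1 else y ~ t1 + I(t1^2)
  rho <- numeric(0)
  if (ar_order == 0L) {
    fit <- lm(f, data = d)
    beta <- coef(fit); V <- vcov(fit)
    res <- residuals(fit)
  } else {
    d$..t <- seq_len(n)
    fit <- nlme::gls(f, data = d,
                     correlation = nlme::corARMA(p = ar_order, form = ~..t),
                     method = "ML")
    beta <- coef(fit); V <- vcov(fit)
    res <- residuals(fit)
    rho <- as.numeric(coef(fit$modelStruct$corStruct, unconstrained = FALSE))
    roots <- polyroot(c(1, -rho))
    if (any(Mod(roots) <= 1 + 1e-8)) {
      stop_validation("estimated AR process is non-stationary",
                      code = "nonstationary")
    }
  }
  X <- if (form == "linear") cbind(1, d$t1) else cbind(1, d$t1, d$t1^2)
  se <- sqrt(diag(V))
  tval <- beta / se
  df_res <- n - p
  pval <- 2 * pt(-abs(tval), df_res)
  fitv <- as.numeric(X %*% beta)
  hw <- qt(0.975, df_res) * sqrt(rowSums((X %*% V) * X))
  coefs <- data.frame(term = names(beta), estimate = as.numeric(beta),
                      se = as.numeric(se), t = as.numeric(tval),
                      p = as.numeric(pval),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(form = form, ar_order = ar_order, coefficients = coefs,
                 rho = rho, year = d$year, y = d$y, fitted = fitv,
                 ci_halfwidth = as.numeric(hw), residuals = as.numeric(res),
                 included = any(pval[-1L] < alpha), alpha = alpha,
                 n = n, df = df_res),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, digits = 4L, ...) {
  cat("Interannual ", x$form, " trend, AR(", x$ar_order, ") errors, n = ",
      x$n, "\n", sep = "")
  print(x$coefficients, digits = digits)
  if (length(x$rho)) cat("AR coefficients:", round(x$rho, digits), "\n")
  cat(if (x$included) paste0("Trend included (p < ", x$alpha, ")")
      else "No trend at the display threshold", "\n")
  invisible(x)
}

#' @export
coef.trend_fit <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
residuals.trend_fit <- function(object, ...) object$residuals

#' @export
predict.trend_fit <- function(object, year = object$year, ...) {
  t1 <- year - mean(object$year)
  X <- if (object$form == "linear") cbind(1, t1) else cbind(1, t1, t1^2)
  as.numeric(X %*% coef(object))
}

#' @export
plot.trend_fit <- function(x, ...) {
  graphics::plot(x$year, x$y, pch = 16, xlab = "year", ylab = "value", ...)
  o <- order(x$year)
  graphics::polygon(c(x$year[o], rev(x$year[o])),
                    c((x$fitted + x$ci_halfwidth)[o],
                      rev((x$fitted - x$ci_halfwidth)[o])),
                    col = grDevices::adjustcolor("grey60", 0.4), border = NA)
  graphics::lines(x$year[o], x$fitted[o], lwd = 2)
  invisible(x)
}
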