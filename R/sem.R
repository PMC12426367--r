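# Piecewise structural equation models over annual indicator series.
#
# A path model is a DAG of linear sub-models fitted one response at a time
# (OLS, or ML generalized least squares with AR(1) errors for short
# autocorrelated annual series).  Overall fit is tested by directed
# separation: each conditional-independence claim implied by the DAG is
# tested by adding the claimed-independent variable to the corresponding
# regression, and the claim p-values are combined into Fisher's
# C = -2 * sum(log p), compared against chi-square with 2k df.

#' Declare a path model
#'
#' @param edges directed edges, either a character vector of
#'   `"cause -> effect"` strings or a data frame with columns `cause`,
#'   `effect`.  The edge set must be acyclic.
#' @param error named character vector giving the residual error structure
#'   (`"iid"` or `"ar1"`) per response; unnamed responses default to
#'   `"iid"`.
#' @param transform named character vector of per-response transforms
#'   (`"none"` or `"log"`), applied to the response before fitting (and
#'   before standardization).
#' @return object of class `path_model` with elements `vars`, `edges`,
#'   `error`, `transform`.
#' @export
path_model <- function(edges, error = NULL, transform = NULL) {
  if (is.character(edges)) {
    parts <- strsplit(edges, "->", fixed = TRUE)
    if (any(lengths(parts) != 2L)) {
      stop_validation("edges must look like 'cause -> effect'",
                      code = "bad_edge")
    }
    edges <- data.frame(cause = trimws(vapply(parts, `[`, "", 1L)),
                        effect = trimws(vapply(parts, `[`, "", 2L)),
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(edges), all(c("cause", "effect") %in% names(edges)))
  if (any(edges$cause == edges$effect)) {
    stop_validation("self-loops are not allowed", code = "cycle")
  }
  vars <- sort(unique(c(edges$cause, edges$effect)))
  # Kahn topological sort; leftover nodes indicate a cycle
  indeg <- setNames(tabulate(match(edges$effect, vars), length(vars)), vars)
  order <- character(0)
  queue <- names(indeg)[indeg == 0L]
  remaining <- edges
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    out <- remaining$cause == v
    for (child in remaining$effect[out]) {
      indeg[child] <- indeg[child] - 1L
      if (indeg[child] == 0L) queue <- c(queue, child)
    }
    remaining <- remaining[!out, , drop = FALSE]
  }
  if (length(order) != length(vars)) {
    stop_validation("edge set contains a cycle", code = "cycle")
  }
  err <- setNames(rep("iid", length(vars)), vars)
  if (!is.null(error)) {
    stopifnot(all(error %in% c("iid", "ar1")), all(names(error) %in% vars))
    err[names(error)] <- error
  }
  tr <- setNames(rep("none", length(vars)), vars)
  if (!is.null(transform)) {
    stopifnot(all(transform %in% c("none", "log")),
              all(names(transform) %in% vars))
    tr[names(transform)] <- transform
  }
  structure(list(vars = vars, edges = edges, error = err, transform = tr,
                 topo = order),
            class = "path_model")
}

pm_parents <- function(pm, v) sort(pm$edges$cause[pm$edges$effect == v])

pm_ancestors <- function(pm) {
  anc <- setNames(vector("list", length(pm$vars)), pm$vars)
  for (v in pm$topo) {
    pa <- pm_parents(pm, v)
    anc[[v]] <- sort(unique(c(pa, unlist(anc[pa]))))
  }
  anc
}

#' Basis set of directed-separation claims
#'
#' For every non-adjacent ordered pair `(u, v)` where `v` is endogenous and
#' not an ancestor of `u`, the model implies the conditional independence
#' `u _||_ v | parents(v) + (parents(u) intersect ancestors(v))`.  Unordered
#' pairs are emitted once, with the dependent variable chosen endogenous
#' (preferring the topologically later variable); pairs of two exogenous
#' variables carry no claim.
#'
#' @param pm a `path_model`.
#' @return list of claims, each a list with elements `u` (independent
#'   variable under test), `v` (dependent variable) and `cond`
#'   (conditioning set, possibly empty).
#' @export
basis_set <- function(pm) {
  vars <- pm$vars
  endo <- unique(pm$edges$effect)
  anc <- pm_ancestors(pm)
  adj <- paste(pmin(pm$edges$cause, pm$edges$effect),
               pmax(pm$edges$cause, pm$edges$effect))
  topo_rank <- setNames(seq_along(pm$topo), pm$topo)
  claims <- list()
  if (length(vars) < 2L) return(claims)
  combs <- utils::combn(vars, 2L)
  for (j in seq_len(ncol(combs))) {
    a <- combs[1L, j]; b <- combs[2L, j]
    if (paste(pmin(a, b), pmax(a, b)) %in% adj) next
    ok <- function(u, v) v %in% endo && !(v %in% anc[[u]])
    cand <- list()
    if (ok(a, b)) cand <- c(cand, list(c(a, b)))
    if (ok(b, a)) cand <- c(cand, list(c(b, a)))
    if (!length(cand)) next
    if (length(cand) == 2L) {
      # keep the claim whose dependent variable is topologically later
      ranks <- vapply(cand, function(p) topo_rank[[p[2L]]], numeric(1L))
      cand <- cand[order(-ranks, vapply(cand, `[`, "", 2L))][1L]
    }
    u <- cand[[1L]][1L]; v <- cand[[1L]][2L]
    cond <- sort(unique(c(pm_parents(pm, v),
                          intersect(pm_parents(pm, u), anc[[v]]))))
    claims[[length(claims) + 1L]] <- list(u = u, v = v, cond = cond)
  }
  claims
}

apply_transform <- function(x, transform) {
  if (transform == "log") {
    if (any(x <= 0)) {
      stop_validation("log transform requires positive values",
                      code = "bad_transform")
    }
    log(x)
  } else x
}

#' Fit one linear sub-model with iid or AR(1) errors
#'
#' OLS for iid errors; for AR(1) errors, maximum-likelihood generalized
#' least squares with a stationarity-constrained autocorrelation parameter
#' (via [nlme::gls()] with [nlme::corAR1()]).  Inference uses t-tests on
#' `n - p` residual df with the (GLS) coefficient covariance.
#'
#' @param data data frame of annual series, rows in time order.
#' @param response response variable name.
#' @param predictors character vector of predictor names (non-empty).
#' @param error `"iid"` or `"ar1"`.
#' @param transform `"none"` or `"log"`, applied to the response.
#' @param fixed_rho optional fixed AR(1) coefficient (e.g., 0 to reproduce
#'   OLS through the GLS machinery).
#' @return list with the coefficient table (`estimate`, `std_estimate`,
#'   `se`, `t`, `p` per term), `rho`, `sigma`, `n`, `df`, `dropped_rows`,
#'   `residuals`, `fitted` and the declared `error`/`transform`.
#' @export
fit_submodel <- function(data, response, predictors,
                         error = c("iid", "ar1"), transform = "none",
                         fixed_rho = NULL) {
  error <- match.arg(error)
  stopifnot(length(predictors) >= 1L)
  used <- c(response, predictors)
  stopifnot(all(used %in% names(data)))
  cc <- complete.cases(data[used])
  dropped <- which(!cc)
  d <- data[cc, used, drop = FALSE]
  n <- nrow(d)
  p <- length(predictors) + 1L
  need <- p + 1L + (error == "ar1")
  if (n < need) {
    stop_validation(paste0("sub-model for ", response, " needs >= ", need,
                           " complete years, got ", n),
                    code = "insufficient_years")
  }
  d[[response]] <- apply_transform(d[[response]], transform)
  X <- cbind(1, as.matrix(d[predictors]))
  if (qr(X)$rank < ncol(X)) {
    stop_validation(paste0("rank-deficient design for response ", response),
                    code = "collinear")
  }
  f <- as.formula(paste(response, "~",
                        paste(sprintf("`%s`", predictors), collapse = " + ")))
  rho <- 0
  if (error == "iid") {
    fit <- lm(f, data = d)
    beta <- coef(fit)
    V <- vcov(fit)
    res <- residuals(fit)
    fitv <- fitted(fit)
    sigma <- summary(fit)$sigma
  } else {
    d$..t <- seq_len(n)
    cs <- if (is.null(fixed_rho)) nlme::corAR1(form = ~..t)
          else nlme::corAR1(value = fixed_rho, form = ~..t, fixed = TRUE)
    fit <- nlme::gls(f, data = d, correlation = cs, method = "ML")
    beta <- coef(fit)
    V <- vcov(fit)
    res <- residuals(fit)
    fitv <- fitted(fit)
    sigma <- fit$sigma
    rho <- as.numeric(coef(fit$modelStruct$corStruct, unconstrained = FALSE))
    if (abs(rho) >= 1) {
      stop_validation("estimated AR(1) coefficient is non-stationary",
                      code = "nonstationary")
    }
  }
  se <- sqrt(diag(V))
  tval <- beta / se
  df_res <- n - p
  pval <- 2 * pt(-abs(tval), df_res)
  sd_y <- sd(d[[response]])
  sd_x <- c(NA_real_, vapply(predictors, function(v) sd(d[[v]]), numeric(1L)))
  coefs <- data.frame(
    term = names(beta),
    estimate = as.numeric(beta),
    std_estimate = as.numeric(beta) * sd_x / sd_y,
    se = as.numeric(se), t = as.numeric(tval), p = as.numeric(pval),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(response = response, predictors = predictors, coefficients = coefs,
       rho = rho, sigma = sigma, n = n, df = df_res,
       dropped_rows = dropped, residuals = as.numeric(res),
       fitted = as.numeric(fitv), error = error, transform = transform)
}

#' Standardize a raw path coefficient
#'
#' @param estimate raw coefficient (response units per predictor unit).
#' @param sd_x,sd_y SDs of the modeled predictor and response (on the
#'   scales entering the regression, i.e., after any declared transform).
#' @return dimensionless standardized coefficient.
#' @export
standardize_coef <- function(estimate, sd_x, sd_y) estimate * sd_x / sd_y

#' Combine independence-claim p-values into Fisher's C
#'
#' `C = -2 * sum(log p_i)` compared to chi-square with `2k` df.  An empty
#' claim set (saturated model) gives `C = 0`, `df = 0`, `p = 1` by
#' convention.  Zero p-values are clamped at 1e-300 with a warning.
#'
#' @param p numeric vector of claim p-values in `[0, 1]`.
#' @return list with `C`, `df`, `p`.
#' @export
fishers_c <- function(p) {
  if (!length(p)) return(list(C = 0, df = 0L, p = 1))
  stopifnot(all(p >= 0 & p <= 1))
  if (any(p == 0)) {
    warning("zero claim p-values clamped at 1e-300")
    p[p == 0] <- 1e-300
  }
  C <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(C = C, df = df, p = pchisq(C, df, lower.tail = FALSE))
}

#' Fit a piecewise structural equation model
#'
#' Fits every sub-model of the declared DAG, tests every directed-separation
#' claim in the basis set (each by adding the claimed-independent variable
#' to the claim's conditional regression, inheriting the error structure
#' and transform declared for the dependent variable), and combines the
#' claim p-values into Fisher's C.
#'
#' @param pm a `path_model`.
#' @param data data frame of annual series (one row per year).  If a
#'   `year` column is present, rows are ordered by it before fitting.
#' @param alpha flagging level for individual paths (default 0.1).
#' @return object of class `psem_fit` with `submodels`, the flat path
#'   table `paths`, the claim table `claims`, `C`, `df`, `p`,
#'   per-sub-model lag-1 residual autocorrelations `resid_ac1`, and
#'   `dropped_years`.
#' @examples
#' set.seed(1)
#' x <- rnorm(17); y <- 0.8 * x + rnorm(17); z <- 0.8 * y + rnorm(17)
#' fit <- fit_psem(path_model(c("x -> y", "y -> z")),
#'                 data.frame(x = x, y = y, z = z))
#' print(fit)
#' coef(fit)
#' @export
fit_psem <- function(pm, data, alpha = 0.1) {
  stopifnot(inherits(pm, "path_model"))
  if ("year" %in% names(data)) data <- data[order(data$year), , drop = FALSE]
  missing_vars <- setdiff(pm$vars, names(data))
  if (length(missing_vars)) {
    stop_validation(paste0("data lacks variables: ",
                           paste(missing_vars, collapse = ", ")),
                    code = "missing_variables")
  }
  endo <- intersect(pm$topo, unique(pm$edges$effect))
  submodels <- list()
  for (v in endo) {
    submodels[[v]] <- fit_submodel(data, v, pm_parents(pm, v),
                                   error = pm$error[[v]],
                                   transform = pm$transform[[v]])
  }
  paths <- do.call(rbind, lapply(endo, function(v) {
    ct <- submodels[[v]]$coefficients
    ct <- ct[ct$term != "(Intercept)", , drop = FALSE]
    data.frame(response = v, predictor = ct$term,
               estimate = ct$estimate, std_estimate = ct$std_estimate,
               se = ct$se, p = ct$p,
               significant = ct$p < alpha,
               error = submodels[[v]]$error,
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  claims <- basis_set(pm)
  claim_rows <- lapply(claims, function(cl) {
    fit <- fit_submodel(data, cl$v, c(cl$cond, cl$u),
                        error = pm$error[[cl$v]],
                        transform = pm$transform[[cl$v]])
    ct <- fit$coefficients
    p_u <- ct$p[ct$term == cl$u]
    data.frame(u = cl$u, v = cl$v,
               cond = paste(cl$cond, collapse = ","),
               p = p_u, stringsAsFactors = FALSE)
  })
  claims_df <- if (length(claim_rows)) do.call(rbind, claim_rows)
               else data.frame(u = character(0), v = character(0),
                               cond = character(0), p = numeric(0),
                               stringsAsFactors = FALSE)
  fc <- fishers_c(claims_df$p)
  ac1 <- vapply(submodels, function(sm) {
    r <- sm$residuals
    if (length(r) < 3L) return(NA_real_)
    as.numeric(acf(r, lag.max = 1L, plot = FALSE)$acf[2L])
  }, numeric(1L))
  dropped <- sort(unique(unlist(lapply(submodels, `[[`, "dropped_rows"))))
  dropped_years <- if ("year" %in% names(data)) data$year[dropped] else dropped
  structure(list(model = pm, submodels = submodels, paths = paths,
                 claims = claims_df, C = fc$C, df = fc$df, p = fc$p,
                 resid_ac1 = ac1, dropped_years = dropped_years,
                 alpha = alpha, n_years = nrow(data)),
            class = "psem_fit")
}

#' @export
print.psem_fit <- function(x, digits = 3L, ...) {
  cat("Piecewise SEM:", length(x$submodels), "sub-models,",
      nrow(x$claims), "d-separation claims\n")
  cat(sprintf("Fisher's C = %.3f, df = %d, p = %.4f\n", x$C, x$df, x$p))
  cat("\nPaths (std. coefficients; * p <", x$alpha, "):\n")
  p <- x$paths
  cat(paste0(sprintf("  %s -> %s: %.*f (p = %.4f)%s",
                     p$predictor, p$response, digits, p$std_estimate, p$p,
                     ifelse(p$significant, " *", "")),
             collapse = "\n"), "\n")
  if (length(x$dropped_years)) {
    cat("Dropped incomplete years:", paste(x$dropped_years, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
summary.psem_fit <- function(object, ...) {
  cat("Piecewise structural equation model\n")
  print(object)
  cat("\nD-separation claims:\n")
  if (nrow(object$claims)) print(object$claims) else cat("  (saturated)\n")
  cat("\nLag-1 residual autocorrelation by sub-model:\n")
  print(round(object$resid_ac1, 3L))
  invisible(object)
}

#' @export
coef.psem_fit <- function(object, standardized = TRUE, ...) {
  p <- object$paths
  setNames(if (standardized) p$std_estimate else p$estimate,
           paste(p$predictor, "->", p$response))
}

#' @export
residuals.psem_fit <- function(object, ...) {
  lapply(object$submodels, `[[`, "residuals")
}

#' Read a path-model declaration from YAML
#'
#' Layout:
#' ```yaml
#' edges: ["cpe_species -> cpe_harvest", "sae_species -> cpe_harvest"]
#' error: {cpe_harvest: ar1}
#' transform: {portfolio_value: log}
#' ```
#'
#' @param path YAML file path.
#' @return a `path_model`.
#' @export
read_path_model <- function(path) {
  y <- yaml::read_yaml(path)
  path_model(unlist(y$edges),
             error = if (length(y$error)) unlist(y$error),
             transform = if (length(y$transform)) unlist(y$transform))
}
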