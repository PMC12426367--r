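# Within-year stability-asynchrony partitioning.
#
# For a species x month matrix of biomass or harvest, aggregate stability
# (inverse CV of the monthly column sums) factors exactly as
#
#   S_agg = phi * S_bar,        phi = SAE * CPE,
#
# where S_bar is the inverse of the abundance-weighted mean species CV,
# phi = sum_i sigma_i / sigma_R is asynchrony (>= 1, with 1 = perfect
# synchrony), SAE = sum_i sigma_i / sqrt(sum_i sigma_i^2) the statistical-
# averaging effect (in [1, sqrt(n)]), and CPE = sqrt(sum_i sigma_i^2) /
# sigma_R the compensation effect (> 1 under negative covariances; the
# inverse square-rooted variance ratio).  All SDs use the sample (T - 1)
# denominator; with T = 5 survey months this choice is numerically
# consequential for the S's though the dimensionless ratios barely move.

panel_matrix <- function(panel) {
  if (inherits(panel, "monthly_panel")) panel$x
  else if (is.matrix(panel)) panel
  else stop_validation("panel must be a matrix or monthly_panel")
}

# Relative threshold below which an SD is treated as exactly zero.
REL_EPS <- 1e-12

#' Per-species and aggregate temporal statistics of a panel
#'
#' @param panel species x month numeric matrix (or a `monthly_panel`), T >= 2
#'   columns, non-negative entries.
#' @return list with per-species means `mu_i`, sample SDs `sigma_i`, CVs
#'   `cv_i` (0 when a species is constant), aggregate mean `mu_R` and SD
#'   `sigma_R` of the column-sum series, species count `n` and series length
#'   `T`.
#' @export
temporal_stats <- function(panel) {
  x <- panel_matrix(panel)
  if (ncol(x) < 2L) {
    stop_validation("need at least two time points", code = "too_short")
  }
  mu_i <- rowMeans(x)
  sigma_i <- apply(x, 1L, sd)
  total <- colSums(x)
  mu_R <- mean(total)
  sigma_R <- sd(total)
  scale0 <- max(mu_R, max(sigma_i))
  if (mu_R <= 0) {
    stop_degenerate("aggregate temporal mean is zero", code = "zero_mean")
  }
  if (max(sigma_i) <= REL_EPS * mu_R) {
    stop_degenerate("every species series is constant (all sigma_i = 0)",
                    code = "all_constant")
  }
  cv_i <- ifelse(mu_i > 0, sigma_i / mu_i, 0)
  list(mu_i = mu_i, sigma_i = sigma_i, cv_i = cv_i,
       mu_R = mu_R, sigma_R = sigma_R,
       n = nrow(x), T = ncol(x), scale = scale0)
}

#' Portfolio (aggregate) stability: inverse CV of a summed series
#'
#' @param total numeric series of monthly totals, length >= 2, positive mean.
#' @return `mean(total) / sd(total)` (dimensionless).
#' @export
portfolio_stability <- function(total) {
  if (length(total) < 2L) {
    stop_validation("need at least two time points", code = "too_short")
  }
  mu <- mean(total)
  sigma <- sd(total)
  if (mu <= 0) stop_degenerate("series mean is zero", code = "zero_mean")
  if (sigma <= REL_EPS * mu) {
    stop_degenerate("series is constant; stability is unbounded",
                    code = "zero_variance")
  }
  mu / sigma
}

#' Species-level stability: inverse weighted-average species variability
#'
#' The inverse of the abundance-weighted mean CV, algebraically
#' `mu_R / sum(sigma_i)`.  Species with zero SD contribute nothing to the
#' weighted average (but do contribute to `mu_R`).
#'
#' @param stats output of [temporal_stats()].
#' @return positive scalar.
#' @export
species_stability <- function(stats) {
  ssum <- sum(stats$sigma_i)
  if (ssum <= REL_EPS * stats$scale) {
    stop_degenerate("all species constant", code = "all_constant")
  }
  stats$mu_R / ssum
}

#' Asynchrony phi
#'
#' `sum(sigma_i) / sigma_R`; >= 1, equal to 1 under perfect synchrony.
#'
#' @param stats output of [temporal_stats()].
#' @return scalar >= 1.
#' @export
asynchrony <- function(stats) {
  if (stats$sigma_R <= REL_EPS * stats$scale) {
    stop_degenerate("aggregate series is constant (perfect compensation)",
                    code = "perfect_compensation")
  }
  sum(stats$sigma_i) / stats$sigma_R
}

#' Statistical averaging effect
#'
#' `sum(sigma_i) / sqrt(sum(sigma_i^2))`; in [1, sqrt(n)], maximal when
#' species variances are even, 1 when a single species carries all variance.
#'
#' @param stats output of [temporal_stats()].
#' @return scalar in `[1, sqrt(n)]`.
#' @export
sae <- function(stats) {
  ssum <- sum(stats$sigma_i)
  if (ssum <= REL_EPS * stats$scale) {
    stop_degenerate("all species constant", code = "all_constant")
  }
  ssum / sqrt(sum(stats$sigma_i^2))
}

#' Compensation effect
#'
#' `sqrt(sum(sigma_i^2)) / sigma_R`: the inverse square-rooted variance
#' ratio.  Values above 1 indicate more aggregate stability than independent
#' fluctuations would give (negative covariances); below 1, synchrony.
#'
#' @param stats output of [temporal_stats()].
#' @return positive scalar.
#' @export
cpe <- function(stats) {
  if (stats$sigma_R <= REL_EPS * stats$scale) {
    stop_degenerate("aggregate series is constant (perfect compensation)",
                    code = "perfect_compensation")
  }
  sqrt(sum(stats$sigma_i^2)) / stats$sigma_R
}

#' Partition within-year stability and asynchrony
#'
#' Computes all six quantities from one pass over the panel and verifies the
#' multiplicative identities `S_agg = phi * S_bar` and `phi = SAE * CPE`
#' to a relative 1e-10 before returning.
#'
#' @param panel species x month matrix or `monthly_panel` (one region-year).
#' @param layer label carried through to output, conventionally `"species"`
#'   for biomass panels or `"harvest"` for landings panels.
#' @return object of class `stability_partition` with elements `S_agg`,
#'   `S_bar`, `phi`, `SAE`, `CPE`, the `layer` label and the underlying
#'   `stats`.
#' @examples
#' x <- rbind(A = c(4, 6), B = c(5, 4))
#' colnames(x) <- c(1, 2)
#' partition_stability(x, layer = "harvest")
#' @export
partition_stability <- function(panel, layer = "species") {
  stats <- tryCatch(
    temporal_stats(panel),
    finstab_degeneracy_error = function(e) {
      e$message <- paste0("[layer ", layer, "] ", e$message)
      stop(e)
    }
  )
  out <- tryCatch({
    S_agg <- stats$mu_R / stats$sigma_R
    if (stats$sigma_R <= REL_EPS * stats$scale) {
      stop_degenerate("aggregate series is constant (perfect compensation)",
                      code = "perfect_compensation")
    }
    list(
      S_agg = S_agg,
      S_bar = species_stability(stats),
      phi = asynchrony(stats),
      SAE = sae(stats),
      CPE = cpe(stats)
    )
  }, finstab_degeneracy_error = function(e) {
    e$message <- paste0("[layer ", layer, "] ", e$message)
    stop(e)
  })
  rel <- function(a, b) abs(a - b) / abs(a)
  if (rel(out$S_agg, out$phi * out$S_bar) > 1e-10 ||
      rel(out$phi, out$SAE * out$CPE) > 1e-10) {
    stop_degenerate("multiplicative identities violated beyond 1e-10; panel ill-conditioned",
                    code = "identity_violation")
  }
  structure(c(out, list(layer = layer, stats = stats)),
            class = "stability_partition")
}

#' @export
print.stability_partition <- function(x, digits = 4L, ...) {
  cat("Within-year stability-asynchrony partition (layer: ", x$layer, ")\n",
      sep = "")
  cat("  n = ", x$stats$n, " species, T = ", x$stats$T, " months\n", sep = "")
  v <- c(S_agg = x$S_agg, S_bar = x$S_bar, phi = x$phi,
         SAE = x$SAE, CPE = x$CPE)
  print(round(v, digits))
  cat("  identities: S_agg = phi * S_bar;  phi = SAE * CPE\n")
  invisible(x)
}

#' @export
as.data.frame.stability_partition <- function(x, ...) {
  data.frame(layer = x$layer, S_agg = x$S_agg, S_bar = x$S_bar,
             phi = x$phi, SAE = x$SAE, CPE = x$CPE,
             n = x$stats$n, T = x$stats$T, stringsAsFactors = FALSE)
}

#' Batch partitioning over region-years
#'
#' Builds one panel per (region, year) for the given quantity kind, runs
#' [partition_stability()] on each, and collects the results.  Degenerate
#' region-years are kept as rows of `NA` with the degeneracy code in
#' `degenerate_flag` rather than aborting the batch.
#'
#' @param records validated long records.
#' @param quantity_kind which measured quantity to partition
#'   (`"biomass_kg"` for the species layer, `"harvest_kg"` for harvests).
#' @param layer layer label stored in the output.
#' @param months months used for every panel (default: the five survey
#'   months); species and harvest layers should be computed on the same
#'   month grid so their asynchronies are comparable.
#' @param species optional fixed species set.
#' @return data frame with columns `layer`, `region`, `year`, `S_agg`,
#'   `S_bar`, `phi`, `SAE`, `CPE`, `n`, `T`, `degenerate_flag`.
#' @export
partition_by_year <- function(records, quantity_kind, layer,
                              months = DEFAULT_SURVEY_MONTHS,
                              species = NULL) {
  records <- validate_long(records)
  sub <- records[records$quantity_kind == quantity_kind, , drop = FALSE]
  keys <- unique(sub[c("region", "year")])
  keys <- keys[order(keys$region, keys$year), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    reg <- keys$region[i]; yr <- keys$year[i]
    base <- data.frame(layer = layer, region = reg, year = yr,
                       S_agg = NA_real_, S_bar = NA_real_, phi = NA_real_,
                       SAE = NA_real_, CPE = NA_real_,
                       n = NA_integer_, T = NA_integer_,
                       degenerate_flag = "", stringsAsFactors = FALSE)
    tryCatch({
      p <- to_panel(sub, reg, yr, quantity_kind,
                    months = months, species = species)
      d <- partition_stability(p, layer = layer)
      base[c("S_agg", "S_bar", "phi", "SAE", "CPE")] <-
        list(d$S_agg, d$S_bar, d$phi, d$SAE, d$CPE)
      base$n <- d$stats$n; base$T <- d$stats$T
      base
    }, finstab_degeneracy_error = function(e) {
      # statistical degeneracies become flagged missing cells; a missing
      # data cell is not a statistic and still aborts
      if (identical(condition_code(e), "incomplete_panel")) stop(e)
      base$degenerate_flag <- condition_code(e)
      base
    })
  })
  do.call(rbind, rows)
}
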