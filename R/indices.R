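# Annual harvest-portfolio indicators.
#
# All indices are computed per region-year.  The seasonal harvest ratio
# (SHR) measures diversification into alternative stocks while the dominant
# fishery is closed; harvest timing is the harvest-weighted mean month;
# the effort index averages per-species trip totals over the survey months;
# portfolio yield/value are annual sums; the short and long portfolio
# stabilities are inverse CVs of monthly totals over survey months and over
# all 12 months.

#' Seasonal harvest ratio (SHR)
#'
#' Ratio of the mean monthly total harvest (summed across species) during
#' the closure window to the mean monthly total harvest outside it.  Only
#' months overlapping the survey enter either side, so with the default
#' survey months and a March-May closure the numerator months are {3, 5}
#' and the denominator months {7, 9, 11} (April, closed but unsurveyed, is
#' excluded).
#'
#' @param panel harvest `monthly_panel` (or species x month matrix with
#'   month numbers as column names) covering the survey months.
#' @param closure integer months of the focal fishery closure.
#' @param survey_months survey months defining the usable season.
#' @return scalar >= 0.
#' @export
seasonal_harvest_ratio <- function(panel, closure,
                                   survey_months = DEFAULT_SURVEY_MONTHS) {
  x <- panel_matrix(panel)
  months <- if (inherits(panel, "monthly_panel")) panel$months
            else as.integer(colnames(x))
  total <- colSums(x)
  num_m <- intersect(survey_months, closure)
  den_m <- setdiff(survey_months, closure)
  if (!length(num_m) || !length(den_m)) {
    stop_validation("closure must split the survey months into two non-empty sets",
                    code = "bad_closure_split")
  }
  if (!all(c(num_m, den_m) %in% months)) {
    stop_validation("panel does not cover all survey months",
                    code = "missing_months")
  }
  den <- mean(total[match(den_m, months)])
  if (den <= 0) {
    stop_degenerate("no harvest outside the closure window", code = "zero_open_harvest")
  }
  mean(total[match(num_m, months)]) / den
}

#' Harvest-weighted mean month of harvest
#'
#' @param harvest numeric vector of monthly harvests for one species-year.
#' @param months month numbers aligned with `harvest` (default: all 12; pass
#'   the survey months for the survey-resolution variant).
#' @return real in `[min(months), max(months)]`.
#' @export
mean_harvest_month <- function(harvest, months = seq_along(harvest)) {
  stopifnot(length(harvest) == length(months))
  tot <- sum(harvest)
  if (tot <= 0) {
    stop_degenerate("zero total harvest; timing undefined",
                    code = "undefined_timing")
  }
  sum(months * harvest) / tot
}

#' Annual fishing-effort index
#'
#' Sums trips per species over the survey months, then averages the totals
#' across species (unweighted).  The alternative of averaging the monthly
#' trip counts is available via `method = "monthly_mean"`.
#'
#' @param panel trips `monthly_panel` (or matrix with month column names)
#'   restricted to the portfolio species.
#' @param survey_months months over which trips are accumulated.
#' @param method `"species_totals"` (default) or `"monthly_mean"`.
#' @return scalar; `NA` with a warning when no trip data are present.
#' @export
effort_index <- function(panel, survey_months = DEFAULT_SURVEY_MONTHS,
                         method = c("species_totals", "monthly_mean")) {
  method <- match.arg(method)
  x <- panel_matrix(panel)
  months <- if (inherits(panel, "monthly_panel")) panel$months
            else as.integer(colnames(x))
  keep <- months %in% survey_months
  if (!any(keep)) {
    warning("no trip data in survey months; effort index is NA")
    return(NA_real_)
  }
  sub <- x[, keep, drop = FALSE]
  if (method == "species_totals") mean(rowSums(sub)) else mean(colMeans(sub))
}

#' Annual portfolio totals
#'
#' @param harvest_panel,value_panel 12-month panels of harvest mass and
#'   (real) dockside value.
#' @return named vector `c(yield = kg, value = USD)`, summed across species
#'   and months.
#' @export
portfolio_totals <- function(harvest_panel, value_panel) {
  c(yield = sum(panel_matrix(harvest_panel)),
    value = sum(panel_matrix(value_panel)))
}

#' Short- and long-window portfolio harvest stability
#'
#' Inverse CV of the monthly total harvest over the survey months
#' (`S_portfolio_S`) and over all 12 months (`S_portfolio_L`).
#'
#' @param panel 12-month harvest `monthly_panel` or matrix with month
#'   column names.
#' @param survey_months the short window.
#' @return named vector `c(S_portfolio_S = , S_portfolio_L = )`.
#' @export
portfolio_stability_short_long <- function(panel,
                                           survey_months = DEFAULT_SURVEY_MONTHS) {
  x <- panel_matrix(panel)
  months <- if (inherits(panel, "monthly_panel")) panel$months
            else as.integer(colnames(x))
  total <- colSums(x)
  c(S_portfolio_S = portfolio_stability(total[months %in% survey_months]),
    S_portfolio_L = portfolio_stability(total))
}

#' Portfolio value stability
#'
#' Inverse CV of the summed monthly harvest value over all 12 months.
#'
#' @param value_panel 12-month value panel.
#' @return positive scalar.
#' @export
value_stability <- function(value_panel) {
  portfolio_stability(colSums(panel_matrix(value_panel)))
}

#' Select the species making up the top 90% of cumulative yield
#'
#' Ranks species by total multi-year yield (descending, ties broken
#' alphabetically), accumulates shares, and keeps species through the first
#' one at which the cumulative share reaches the threshold (the crossing
#' species is included).
#'
#' @param yields named numeric vector of per-species summed yields.
#' @param threshold cumulative-share cutoff (default 0.90).
#' @return character vector of selected species, in rank order.
#' @export
select_top_species <- function(yields, threshold = 0.90) {
  stopifnot(!is.null(names(yields)), all(yields >= 0))
  tot <- sum(yields)
  if (tot <= 0) stop_degenerate("all yields zero", code = "zero_yield")
  ord <- order(-yields, names(yields))
  cum_share <- cumsum(yields[ord]) / tot
  k <- which(cum_share >= threshold - 1e-12)[1L]
  names(yields)[ord][seq_len(k)]
}

#' Annual indicator table for one region
#'
#' Computes, for every year with data, the full set of portfolio
#' indicators: SHR (when a closure is defined for the region), effort
#' index, portfolio yield and value, short/long portfolio harvest
#' stability, value stability, and per-species harvest timing (wide
#' columns `timing_<species>`).  Degenerate cells are `NA` with the
#' degeneracy code accumulated in `flags`.
#'
#' @param records validated long records for (at least) one region,
#'   containing `harvest_kg` and optionally `value_usd` and `trips` kinds.
#' @param region region label.
#' @param calendar a `closure_calendar`; its survey months define the short
#'   windows and the SHR/effort month sets.
#' @param species portfolio species (default: [select_top_species()] on the
#'   region's multi-year harvest totals).
#' @param shr_species species whose closure defines the SHR window
#'   (default: the region's closed species with the longest closure, if
#'   any).
#' @param timing_months months used for the harvest-timing index (default
#'   all 12; pass `calendar$survey_months` for the survey-resolution
#'   variant).
#' @return data frame, one row per year.
#' @export
annual_indicators <- function(records, region, calendar = default_calendar(),
                              species = NULL, shr_species = NULL,
                              timing_months = 1:12) {
  records <- validate_long(records)
  records <- records[records$region == region, , drop = FALSE]
  if (!nrow(records)) stop_validation(paste0("no records for region ", region))
  surv <- calendar$survey_months

  harv <- records[records$quantity_kind == "harvest_kg", , drop = FALSE]
  if (is.null(species)) {
    totals <- tapply(harv$value, harv$species, sum)
    species <- select_top_species(setNames(as.numeric(totals), names(totals)))
    species <- sort(species)
  }
  if (is.null(shr_species)) {
    # a usable SHR closure must split the survey months into non-empty
    # closed and open sets; among qualifying species take the one whose
    # closure overlaps the most survey months
    overlap <- vapply(species, function(sp) {
      cm <- closed_months(calendar, region, sp)
      if (length(intersect(surv, cm)) && length(setdiff(surv, cm)))
        length(intersect(surv, cm)) else 0L
    }, integer(1L))
    if (any(overlap > 0L)) shr_species <- species[which.max(overlap)]
  }
  closure <- if (is.null(shr_species)) integer(0)
             else closed_months(calendar, region, shr_species)

  years <- sort(unique(harv$year))
  rows <- lapply(years, function(yr) {
    flags <- character(0)
    note <- function(code) flags <<- c(flags, code)
    grab <- function(expr) tryCatch(expr, finstab_degeneracy_error = function(e) {
      note(condition_code(e)); NA_real_
    })
    h12 <- tryCatch(
      to_panel(records, region, yr, "harvest_kg", months = 1:12,
               species = species),
      finstab_degeneracy_error = function(e) { note(condition_code(e)); NULL })
    v12 <- tryCatch(
      to_panel(records, region, yr, "value_usd", months = 1:12,
               species = species),
      error = function(e) NULL)
    t_p <- tryCatch(
      to_panel(records, region, yr, "trips", months = surv,
               species = species),
      error = function(e) NULL)

    shr <- s_s <- s_l <- vs <- eff <- yield <- val <- NA_real_
    timing <- setNames(rep(NA_real_, length(species)),
                       paste0("timing_", species))
    if (!is.null(h12)) {
      if (length(closure)) {
        shr <- grab(seasonal_harvest_ratio(h12, closure, surv))
      }
      ssl <- c(S_portfolio_S = grab(portfolio_stability(
                 colSums(h12$x[, h12$months %in% surv, drop = FALSE]))),
               S_portfolio_L = grab(portfolio_stability(colSums(h12$x))))
      s_s <- ssl[[1L]]; s_l <- ssl[[2L]]
      yield <- sum(h12$x)
      for (sp in species) {
        cols <- h12$months %in% timing_months
        timing[paste0("timing_", sp)] <- tryCatch(
          mean_harvest_month(h12$x[sp, cols], h12$months[cols]),
          finstab_degeneracy_error = function(e) { note("undefined_timing"); NA_real_ })
      }
    }
    if (!is.null(v12)) {
      vs <- grab(value_stability(v12))
      val <- sum(v12$x)
    }
    if (!is.null(t_p)) {
      eff <- effort_index(t_p, surv)
    } else {
      note("no_trip_data")
    }
    cbind(
      data.frame(region = region, year = yr, shr = shr,
                 effort_index = eff, portfolio_yield = yield,
                 portfolio_value = val, s_portfolio_s = s_s,
                 s_portfolio_l = s_l, value_stability = vs,
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(timing)),
      data.frame(flags = paste(unique(flags), collapse = ";"),
                 stringsAsFactors = FALSE)
    )
  })
  do.call(rbind, rows)
}
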