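# Synthetic demersal-finfish scenario generator.
#
# Emulates a Chesapeake-like system: a handful of seasonally migrating
# species observed by a five-cruise stratified trawl survey over 17 years,
# with commercial harvests produced by effort that switches among open
# species and is masked by seasonal closures.  Observation noise on trawl
# catches is compound Poisson-gamma (Tweedie, 1 < p < 2), giving the
# positive, right-skewed, zero-inflated catches characteristic of trawl
# data.

#' Simulate compound Poisson-gamma (Tweedie) deviates
#'
#' Exact simulation by its compound representation: a Poisson number
#' `N` of gamma summands, with `lambda = mu^(2-p) / (phi * (2-p))`,
#' gamma shape `alpha = (2-p)/(p-1)` and scale `theta =
#' phi * (p-1) * mu^(p-1)`, so that the mean is `mu` and the variance
#' `phi * mu^p`.
#'
#' @param n number of draws.
#' @param mu mean (>= 0; zero means give zero draws).
#' @param p power parameter in (1, 2).
#' @param phi dispersion (> 0).
#' @return numeric vector of non-negative draws.
#' @examples
#' set.seed(3)
#' x <- rtweedie_cpg(1000, mu = 5, p = 1.5, phi = 2)
#' c(mean = mean(x), var = var(x), zeros = mean(x == 0))
#' @export
rtweedie_cpg <- function(n, mu, p, phi) {
  stopifnot(p > 1, p < 2, phi > 0, all(mu >= 0))
  mu <- rep_len(mu, n)
  out <- numeric(n)
  pos <- mu > 0
  if (any(pos)) {
    lambda <- mu[pos]^(2 - p) / (phi * (2 - p))
    alpha <- (2 - p) / (p - 1)
    theta <- phi * (p - 1) * mu[pos]^(p - 1)
    N <- rpois(sum(pos), lambda)
    draw <- numeric(sum(pos))
    nz <- N > 0
    # sum of N iid gamma(alpha, theta) is gamma(N * alpha, theta)
    draw[nz] <- rgamma(sum(nz), shape = N[nz] * alpha, scale = theta[nz])
    out[pos] <- draw
  }
  out
}

#' Construct a synthetic scenario configuration
#'
#' @param region region label.
#' @param years number of years (default 17, mirroring a 2002-2018-style
#'   series).
#' @param species data frame with one row per species and columns `name`,
#'   `baseline` (kg, annual-mean biomass), `amplitude` (seasonal relative
#'   amplitude in `[0, 1)`), `phase` (month offset of the seasonal
#'   sinusoid), `trend` (multiplicative per-year factor > 0),
#'   `catchability` (per-trip), `price` (USD/kg).
#' @param year_sd SD of the per-species-year lognormal biomass deviation
#'   (interannual "good year / bad year" variation shared by survey and
#'   fishery).
#' @param year_cor squared loading of the shared annual environmental
#'   factor in the species' log year effects (0 = independent years across
#'   species); per-species loadings can be modulated by an optional
#'   `year_loading` column in `species` (e.g., 0 for a coastal migratory
#'   stock whose dynamics are set outside the estuary).
#' @param phase_jitter_sd SD (months) of per-species-year jitter in
#'   seasonal timing.
#' @param tweedie_p,tweedie_phi Tweedie power and dispersion of trawl
#'   catches.
#' @param base_effort baseline total trips per month.
#' @param elasticity effort-switching elasticity: monthly effort shares are
#'   proportional to `(catchability * biomass * price)^elasticity` among
#'   open species (0 = fixed equal shares; large = winner-take-all).
#' @param effort_power exponent tying total monthly effort to currently
#'   open biomass (0 = constant effort; 0.5 = effort declines as the
#'   resource does).
#' @param obs_sd SD of the multiplicative lognormal observation noise on
#'   monthly harvests (right-skewed, mean-one).
#' @param trips_jitter_sd SD of the lognormal jitter on trip counts.
#' @param calendar a `closure_calendar`.
#' @param stratum_areas named stratum areas (km^2).
#' @param hauls_per_stratum trawl hauls per stratum per survey month.
#' @param swept_km2 area swept by one haul (km^2).
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(region, species, years = 17L,
                            year_sd = 0.35, year_cor = 0.5,
                            phase_jitter_sd = 0.75,
                            tweedie_p = 1.5, tweedie_phi = 2,
                            base_effort = 300, elasticity = 1,
                            effort_power = 0.5, obs_sd = 0.25,
                            trips_jitter_sd = 0.15,
                            calendar = default_calendar(),
                            stratum_areas = c(`1` = 400, `2` = 300, `3` = 200),
                            hauls_per_stratum = 10L, swept_km2 = 0.012) {
  stopifnot(is.data.frame(species),
            all(c("name", "baseline", "amplitude", "phase", "trend",
                  "catchability", "price") %in% names(species)))
  if (any(species$amplitude < 0 | species$amplitude >= 1)) {
    stop_validation("amplitudes must lie in [0, 1)", code = "bad_amplitude")
  }
  if (any(species$trend <= 0)) {
    stop_validation("trend factors must be positive", code = "bad_trend")
  }
  if (tweedie_p <= 1 || tweedie_p >= 2 || tweedie_phi <= 0) {
    stop_validation("need 1 < p < 2 and dispersion > 0", code = "bad_tweedie")
  }
  if (any(species$price < 0)) {
    stop_validation("prices must be non-negative", code = "bad_price")
  }
  structure(list(
    region = region, years = as.integer(years), species = species,
    year_sd = year_sd, year_cor = year_cor,
    phase_jitter_sd = phase_jitter_sd,
    tweedie_p = tweedie_p, tweedie_phi = tweedie_phi,
    base_effort = base_effort, elasticity = elasticity,
    effort_power = effort_power, obs_sd = obs_sd,
    trips_jitter_sd = trips_jitter_sd, calendar = calendar,
    stratum_areas = stratum_areas,
    hauls_per_stratum = as.integer(hauls_per_stratum),
    swept_km2 = swept_km2
  ), class = "scenario_config")
}

#' Per-year trend factor matching a target period-on-period decline
#'
#' Solves for the multiplicative per-year factor `r` such that the mean of
#' `r^(y-1)` over years `split+1 .. years`, relative to its mean over years
#' `1 .. split`, equals `1 - decline` (e.g., `decline = 0.92` for a 92%
#' decline between the first and second halves of the record).
#'
#' @param decline fractional decline between period means, in (-Inf, 1).
#' @param years total years (default 17).
#' @param split last year of the first period (default 9, i.e., a
#'   2002-2010 vs 2011-2018 style split).
#' @return scalar trend factor.
#' @export
decline_to_trend <- function(decline, years = 17L, split = 9L) {
  stopifnot(decline < 1, split >= 1, split < years)
  target <- 1 - decline
  f <- function(r) {
    g <- r^(0:(years - 1L))
    mean(g[(split + 1L):years]) / mean(g[1:split]) - target
  }
  uniroot(f, c(1e-4, 10), tol = 1e-12)$root
}

#' Draw interannual year effects for a scenario
#'
#' Mean-one lognormal per-species-year biomass multipliers and Gaussian
#' per-species-year shifts of seasonal timing.  A shared annual factor
#' (environmental covariation: recruitment and estuarine conditions common
#' to resident species) enters each species' log-multiplier with loading
#' `sqrt(year_cor) * year_loading[i]`, the remainder being species-specific;
#' total log-variance is `year_sd^2` for every species.  Uses the current
#' RNG state.
#'
#' @param config a `scenario_config`.
#' @return list with matrices `mult` and `phase_shift`
#'   (species x years).
#' @export
gen_year_effects <- function(config) {
  ns <- nrow(config$species); ny <- config$years
  s <- config$year_sd
  load <- config$species$year_loading %||% rep(1, ns)
  a <- sqrt(config$year_cor) * load           # shared-factor loading
  z_common <- rnorm(ny)
  z_own <- matrix(rnorm(ns * ny), ns, ny)
  logm <- s * (outer(a, z_common) + sqrt(1 - a^2) * z_own) - s^2 / 2
  mult <- exp(logm)
  shift <- matrix(rnorm(ns * ny, 0, config$phase_jitter_sd), ns, ny)
  dimnames(mult) <- dimnames(shift) <- list(config$species$name, NULL)
  list(mult = mult, phase_shift = shift)
}

#' Generate true monthly community biomass
#'
#' Deterministic seasonal-sinusoid mean structure,
#' `baseline * trend^(year-1) * (1 + amplitude * sin(2*pi*(month - phase)/12))`,
#' truncated at zero; optional stochastic year effects (from
#' [gen_year_effects()]) multiply the level and shift the phase.
#'
#' @param config a `scenario_config`.
#' @param year_effects optional output of [gen_year_effects()]; `NULL`
#'   gives the deterministic mean field.
#' @return numeric array `[species, month (1..12), year]` of biomass (kg).
#' @export
gen_community <- function(config, year_effects = NULL) {
  sp <- config$species
  ns <- nrow(sp); ny <- config$years
  B <- array(0, dim = c(ns, 12L, ny),
             dimnames = list(sp$name, 1:12, NULL))
  for (i in seq_len(ns)) {
    for (y in seq_len(ny)) {
      mult <- 1; shift <- 0
      if (!is.null(year_effects)) {
        mult <- year_effects$mult[i, y]
        shift <- year_effects$phase_shift[i, y]
      }
      seas <- 1 + sp$amplitude[i] *
        sin(2 * pi * ((1:12) - sp$phase[i] - shift) / 12)
      B[i, , y] <- pmax(0, sp$baseline[i] * sp$trend[i]^(y - 1L) * mult * seas)
    }
  }
  B
}

#' Simulate a stratified trawl survey of the community
#'
#' Density is taken as uniform within the region (biomass / total stratum
#' area); each haul's catch is compound Poisson-gamma with mean
#' `density * swept area`.  Uses the current RNG state.
#'
#' @param biomass array from [gen_community()].
#' @param config the `scenario_config`.
#' @param start_year calendar year of year 1 (default 2002).
#' @return data frame of `TrawlRecord` rows: `station`, `x`, `y`,
#'   `stratum`, `year`, `month`, `species`, `catch_kg`, `swept_km2`.
#' @export
gen_trawl_survey <- function(biomass, config, start_year = 2002L) {
  areas <- config$stratum_areas
  total_area <- sum(areas)
  months <- config$calendar$survey_months
  ns <- dim(biomass)[1L]; ny <- dim(biomass)[3L]
  nh <- config$hauls_per_stratum
  rows <- vector("list", ny * length(months))
  k <- 0L; station <- 0L
  for (y in seq_len(ny)) {
    for (m in months) {
      haul_s <- rep(names(areas), each = nh)
      xs <- runif(length(haul_s), 0, sqrt(total_area))
      ys <- runif(length(haul_s), 0, sqrt(total_area))
      st <- station + seq_along(haul_s)
      station <- station + length(haul_s)
      per_sp <- lapply(seq_len(ns), function(i) {
        dens <- biomass[i, m, y] / total_area
        catch <- rtweedie_cpg(length(haul_s), dens * config$swept_km2,
                              config$tweedie_p, config$tweedie_phi)
        data.frame(station = st, x = xs, y = ys, stratum = haul_s,
                   year = start_year + y - 1L, month = m,
                   species = dimnames(biomass)[[1L]][i],
                   catch_kg = catch, swept_km2 = config$swept_km2,
                   stringsAsFactors = FALSE)
      })
      k <- k + 1L
      rows[[k]] <- do.call(rbind, per_sp)
    }
  }
  do.call(rbind, rows)
}

#' Generate monthly harvests, values and trips from biomass and effort
#'
#' Monthly total effort is `base_effort * (open biomass / reference
#' biomass)^effort_power`; it is shared among open species in proportion to
#' `(catchability * biomass * price)^elasticity` (closed species-months get
#' zero harvest and zero targeted trips; a month with every species closed
#' is a valid zero-harvest month).  Harvest is `catchability * share *
#' effort * biomass` times mean-one lognormal observation noise; value is
#' harvest times price; trips are the rounded species share of effort with
#' lognormal jitter.  Uses the current RNG state.
#'
#' @param biomass array from [gen_community()].
#' @param config the `scenario_config`.
#' @param start_year calendar year of year 1 (default 2002).
#' @return validated long records with kinds `harvest_kg`, `value_usd`,
#'   `trips` (explicit zeros for closed species-months).
#' @export
gen_harvest <- function(biomass, config, start_year = 2002L) {
  sp <- config$species
  ns <- nrow(sp); ny <- dim(biomass)[3L]
  B_ref <- sum(sp$baseline)
  closed <- vapply(sp$name, function(s) {
    cm <- closed_months(config$calendar, config$region, s)
    (1:12) %in% cm
  }, logical(12L))                      # 12 x ns
  out <- vector("list", ny)
  for (y in seq_len(ny)) {
    harvest <- value <- trips <- matrix(0, ns, 12L)
    for (m in 1:12) {
      open <- !closed[m, ]
      if (!any(open)) next
      b <- biomass[, m, y]
      E_m <- config$base_effort * (sum(b[open]) / B_ref)^config$effort_power
      w <- (sp$catchability * b * sp$price)^config$elasticity
      w[!open] <- 0
      if (sum(w) <= 0) next
      share <- w / sum(w)
      noise <- exp(rnorm(ns, -config$obs_sd^2 / 2, config$obs_sd))
      harvest[, m] <- sp$catchability * share * E_m * b * noise
      value[, m] <- harvest[, m] * sp$price
      jit <- exp(rnorm(ns, -config$trips_jitter_sd^2 / 2,
                       config$trips_jitter_sd))
      trips[, m] <- round(share * E_m * jit)
    }
    yr <- start_year + y - 1L
    grid <- expand.grid(species = sp$name, month = 1:12,
                        stringsAsFactors = FALSE)
    out[[y]] <- data.frame(
      region = config$region, year = yr,
      month = rep(grid$month, 3L), species = rep(grid$species, 3L),
      quantity_kind = rep(c("harvest_kg", "value_usd", "trips"),
                          each = nrow(grid)),
      value = c(as.vector(harvest), as.vector(value), as.vector(trips)),
      stringsAsFactors = FALSE
    )
  }
  validate_long(do.call(rbind, out))
}

#' Calibrate per-species catchabilities to target annual harvests
#'
#' With effort shares proportional to `(q * B * price)^elasticity`, the
#' expected annual harvest of species i scales as
#' `(q_i B_i)^(1+elasticity) * price_i^elasticity`.  Given baseline
#' biomasses and target annual harvests (e.g., the observed landings the
#' scenario should echo), this inverts that relationship and rescales so
#' the implied total annual harvest at baseline matches the target total.
#'
#' @param baseline per-species mean biomass (kg).
#' @param price per-species price (USD/kg).
#' @param target per-species target annual harvest (kg).
#' @param elasticity effort-switching elasticity.
#' @param base_effort baseline trips per month.
#' @return numeric vector of catchabilities (per trip).
#' @export
calibrate_catchability <- function(baseline, price, target, elasticity,
                                   base_effort = 300) {
  stopifnot(all(baseline > 0), all(target > 0))
  a <- (target / price^elasticity)^(1 / (1 + elasticity))
  q <- a / baseline
  w <- (q * baseline * price)^elasticity
  share <- w / sum(w)
  implied <- sum(q * share * base_effort * baseline) * 12
  q * sum(target) / implied
}

#' Named scenario presets
#'
#' * `synchronous_null`: two species with identical seasonal phase; no
#'   closure (all-synchronous baseline).
#' * `va_compensation`: three species (croaker-, spot-, striped-bass-like)
#'   with dispersed seasonal phases and the southern-region winter
#'   closures; compensatory within-year dynamics.
#' * `md_closure`: five species with a dominant striped-bass-like stock
#'   closed March-May, forcing effort switching to alternatives during the
#'   closure.
#' * `va_decline`: `va_compensation` overlaid with interannual declines of
#'   92%, 77% and 51% (period means, years 1-9 vs 10-17) concentrated in
#'   the dominant species.
#'
#' Baselines and prices echo the magnitudes of real mid-Atlantic mainstem
#' landings (dominant stock of order 1e6 kg/yr); amplitudes of 0.55-0.7
#' reflect strong seasonal migration.
#'
#' @param name preset name.
#' @return a `scenario_config`.
#' @export
scenario_preset <- function(name = c("md_closure", "va_compensation",
                                     "va_decline", "synchronous_null")) {
  name <- match.arg(name)
  elast <- 0.5
  # Southern region: croaker-dominated biomass, landings echoing observed
  # annual magnitudes; croaker peaks in late spring/summer, spot and
  # striped bass in autumn/winter (6-month phase offset -> compensation).
  va_species <- data.frame(
    name = c("atlantic_croaker", "spot", "striped_bass"),
    baseline = c(8e6, 1.5e6, 8e5),
    amplitude = c(0.65, 0.65, 0.65),
    phase = c(3, 8, 8),
    trend = c(1, 1, 1),
    catchability = NA_real_,
    price = c(1.49, 2.22, 5.12),
    stringsAsFactors = FALSE
  )
  va_species$catchability <- calibrate_catchability(
    va_species$baseline, va_species$price,
    target = c(1489750, 554203, 304782), elasticity = elast
  )
  md_species <- data.frame(
    name = c("striped_bass", "white_perch", "atlantic_croaker",
             "channel_catfish", "gizzard_shad"),
    baseline = c(1.5e6, 1.2e6, 5e5, 4e5, 6e5),
    amplitude = c(0.55, 0.6, 0.7, 0.5, 0.6),
    phase = c(9, 3, 5, 6, 3),
    trend = 1,
    catchability = NA_real_,
    price = c(5.47, 1.64, 1.37, 1.22, 0.32),
    year_loading = c(0, 1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
  md_species$catchability <- calibrate_catchability(
    md_species$baseline, md_species$price,
    target = c(554372, 162971, 77677, 87480, 54250), elasticity = elast
  )
  switch(name,
    synchronous_null = scenario_config(
      region = "XX",
      species = data.frame(
        name = c("species_a", "species_b"),
        baseline = c(500000, 400000), amplitude = 0.6, phase = c(6, 6),
        trend = 1, catchability = 5e-5, price = c(2, 2),
        stringsAsFactors = FALSE
      ),
      elasticity = elast,
      calendar = closure_calendar(NULL)
    ),
    va_compensation = scenario_config(region = "VA", species = va_species,
                                      elasticity = elast),
    va_decline = {
      sp <- va_species
      sp$trend <- vapply(c(0.92, 0.77, 0.51), decline_to_trend, numeric(1L))
      scenario_config(region = "VA", species = sp, elasticity = elast)
    },
    md_closure = scenario_config(region = "MD", species = md_species,
                                 elasticity = elast)
  )
}

#' Simulate a complete scenario dataset
#'
#' Seeds the RNG, draws year effects, builds the true biomass field, the
#' trawl survey and the fishery records, and estimates design-based
#' biomass indices from the survey.  Pure function of `(config, seed)`:
#' identical inputs give bit-identical outputs.
#'
#' @param config a `scenario_config` (or preset name).
#' @param seed integer RNG seed.
#' @param start_year calendar year of year 1 (default 2002).
#' @return list with `config`, `biomass` (true array), `hauls`,
#'   `indices` (design-based `BiomassIndex` rows), and `records` (long
#'   records combining the fishery kinds with the estimated
#'   `biomass_kg` indices).
#' @export
simulate_scenario <- function(config, seed, start_year = 2002L) {
  if (is.character(config)) config <- scenario_preset(config)
  stopifnot(inherits(config, "scenario_config"))
  set.seed(as.integer(seed))
  ye <- gen_year_effects(config)
  biomass <- gen_community(config, ye)
  hauls <- gen_trawl_survey(biomass, config, start_year)
  fishery <- gen_harvest(biomass, config, start_year)
  idx <- survey_biomass_index(hauls, config$stratum_areas,
                              region = config$region)
  records <- rbind(fishery, index_to_long(idx))
  list(config = config, biomass = biomass, hauls = hauls,
       indices = idx, records = validate_long(records))
}
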