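#' Site configuration for the isotope chain
#'
#' Holds the geographic and atmospheric parameters the climate
#' reconstructions need. The atmospheric correction `corr` applied to
#' enamel-derived diet values is the difference between the paleo-atmosphere
#' delta-13C of CO2 and the modern (post-1930) reference of -8 permil; for an
#' Aquitanian site with a reconstructed paleo-atmosphere of -6.1 permil this
#' gives corr = 1.9 permil.
#'
#' @param latitude_deg Site latitude in decimal degrees (absolute value is
#'   used by the precipitation equation).
#' @param altitude_m Site altitude in m above sea level.
#' @param d13C_atm_paleo Paleo-atmospheric delta-13C of CO2, permil VPDB.
#' @param d13C_atm_modern Modern reference atmospheric delta-13C, permil VPDB.
#' @param lifespan_years Conventional lifespan for age-class scaling.
#' @return List of class `site_config` including the derived `corr`.
#' @export
site_config <- function(latitude_deg, altitude_m,
                        d13C_atm_paleo = -6.1, d13C_atm_modern = -8,
                        lifespan_years = 40) {
  stopifnot(is.numeric(latitude_deg), abs(latitude_deg) <= 90,
            is.numeric(altitude_m), is.finite(altitude_m))
  structure(
    list(latitude_deg = latitude_deg, altitude_m = altitude_m,
         d13C_atm_paleo = d13C_atm_paleo, d13C_atm_modern = d13C_atm_modern,
         corr = d13C_atm_paleo - d13C_atm_modern,
         lifespan_years = lifespan_years),
    class = "site_config"
  )
}

#' Diet-bioapatite carbon enrichment factor
#'
#' Body-mass-dependent enrichment between diet and enamel carbonate for
#' herbivorous mammals: `epsilon* = exp(2.42 + 0.032 * ln(mass_kg))` permil.
#' Larger animals (longer gut retention) show a larger enrichment.
#'
#' @param mass_kg Body mass in kilograms, > 0.
#' @return Enrichment in permil; strictly increasing in mass.
#' @examples
#' epsilon_star(1)       # 11.25 permil
#' epsilon_star(532.53)  # 13.75 permil
#' @export
epsilon_star <- function(mass_kg) {
  if (any(!is.finite(mass_kg)) || any(mass_kg <= 0)) {
    stop("mass_kg must be finite and > 0", call. = FALSE)
  }
  exp(2.42 + 0.032 * log(mass_kg))
}

#' Diet delta-13C from enamel carbonate
#'
#' `d13C_diet = d13C_enamel - epsilon*(mass) - corr`, where `corr` is the
#' atmospheric delta-13C correction held by the site configuration.
#'
#' @param d13C_enamel Enamel carbonate delta-13C, permil VPDB.
#' @param mass_kg Body mass (kg) feeding the enrichment factor.
#' @param config A [site_config()].
#' @return Diet delta-13C in permil VPDB.
#' @export
d13c_diet <- function(d13C_enamel, mass_kg, config) {
  stopifnot(inherits(config, "site_config"))
  d13C_enamel - epsilon_star(mass_kg) - config$corr
}

#' Mean annual precipitation from diet delta-13C
#'
#' Inverts the aridity relation of C3 plant delta-13C (Kohn 2010) at the
#' site's latitude and altitude:
#' `MAP = 10^((-d13C_diet - 10.29 - 0.0124*|lat| + 1.9e-4*alt)/5.61) - 300`
#' mm/yr. The inversion can legitimately return negative values when the
#' diet signal is heavier than the local C3 baseline (e.g. canopy-free
#' habitats or within-locality plant variation); negative results are
#' returned as-is so callers can flag rather than clamp them.
#'
#' @param d13C_diet Diet delta-13C, permil VPDB.
#' @param config A [site_config()].
#' @return MAP in mm/yr (possibly negative); strictly decreasing in
#'   `d13C_diet`.
#' @export
map_from_diet <- function(d13C_diet, config) {
  stopifnot(inherits(config, "site_config"))
  expo <- (-d13C_diet - 10.29 - 0.0124 * abs(config$latitude_deg) +
             1.9e-4 * config$altitude_m) / 5.61
  10^expo - 300
}

#' Convert delta-18O from VPDB to VSMOW
#'
#' `d18O_VSMOW = 1.03091 * d18O_VPDB + 30.91` (Coplen scale conversion for
#' carbonates).
#'
#' @param d18O_vpdb delta-18O in permil VPDB.
#' @return delta-18O in permil VSMOW.
#' @export
vpdb_to_vsmow <- function(d18O_vpdb) {
  1.03091 * d18O_vpdb + 30.91
}

#' delta-18O of precipitation from enamel carbonate delta-18O (VSMOW)
#'
#' Combines the modern-elephant calibration between phosphate delta-18O and
#' precipitation (`d18O_PO4 = 0.94 * d18O_precip + 23.3`) with the
#' phosphate-carbonate relation (`d18O_PO4 = 0.96 * d18O_CO3 - 8.05`),
#' giving the rounded combined form `d18O_precip = 1.02 * d18O_CO3 - 33.3`.
#' Both routes are available; they agree within 0.06 permil over the
#' physiological enamel range (15-35 permil VSMOW).
#'
#' @param d18O_co3_vsmow Enamel carbonate delta-18O, permil VSMOW.
#' @param method `"combined"` (default) or `"two_step"`.
#' @return delta-18O of precipitation, permil VSMOW.
#' @export
d18o_precipitation <- function(d18O_co3_vsmow,
                               method = c("combined", "two_step")) {
  method <- match.arg(method)
  if (method == "combined") {
    1.02 * d18O_co3_vsmow - 33.3
  } else {
    po4 <- 0.96 * d18O_co3_vsmow - 8.05
    (po4 - 23.3) / 0.94
  }
}

#' Mean annual temperature from precipitation delta-18O
#'
#' `MAT = (d18O_precipitation + 14.178) / 0.442` degrees C, the mid-latitude
#' relation between meteoric-water delta-18O and mean annual temperature.
#'
#' @param d18O_precip delta-18O of precipitation, permil VSMOW.
#' @return MAT in degrees C.
#' @export
mat_from_precipitation <- function(d18O_precip) {
  (d18O_precip + 14.178) / 0.442
}

#' Flag outliers by Tukey boxplot fences
#'
#' Values outside `[lower hinge - 1.5 IQR, upper hinge + 1.5 IQR]` are
#' flagged, exactly the points a default R boxplot draws outside its
#' whiskers. Hinges are Tukey's (via [stats::fivenum()]); `quantile_type`
#' switches to interpolated sample quantiles ([stats::quantile()] types) if
#' a different convention is wanted. With fewer than 4 values no fence is
#' meaningful: the function warns and flags nothing.
#'
#' @param values Numeric vector.
#' @param k Fence multiplier (default 1.5).
#' @param quantile_type `"hinges"` (default) or an integer 1-9 passed to
#'   [stats::quantile()].
#' @return Logical vector, `TRUE` for flagged values.
#' @export
flag_outliers <- function(values, k = 1.5, quantile_type = "hinges") {
  stopifnot(is.numeric(values))
  if (length(values) < 4) {
    warning("fewer than 4 values: outlier screening refused, nothing flagged")
    return(rep(FALSE, length(values)))
  }
  if (identical(quantile_type, "hinges")) {
    fn <- stats::fivenum(values)
    q1 <- fn[2]; q3 <- fn[4]
  } else {
    q <- stats::quantile(values, c(0.25, 0.75), type = as.integer(quantile_type),
                         names = FALSE)
    q1 <- q[1]; q3 <- q[2]
  }
  iqr <- q3 - q1
  values < q1 - k * iqr | values > q3 + k * iqr
}

#' Full enamel-carbonate climate chain over a sample table
#'
#' Runs the per-specimen chain (diet delta-13C, MAP, VSMOW conversion,
#' precipitation delta-18O, MAT) and aggregates per species and with both
#' species merged. Outlier screening operates on the pooled enamel
#' delta-18O (VPDB) values. Aggregation policy: diet means are reported with
#' all specimens and with outliers removed; the precipitation/MAT aggregate
#' removes flagged outliers; the MAP aggregate is the mean of per-specimen
#' MAPs (not the MAP of the mean diet), excluding outliers and negative-MAP
#' specimens, which are counted in `n_map_negative`.
#'
#' @param samples Data frame with columns `specimen_id`, `species`,
#'   `d13C_vpdb`, `d18O_vpdb` (e.g. `load_fixture("table3_isotopes")`).
#' @param masses Named numeric vector: body mass in kg per species.
#' @param config A [site_config()].
#' @param outlier_filter If `FALSE`, skip outlier screening (nothing
#'   flagged).
#' @return List of class `climate_estimate` with `per_specimen`,
#'   `by_species`, `merged` data frames and the `config` used.
#' @export
climate_summary <- function(samples, masses, config, outlier_filter = TRUE) {
  stopifnot(inherits(config, "site_config"), nrow(samples) >= 1)
  missing_sp <- setdiff(unique(samples$species), names(masses))
  if (length(missing_sp) > 0) {
    stop(sprintf("no body mass configured for species: %s",
                 paste(missing_sp, collapse = ", ")), call. = FALSE)
  }
  mass <- unname(masses[samples$species])
  per <- data.frame(
    specimen_id = samples$specimen_id,
    species = samples$species,
    mass_kg = mass,
    d13C_vpdb = samples$d13C_vpdb,
    d18O_vpdb = samples$d18O_vpdb,
    stringsAsFactors = FALSE
  )
  per$d13C_diet <- d13c_diet(per$d13C_vpdb, per$mass_kg, config)
  per$map_mm_yr <- map_from_diet(per$d13C_diet, config)
  per$map_negative <- per$map_mm_yr < 0
  per$d18O_vsmow <- vpdb_to_vsmow(per$d18O_vpdb)
  per$d18O_precip <- d18o_precipitation(per$d18O_vsmow)
  per$mat_c <- mat_from_precipitation(per$d18O_precip)
  per$outlier <- if (outlier_filter) flag_outliers(per$d18O_vpdb) else rep(FALSE, nrow(per))

  aggregate_rows <- function(rows, label) {
    kept <- rows[!rows$outlier, , drop = FALSE]
    map_rows <- kept[!kept$map_negative, , drop = FALSE]
    precip_mean <- if (nrow(kept)) mean(kept$d18O_precip) else NA_real_
    data.frame(
      group = label,
      n = nrow(rows),
      n_outliers = sum(rows$outlier),
      d13C_diet_mean = mean(rows$d13C_diet),
      d13C_diet_sd = stats::sd(rows$d13C_diet),
      d13C_diet_mean_no_outlier = if (nrow(kept)) mean(kept$d13C_diet) else NA_real_,
      d18O_precip_mean = precip_mean,
      mat_c = mat_from_precipitation(precip_mean),
      map_mm_yr = if (nrow(map_rows)) mean(map_rows$map_mm_yr) else NA_real_,
      n_map = nrow(map_rows),
      n_map_negative = sum(kept$map_negative),
      stringsAsFactors = FALSE
    )
  }
  by_species <- do.call(rbind, lapply(split(per, per$species), function(rows) {
    aggregate_rows(rows, rows$species[1])
  }))
  rownames(by_species) <- NULL
  merged <- aggregate_rows(per, "merged")
  structure(
    list(per_specimen = per, by_species = by_species, merged = merged,
         config = config),
    class = "climate_estimate"
  )
}

#' @export
print.climate_estimate <- function(x, ...) {
  cat(sprintf("Climate estimate from %d enamel samples (%d outlier(s) flagged)\n",
              nrow(x$per_specimen), sum(x$per_specimen$outlier)))
  cat(sprintf("  merged: d18O_precip = %.2f permil VSMOW, MAT = %.1f C, MAP = %.0f mm/yr (n_map = %d)\n",
              x$merged$d18O_precip_mean, x$merged$mat_c,
              x$merged$map_mm_yr, x$merged$n_map))
  invisible(x)
}
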