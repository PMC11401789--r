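#' Assemblage CSV schema
#'
#' One row per tooth. Mandatory columns: `specimen_id`, `species`, `locus`,
#' `side`, `wear`. Optional columns: `association_id` (teeth sharing it
#' belong to one individual), `length_mm`, `width_mm`, `crown_height_mm`,
#' `damaged`, `mesowear_score`, `hypoplasia_n`, `dmta_facet`,
#' `dmta_neweplsar`, `dmta_asfc`, `dmta_hasfc9`, `dmta_hasfc81`,
#' `d13C_vpdb`, `d18O_vpdb`. Units are encoded in the column names (`_mm`,
#' `_vpdb` in permil); decimals use `.`; absent values are empty cells.
#' Unknown extra columns are preserved.
#'
#' @name assemblage-schema
NULL

assemblage_required_cols <- c("specimen_id", "species", "locus", "side", "wear")
assemblage_optional_cols <- c(
  "association_id", "length_mm", "width_mm", "crown_height_mm", "damaged",
  "mesowear_score", "hypoplasia_n", "dmta_facet", "dmta_neweplsar",
  "dmta_asfc", "dmta_hasfc9", "dmta_hasfc81", "d13C_vpdb", "d18O_vpdb"
)

#' Read a tooth assemblage from CSV
#'
#' Validates the schema row by row (parseable locus, wear stage in 1-10,
#' positive measurements, side values) and reports every offending row in
#' one error rather than stopping at the first.
#'
#' @param path Path to a CSV following the assemblage schema
#'   (see [assemblage-schema]).
#' @return Validated assemblage data frame with all optional columns present
#'   (filled with `NA` where absent from the file).
#' @export
read_assemblage <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("assemblage file does not exist: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  missing_cols <- setdiff(assemblage_required_cols, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("assemblage file is missing mandatory column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in assemblage_optional_cols) {
    if (!col %in% names(df)) df[[col]] <- rep(NA, nrow(df))
  }
  if (nrow(df) == 0) return(df)
  df$association_id <- as.character(df$association_id)
  df$wear <- suppressWarnings(as.integer(df$wear))
  df$damaged <- !is.na(df$damaged) & as.logical(df$damaged)

  problems <- character(0)
  lf <- locus_fields(df$locus)
  bad <- which(!lf$valid)
  if (length(bad)) {
    problems <- c(problems, sprintf("row %d: unparseable locus '%s'",
                                    bad, df$locus[bad]))
  }
  bad <- which(!is.na(df$wear) & (df$wear < 1 | df$wear > 10))
  if (length(bad)) {
    problems <- c(problems, sprintf("row %d: wear stage %d outside 1-10",
                                    bad, df$wear[bad]))
  }
  bad <- which(!df$side %in% c("left", "right", "unknown"))
  if (length(bad)) {
    problems <- c(problems, sprintf("row %d: side '%s' not left/right/unknown",
                                    bad, df$side[bad]))
  }
  for (col in c("length_mm", "width_mm", "crown_height_mm")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    df[[col]] <- v
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad)) {
      problems <- c(problems, sprintf("row %d: %s must be > 0 (got %g)",
                                      bad, col, v[bad]))
    }
  }
  if (length(problems) > 0) {
    stop(sprintf("invalid assemblage file %s:\n  %s", path,
                 paste(problems, collapse = "\n  ")), call. = FALSE)
  }
  df
}

#' Write a tooth assemblage to CSV
#'
#' @param records Assemblage data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assemblage <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Load a packaged data fixture
#'
#' Exact transcriptions of the published Ulm-Westtangente tables, packaged
#' so the whole pipeline is runnable offline: `table1_counts` (specimens per
#' method and species), `table3_isotopes` (the eight enamel carbonate
#' delta-13C/delta-18O analyses), `table4_hypoplasia` (hypoplasia counts by
#' locus, species merged), `table5_masses` (body-mass means per dental
#' proxy), and `site_ulm` (the locality's coordinates and atmospheric
#' parameters, returned as a [site_config()]).
#'
#' @param name One of `"table1_counts"`, `"table3_isotopes"`,
#'   `"table4_hypoplasia"`, `"table5_masses"`, `"site_ulm"`.
#' @return A data frame, or a `site_config` for `"site_ulm"`.
#' @examples
#' load_fixture("table3_isotopes")
#' @export
load_fixture <- function(name) {
  known <- c("table1_counts", "table3_isotopes", "table4_hypoplasia",
             "table5_masses", "site_ulm")
  if (!name %in% known) {
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(known, collapse = ", ")), call. = FALSE)
  }
  if (name == "site_ulm") {
    path <- system.file("extdata", "site_ulm.yaml", package = "paleomolar")
    site <- yaml::read_yaml(path)
    cfg <- site_config(latitude_deg = site$latitude_deg,
                       altitude_m = site$altitude_m,
                       d13C_atm_paleo = site$d13C_atm_paleo,
                       d13C_atm_modern = site$d13C_atm_modern,
                       lifespan_years = site$lifespan_years)
    cfg$longitude_deg <- site$longitude_deg
    return(cfg)
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "paleomolar")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("specimen_id" %in% names(df)) df$specimen_id <- as.character(df$specimen_id)
  df
}

#' Run the full multi-proxy report
#'
#' Chains demography, body mass, the isotope climate chain and the
#' dental-health summaries over one assemblage, and returns everything in a
#' single bundle with the configuration used. Stages that lack the columns
#' they need (e.g. no isotope samples) are reported as `NULL` rather than
#' failing the whole run.
#'
#' @param records Assemblage data frame.
#' @param site A [site_config()].
#' @param masses Named species mass vector for the isotope chain; if `NULL`,
#'   species means from the upper-M2 Damuth proxy computed from the
#'   assemblage itself (falling back per species to the first available
#'   proxy).
#' @param outlier_filter Passed to [climate_summary()].
#' @param lookup,table Ageing configuration.
#' @return List of class `paleo_report` with elements `curves` (per
#'   species), `structure`, `mni`, `mass_summary`, `climate`, `mesowear`,
#'   `prevalence`, `config`.
#' @export
run_report <- function(records, site, masses = NULL, outlier_filter = TRUE,
                       lookup = default_wear_age_lookup(),
                       table = default_age_classes()) {
  species <- sort(unique(records$species))
  assignments <- assign_ages(records, lookup, table)
  curves <- lapply(stats::setNames(species, species), function(sp) {
    a <- assign_ages(records[records$species == sp, , drop = FALSE], lookup, table)
    if (nrow(a) == 0) NULL else build_curve(a, table)
  })
  structure_pct <- age_structure(assignments)
  mni_by_species <- lapply(stats::setNames(species, species), function(sp) {
    mni(records[records$species == sp, , drop = FALSE])
  })
  estimates <- estimate_mass(records)
  mass_summary <- species_mass_summary(estimates)

  if (is.null(masses)) {
    masses <- vapply(species, function(sp) {
      rows <- mass_summary[mass_summary$species == sp, , drop = FALSE]
      if (nrow(rows) == 0) return(NA_real_)
      hit <- rows$mean_kg[rows$equation_id == "damuth_M2"]
      if (length(hit) == 1) hit else rows$mean_kg[1]
    }, numeric(1))
    masses <- masses[!is.na(masses)]
  }
  iso <- records[!is.na(records$d13C_vpdb) & !is.na(records$d18O_vpdb), ,
                 drop = FALSE]
  iso <- iso[iso$species %in% names(masses), , drop = FALSE]
  climate <- if (nrow(iso) > 0) {
    climate_summary(iso, masses, site, outlier_filter = outlier_filter)
  } else NULL

  eligible <- records[hypoplasia_eligible(records), , drop = FALSE]
  out <- list(
    curves = curves,
    structure = structure_pct,
    mni = mni_by_species,
    mass_summary = mass_summary,
    climate = climate,
    mesowear = mesowear_summary(records),
    prevalence = if (nrow(eligible) > 0) prevalence(eligible) else NULL,
    config = list(
      package_version = as.character(utils::packageVersion("paleomolar")),
      site = unclass(site), masses = as.list(masses),
      outlier_filter = outlier_filter,
      n_records = nrow(records), species = species
    )
  )
  class(out) <- "paleo_report"
  out
}

#' Write a report bundle to disk
#'
#' Emits one JSON summary (`report.json`) plus per-stage CSV tables into
#' `dir`. Output is deterministic for identical inputs and configuration.
#'
#' @param report A `paleo_report` from [run_report()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "paleo_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(
    config = report$config,
    structure = as.list(report$structure),
    mni = report$mni,
    climate = if (!is.null(report$climate)) {
      list(merged = as.list(report$climate$merged),
           MAT_c = report$climate$merged$mat_c,
           MAP_mm_yr = report$climate$merged$map_mm_yr)
    }
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  for (sp in names(report$curves)) {
    if (is.null(report$curves[[sp]])) next
    curve <- report$curves[[sp]]
    curve <- cbind(curve, lifespan_fraction(curve$class_id)[, c("start_pct", "end_pct")])
    utils::write.csv(curve, file.path(dir, sprintf("curve_%s.csv",
                                                   gsub("[^A-Za-z0-9]+", "_", sp))),
                     row.names = FALSE)
  }
  if (nrow(report$mass_summary) > 0) {
    utils::write.csv(report$mass_summary, file.path(dir, "mass_summary.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$prevalence)) {
    utils::write.csv(report$prevalence, file.path(dir, "hypoplasia_prevalence.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$climate)) {
    utils::write.csv(report$climate$per_specimen,
                     file.path(dir, "climate_per_specimen.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
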