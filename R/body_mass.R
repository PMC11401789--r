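#' Dental allometric body-mass equations
#'
#' Eight published regressions predicting body mass from lower/upper molar
#' dimensions in large herbivores. Janis' equations take length in cm
#' (length/10) and return kg; Damuth's, Legendre's and Fortelius &
#' Kappelman's take mm and return g (converted to kg here). The Legendre m1
#' equation uses the occlusal surface proxy length x width; all others use
#' length alone.
#'
#' @return Data frame of class `mass_equation_table` with columns `id`,
#'   `locus`, `predictor` (`"length"`/`"length_width"`), `log_base`
#'   (`"log10"`/`"ln"`), `slope`, `intercept`, `length_divisor`,
#'   `output_unit` (`"g"`/`"kg"`), `source`.
#' @export
mass_equations <- function() {
  out <- data.frame(
    id = c("legendre_m1", "janis_m1", "janis_m2", "damuth_m2",
           "fk_M1", "janis_M2", "damuth_M2", "fk_M2"),
    locus = c("m1", "m1", "m2", "m2", "M1", "M2", "M2", "M2"),
    predictor = c("length_width", "length", "length", "length",
                  "length", "length", "length", "length"),
    log_base = c("ln", "log10", "log10", "log10", "ln", "log10", "log10", "ln"),
    slope = c(1.5133, 3.26, 3.2, 3.07, 3.19, 3.18, 3.03, 3.09),
    intercept = c(3.6515, 1.337, 1.13, 1.07, 2.1, 1.091, 1.06, 2.14),
    length_divisor = c(1, 10, 10, 1, 1, 10, 1, 1),
    output_unit = c("g", "kg", "kg", "g", "g", "kg", "g", "g"),
    source = c("Legendre 1986", "Janis 1990", "Janis 1990", "Damuth 1990",
               "Fortelius & Kappelman 1993", "Janis 1990", "Damuth 1990",
               "Fortelius & Kappelman 1993"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("mass_equation_table", "data.frame")
  out
}

get_equation <- function(id, equations = mass_equations()) {
  row <- equations[equations$id == id, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop(sprintf("unknown mass equation id '%s'", id), call. = FALSE)
  }
  row
}

#' Evaluate a mass equation
#'
#' @param equation_id Equation id from [mass_equations()].
#' @param length_mm Tooth length in mm (vectorised).
#' @param width_mm Tooth width in mm; required for `length_width` predictors.
#' @param equations Equation table.
#' @return Body mass in kg.
#' @examples
#' apply_mass_equation("janis_m1", 10)   # 10^1.337 = 21.73 kg
#' @export
apply_mass_equation <- function(equation_id, length_mm, width_mm = NULL,
                                equations = mass_equations()) {
  eq <- get_equation(equation_id, equations)
  if (any(!is.finite(length_mm)) || any(length_mm <= 0)) {
    stop("length_mm must be finite and > 0", call. = FALSE)
  }
  pred <- if (eq$predictor == "length_width") {
    if (is.null(width_mm)) {
      stop(sprintf("equation '%s' needs width_mm (length x width predictor)",
                   equation_id), call. = FALSE)
    }
    if (any(!is.finite(width_mm)) || any(width_mm <= 0)) {
      stop("width_mm must be finite and > 0", call. = FALSE)
    }
    length_mm * width_mm
  } else {
    length_mm / eq$length_divisor
  }
  logf <- if (eq$log_base == "log10") log10 else log
  expf <- if (eq$log_base == "log10") function(x) 10^x else exp
  mass <- expf(eq$slope * logf(pred) + eq$intercept)
  if (eq$output_unit == "g") mass <- mass / 1000
  mass
}

#' Invert a mass equation
#'
#' Returns the predictor value (length in mm, or the length x width product
#' in mm^2) that yields the requested mass. Used by the synthetic-assemblage
#' generator to manufacture tooth measurements from a target species mass.
#'
#' @inheritParams apply_mass_equation
#' @param mass_kg Target body mass in kg, > 0.
#' @return Predictor value on the mm scale (mm, or mm^2 for `length_width`).
#' @export
invert_mass_equation <- function(equation_id, mass_kg,
                                 equations = mass_equations()) {
  eq <- get_equation(equation_id, equations)
  if (any(!is.finite(mass_kg)) || any(mass_kg <= 0)) {
    stop("mass_kg must be finite and > 0", call. = FALSE)
  }
  mass <- if (eq$output_unit == "g") mass_kg * 1000 else mass_kg
  logf <- if (eq$log_base == "log10") log10 else log
  expf <- if (eq$log_base == "log10") function(x) 10^x else exp
  pred <- expf((logf(mass) - eq$intercept) / eq$slope)
  if (eq$predictor == "length_width") pred else pred * eq$length_divisor
}

#' Per-tooth body-mass estimates for an assemblage
#'
#' Applies every equation whose locus matches each measured tooth. Worn
#' first lower molars shorten with wear, biasing length-based estimates
#' downwards; teeth at wear stage >= 8 are flagged (`worn_flag`), not
#' corrected.
#'
#' @param records Assemblage data frame.
#' @param equations Equation table (default [mass_equations()]).
#' @return Data frame with `specimen_id`, `species`, `locus`, `side`,
#'   `equation_id`, `mass_kg`, `worn_flag`.
#' @export
estimate_mass <- function(records, equations = mass_equations()) {
  out <- list()
  for (i in seq_len(nrow(equations))) {
    eq <- equations[i, ]
    rows <- records[records$locus == eq$locus & !is.na(records$length_mm), ,
                    drop = FALSE]
    if (eq$predictor == "length_width") {
      rows <- rows[!is.na(rows$width_mm), , drop = FALSE]
    }
    if (nrow(rows) == 0) next
    mass <- apply_mass_equation(eq$id, rows$length_mm,
                                if (eq$predictor == "length_width") rows$width_mm,
                                equations)
    out[[eq$id]] <- data.frame(
      specimen_id = rows$specimen_id, species = rows$species,
      locus = rows$locus, side = rows$side, equation_id = eq$id,
      mass_kg = mass,
      worn_flag = !is.na(rows$wear) & rows$wear >= 8,
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    return(data.frame(specimen_id = character(), species = character(),
                      locus = character(), side = character(),
                      equation_id = character(), mass_kg = numeric(),
                      worn_flag = logical(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Species-level mean body mass per equation
#'
#' Deduplicates to one tooth per specimen per equation (left preferred, then
#' right, then unknown side) before averaging, so bilaterally preserved
#' specimens do not count twice.
#'
#' @param estimates Output of [estimate_mass()].
#' @return Data frame with `species`, `equation_id`, `n`, `mean_kg`.
#' @export
species_mass_summary <- function(estimates) {
  if (nrow(estimates) == 0) {
    return(data.frame(species = character(), equation_id = character(),
                      n = integer(), mean_kg = numeric(),
                      stringsAsFactors = FALSE))
  }
  pref <- match(estimates$side, c("left", "right"))
  pref[is.na(pref)] <- 3L
  ord <- order(estimates$species, estimates$equation_id,
               estimates$specimen_id, pref)
  est <- estimates[ord, , drop = FALSE]
  keep <- !duplicated(est[, c("species", "equation_id", "specimen_id")])
  est <- est[keep, , drop = FALSE]
  agg <- stats::aggregate(mass_kg ~ species + equation_id, data = est,
                          FUN = function(x) c(n = length(x), mean = mean(x)))
  data.frame(
    species = agg$species,
    equation_id = agg$equation_id,
    n = as.integer(agg$mass_kg[, "n"]),
    mean_kg = agg$mass_kg[, "mean"],
    stringsAsFactors = FALSE
  )
}
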