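#' Age individuals from tooth wear
#'
#' Implements the standard tooth-wear ageing protocol for rhinocerotid
#' assemblages: each isolated tooth counts as one individual with total
#' weight 1; its wear stage maps (per locus) to one or several age classes,
#' each receiving equal weight (1 if one class, 1/2 if two, and so on).
#' Teeth sharing an `association_id` are grouped as a single individual whose
#' admissible classes are the intersection of the members' class sets; an
#' empty intersection is an error (the association proposes no coherent age).
#'
#' @param records An assemblage data frame (see [read_assemblage()] for the
#'   schema). Rows without a wear stage are ignored.
#' @param lookup Wear-age lookup (default packaged).
#' @param table Age class table (default [default_age_classes()]).
#' @return Data frame with columns `individual_id`, `class_id`, `weight`;
#'   weights sum to 1 within each individual. The number of individuals is
#'   `length(unique(individual_id))`.
#' @export
assign_ages <- function(records, lookup = default_wear_age_lookup(),
                        table = default_age_classes()) {
  validate_age_class_table(table)
  idx <- lookup_index(lookup)
  scored <- records[!is.na(records$wear), , drop = FALSE]
  if (nrow(scored) == 0) {
    return(data.frame(individual_id = character(), class_id = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  }
  key <- paste(scored$locus, scored$wear, sep = "|")
  miss <- !(key %in% names(idx))
  if (any(miss)) {
    stop(sprintf("no wear-age lookup entry for: %s",
                 paste(unique(sprintf("%s stage %s", scored$locus[miss],
                                      scored$wear[miss])), collapse = ", ")),
         call. = FALSE)
  }
  sets <- idx[key]
  assoc <- if ("association_id" %in% names(scored)) scored$association_id else rep(NA, nrow(scored))
  assoc <- ifelse(is.na(assoc) | assoc == "", NA, as.character(assoc))
  unit <- ifelse(is.na(assoc),
                 sprintf("tooth:%s#%d", scored$specimen_id, seq_len(nrow(scored))),
                 sprintf("assoc:%s", assoc))
  groups <- split(seq_len(nrow(scored)), unit)
  out <- lapply(names(groups), function(u) {
    rows <- groups[[u]]
    cls <- Reduce(intersect, sets[rows])
    if (length(cls) == 0) {
      stop(sprintf(
        "associated teeth in group '%s' have incompatible wear ages (members: %s)",
        sub("^assoc:", "", u),
        paste(sprintf("%s %s wear %s", scored$specimen_id[rows],
                      scored$locus[rows], scored$wear[rows]), collapse = "; ")),
        call. = FALSE)
    }
    data.frame(individual_id = u, class_id = cls, weight = 1 / length(cls),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Build a mortality curve from individual age assignments
#'
#' The raw curve sums individual weights per age class; the corrected curve
#' divides each class's raw weight by the class duration in years, giving a
#' per-year mortality rate that is comparable across classes of unequal
#' length.
#'
#' @param assignments Output of [assign_ages()].
#' @param table Age class table.
#' @return A data frame of class `mortality_curve` with one row per age class
#'   (`class_id`, `start_years`, `end_years`, `raw`, `corrected`) and
#'   attribute `n_individuals`.
#' @export
build_curve <- function(assignments, table = default_age_classes()) {
  validate_age_class_table(table)
  if (nrow(assignments) == 0) {
    stop("cannot build a mortality curve from an empty set of assignments",
         call. = FALSE)
  }
  raw <- tapply(assignments$weight, factor(assignments$class_id,
                                           levels = table$class_id), sum)
  raw[is.na(raw)] <- 0
  dur <- table$end_years - table$start_years
  out <- data.frame(
    class_id = table$class_id,
    start_years = table$start_years,
    end_years = table$end_years,
    raw = as.numeric(raw),
    corrected = as.numeric(raw) / dur,
    stringsAsFactors = FALSE
  )
  attr(out, "n_individuals") <- length(unique(assignments$individual_id))
  class(out) <- c("mortality_curve", "data.frame")
  out
}

#' Age structure by ontogenetic stage
#'
#' Routes each individual's weight mass through [stage_of()] and reports the
#' percentage of juveniles (classes 0-V), subadults (VI-VIII) and adults
#' (IX-XVI).
#'
#' @param assignments Output of [assign_ages()].
#' @return Named numeric vector `c(juvenile, subadult, adult)` in percent,
#'   summing to 100.
#' @export
age_structure <- function(assignments) {
  if (nrow(assignments) == 0) {
    stop("cannot compute an age structure from an empty set of assignments",
         call. = FALSE)
  }
  stage <- factor(stage_of(assignments$class_id),
                  levels = c("juvenile", "subadult", "adult"))
  mass <- tapply(assignments$weight, stage, sum)
  mass[is.na(mass)] <- 0
  stats::setNames(as.numeric(100 * mass / sum(mass)), names(mass))
}

#' Compare two mortality curves
#'
#' Two-sample Kolmogorov-Smirnov test on the duration-corrected per-class
#' rates (each age class contributes one value per curve). With 17-class
#' tables both samples are small; `stats::ks.test` uses the exact
#' small-sample distribution where feasible.
#'
#' @param a,b Mortality curves from [build_curve()] on the same class table.
#' @return List with `D` (the KS statistic) and `p`.
#' @export
compare_curves <- function(a, b) {
  if (!identical(a$class_id, b$class_id)) {
    stop("mortality curves must be built on the same age class table", call. = FALSE)
  }
  if (nrow(a) == 0 || nrow(b) == 0 || sum(a$raw) == 0 || sum(b$raw) == 0) {
    stop("cannot compare empty mortality curves", call. = FALSE)
  }
  ks <- suppressWarnings(stats::ks.test(a$corrected, b$corrected))
  list(D = unname(ks$statistic), p = unname(ks$p.value))
}

#' Dental eruption-incompatibility groups
#'
#' Loci that never co-occur in a single functioning tooth row and therefore
#' raise the minimum number of individuals: milk teeth are replaced before
#' the third molars erupt (group `a`) and before the fourth premolars erupt
#' (group `b`); third milk molars are shed when the third premolars erupt
#' (group `d`).
#'
#' @return List of groups, each a list with `id`, `set_A`, `set_B` (locus
#'   code vectors).
#' @export
default_incompatibility_groups <- function() {
  milk <- c(paste0("d", 1:4), paste0("D", 1:4))
  list(
    list(id = "a", set_A = milk, set_B = c("m3", "M3")),
    list(id = "b", set_A = milk, set_B = c("p4", "P4")),
    list(id = "d", set_A = c("d3", "D3"), set_B = c("p3", "P3"))
  )
}

#' Minimum number of individuals
#'
#' The simple MNI is the count of the most abundant sided element (e.g. left
#' m1), with associated teeth counted once. Eruption-incompatibility groups
#' refine it: no individual bears functional teeth from both sides of a
#' group, so the best single sided-locus count within `set_A` plus the best
#' within `set_B` (sides chosen independently; the incompatibility is
#' ontogenetic, not bilateral) is also a lower bound. Teeth of unknown side
#' do not enter the sided maxima.
#'
#' @param records Assemblage data frame for one species.
#' @param groups Incompatibility groups (default [default_incompatibility_groups()]).
#' @return List with `simple`, `by_group` (named numeric) and `overall`.
#' @export
mni <- function(records, groups = default_incompatibility_groups()) {
  if (nrow(records) == 0) {
    return(list(simple = 0L,
                by_group = stats::setNames(numeric(0), character(0)),
                overall = 0L))
  }
  assoc <- if ("association_id" %in% names(records)) records$association_id else rep(NA, nrow(records))
  assoc <- ifelse(is.na(assoc) | assoc == "", NA, as.character(assoc))
  unit <- ifelse(is.na(assoc), sprintf("row#%d", seq_len(nrow(records))),
                 sprintf("assoc:%s", assoc))
  sided <- records$side %in% c("left", "right")
  counts <- if (any(sided)) {
    df <- data.frame(locus = records$locus[sided], side = records$side[sided],
                     unit = unit[sided], stringsAsFactors = FALSE)
    df <- unique(df)
    tab <- table(paste(df$locus, df$side))
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(0), character(0))
  }
  max_for <- function(loci) {
    keys <- as.vector(outer(loci, c("left", "right"), paste))
    hits <- counts[names(counts) %in% keys]
    if (length(hits) == 0) 0L else max(hits)
  }
  # a non-empty assemblage implies at least one individual even if no tooth
  # is sided
  simple <- if (length(counts) == 0) 1L else max(counts)
  by_group <- vapply(groups, function(g) max_for(g$set_A) + max_for(g$set_B),
                     numeric(1))
  names(by_group) <- vapply(groups, `[[`, character(1), "id")
  list(simple = as.integer(simple),
       by_group = by_group,
       overall = as.integer(max(c(simple, by_group))))
}
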