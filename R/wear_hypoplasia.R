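#' Hypsodonty index of an unworn third lower molar
#'
#' `HI = crown height / width` of an unworn m3. Crown-height classes use the
#' conventional thresholds (configurable): brachyodont below 1.5, mesodont
#' in [1.5, 2.5), hypsodont at 2.5 and above.
#'
#' @param crown_height_mm,width_mm Positive measurements in mm (vectorised).
#' @param thresholds Length-2 numeric `c(mesodont_from, hypsodont_from)`.
#' @return Data frame with `index` and `class`.
#' @examples
#' hypsodonty_index(c(39.3, 46.5), c(30, 30))
#' @export
hypsodonty_index <- function(crown_height_mm, width_mm,
                             thresholds = c(1.5, 2.5)) {
  if (any(!is.finite(width_mm)) || any(width_mm <= 0)) {
    stop("width_mm must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(crown_height_mm)) || any(crown_height_mm <= 0)) {
    stop("crown_height_mm must be finite and > 0", call. = FALSE)
  }
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  hi <- crown_height_mm / width_mm
  cls <- cut(hi, breaks = c(-Inf, thresholds, Inf),
             labels = c("brachyodont", "mesodont", "hypsodont"),
             right = FALSE)
  data.frame(index = hi, class = as.character(cls), stringsAsFactors = FALSE)
}

#' Mesowear eligibility
#'
#' Mesowear is scored on upper molars only, and only at average wear (stages
#' 4-7): little-worn cusps have not yet acquired a dietary signature and
#' heavily worn ones lose it. Damaged teeth are excluded.
#'
#' @param records Assemblage data frame.
#' @return Logical vector, one element per row.
#' @export
mesowear_eligible <- function(records) {
  lf <- locus_fields(records$locus)
  damaged <- if ("damaged" %in% names(records)) {
    !is.na(records$damaged) & records$damaged
  } else {
    rep(FALSE, nrow(records))
  }
  lf$valid & lf$arcade == "upper" & lf$family == "molar" &
    !is.na(records$wear) & records$wear >= 4 & records$wear <= 7 & !damaged
}

#' Hypoplasia eligibility
#'
#' Very worn teeth (stages 9-10) and damaged teeth (limited to no enamel
#' preserved) are excluded to limit false negatives; everything else,
#' including unscored wear, is eligible.
#'
#' @param records Assemblage data frame.
#' @return Logical vector, one element per row.
#' @export
hypoplasia_eligible <- function(records) {
  damaged <- if ("damaged" %in% names(records)) {
    !is.na(records$damaged) & records$damaged
  } else {
    rep(FALSE, nrow(records))
  }
  very_worn <- !is.na(records$wear) & records$wear %in% c(9, 10)
  !very_worn & !damaged
}

#' Summarise ordinal scores per group
#'
#' @param values Numeric scores.
#' @param group Grouping vector of the same length.
#' @return Data frame with `group`, `n`, `mean`, `sd` (`sd` is `NA` for
#'   single observations). Empty groups are absent.
#' @export
summarize_scores <- function(values, group) {
  stopifnot(length(values) == length(group))
  keep <- !is.na(values)
  values <- values[keep]; group <- group[keep]
  if (length(values) == 0) {
    return(data.frame(group = character(), n = integer(), mean = numeric(),
                      sd = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(split(values, group), function(v) {
    data.frame(n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  }))
  data.frame(group = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Mesowear summary per species
#'
#' Filters to eligible teeth, keeps one tooth per specimen (second molars
#' preferred, then by position), and summarises the ruler scores (0 high
#' sharp - 6 low blunt).
#'
#' @param records Assemblage data frame with `mesowear_score`.
#' @return Data frame with `group` (species), `n`, `mean`, `sd`.
#' @export
mesowear_summary <- function(records) {
  rows <- records[mesowear_eligible(records) & !is.na(records$mesowear_score), ,
                  drop = FALSE]
  if (nrow(rows) == 0) {
    return(data.frame(group = character(), n = integer(), mean = numeric(),
                      sd = numeric(), stringsAsFactors = FALSE))
  }
  pos <- locus_fields(rows$locus)$position
  # prefer M2, then M1, then M3; deterministic within specimen
  pref <- match(pos, c(2L, 1L, 3L))
  ord <- order(rows$species, rows$specimen_id, pref)
  rows <- rows[ord, , drop = FALSE]
  rows <- rows[!duplicated(rows[, c("species", "specimen_id")]), , drop = FALSE]
  summarize_scores(rows$mesowear_score, rows$species)
}

#' DMTA texture-variable summary
#'
#' Summarises the ingested microwear texture variables (NewepLsar, Asfc,
#' HAsfc9, HAsfc81) per species and wear facet. The variables themselves are
#' measured upstream by scale-sensitive fractal analysis of surface scans;
#' this package only ingests and summarises them.
#'
#' @param records Assemblage data frame with `dmta_facet` and `dmta_*`
#'   columns.
#' @return Data frame with `species`, `facet`, `variable`, `n`, `mean`, `sd`.
#' @export
dmta_summary <- function(records) {
  vars <- c("dmta_neweplsar", "dmta_asfc", "dmta_hasfc9", "dmta_hasfc81")
  rows <- records[!is.na(records$dmta_facet), , drop = FALSE]
  out <- list()
  for (v in vars) {
    if (!v %in% names(rows)) next
    s <- summarize_scores(rows[[v]], paste(rows$species, rows$dmta_facet, sep = "|"))
    if (nrow(s) == 0) next
    parts <- strsplit(s$group, "|", fixed = TRUE)
    out[[v]] <- data.frame(
      species = vapply(parts, `[`, character(1), 1),
      facet = vapply(parts, `[`, character(1), 2),
      variable = sub("^dmta_", "", v),
      s[, c("n", "mean", "sd")],
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    return(data.frame(species = character(), facet = character(),
                      variable = character(), n = integer(), mean = numeric(),
                      sd = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hypoplasia prevalence table
#'
#' A tooth is affected if it bears at least one hypoplastic defect
#' (`hypoplasia_n >= 1`). Input records should already be restricted with
#' [hypoplasia_eligible()]. Frequencies are exact percentages
#' `100 * affected / (affected + unaffected)`; a grand `TOTAL` row is
#' appended.
#'
#' @param records Eligible assemblage data frame.
#' @param by Grouping: `"locus"` (species merged), `"species_locus"` or
#'   `"species"`.
#' @return Data frame of class `prevalence_table` with group columns,
#'   `affected`, `unaffected`, `n`, `frequency`.
#' @export
prevalence <- function(records, by = c("locus", "species_locus", "species")) {
  by <- match.arg(by)
  affected <- !is.na(records$hypoplasia_n) & records$hypoplasia_n >= 1
  group <- switch(by,
    locus = records$locus,
    species = records$species,
    species_locus = paste(records$species, records$locus, sep = "|")
  )
  tab <- do.call(rbind, lapply(split(affected, group), function(a) {
    data.frame(affected = sum(a), unaffected = sum(!a), n = length(a))
  }))
  out <- data.frame(group = rownames(tab), tab, row.names = NULL,
                    stringsAsFactors = FALSE)
  total <- data.frame(group = "TOTAL", affected = sum(affected),
                      unaffected = sum(!affected), n = length(affected),
                      stringsAsFactors = FALSE)
  out <- rbind(out, total)
  out$frequency <- ifelse(out$n > 0, 100 * out$affected / out$n, NA_real_)
  class(out) <- c("prevalence_table", "data.frame")
  out
}

#' Two-group rank comparison (Kruskal-Wallis)
#'
#' Thin contract over [stats::kruskal.test()] with tie correction, used for
#' species comparisons of mesowear scores, hypsodonty indices and hypoplasia
#' prevalences. If every pooled value is identical the test is degenerate:
#' `H = 0`, `p = 1`.
#'
#' @param a,b Numeric vectors, each with at least one value.
#' @return List with `H` (chi-squared statistic), `df`, `p`.
#' @export
rank_compare <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    return(list(H = 0, df = 1L, p = 1))
  }
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  kt <- stats::kruskal.test(pooled, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value))
}
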