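# Builders for in-code fixtures.

# One tooth row with sensible defaults; override any schema column.
tooth <- function(specimen_id = "T1", species = SP_MINUTUM, locus = "m1",
                  side = "left", wear = 5, association_id = NA_character_,
                  length_mm = NA_real_, width_mm = NA_real_,
                  crown_height_mm = NA_real_, damaged = FALSE,
                  mesowear_score = NA_integer_, hypoplasia_n = 0L,
                  d13C_vpdb = NA_real_, d18O_vpdb = NA_real_) {
  data.frame(specimen_id = specimen_id, species = species, locus = locus,
             side = side, wear = wear, association_id = association_id,
             length_mm = length_mm, width_mm = width_mm,
             crown_height_mm = crown_height_mm, damaged = damaged,
             mesowear_score = mesowear_score, hypoplasia_n = hypoplasia_n,
             d13C_vpdb = d13C_vpdb, d18O_vpdb = d18O_vpdb,
             stringsAsFactors = FALSE)
}

assemblage <- function(...) {
  do.call(rbind, list(...))
}

# A hand-written mini-lookup for tests that need known multi-class keys.
toy_lookup <- function() {
  data.frame(
    locus = c("m1", "m1", "m2", "m2", "m3"),
    wear_stage = c(1L, 2L, 1L, 2L, 1L),
    age_classes = c("V;VI", "IX", "VI;VII", "VII;VIII", "IX"),
    stringsAsFactors = FALSE
  )
}

# Expand a per-locus count table (unaffected/affected) into one row per
# tooth, the form prevalence() consumes.
expand_hypoplasia_counts <- function(counts) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    n_aff <- counts$affected[i]
    n_un <- counts$unaffected[i]
    k <- n_aff + n_un
    if (k == 0) return(NULL)
    tooth(specimen_id = sprintf("%s-%03d", counts$locus[i], seq_len(k)),
          locus = counts$locus[i], wear = 5,
          hypoplasia_n = rep(c(1L, 0L), c(n_aff, n_un)))
  })
  do.call(rbind, rows)
}

# Brute-force two-sample KS statistic: max ECDF gap over the pooled values.
brute_force_ks <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(abs(vapply(grid, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# Kruskal-Wallis H from first principles (tie-corrected), as an independent
# check on rank_compare.
brute_force_kw <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n <- length(pooled)
  groups <- list(r[seq_along(a)], r[length(a) + seq_along(b)])
  h <- 12 / (n * (n + 1)) *
    sum(vapply(groups, function(g) length(g) * (mean(g) - (n + 1) / 2)^2,
               numeric(1)))
  ties <- table(pooled)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}
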