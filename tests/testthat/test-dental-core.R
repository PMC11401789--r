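test_that("locus codes parse into arcade, generation, family and position", {
  d3 <- parse_locus("d3")
  expect_equal(d3$arcade, "lower")
  expect_equal(d3$generation, "deciduous")
  expect_equal(d3$family, "milk_molar")
  expect_equal(d3$position, 3L)

  M2 <- parse_locus("M2")
  expect_equal(M2$arcade, "upper")
  expect_equal(M2$generation, "permanent")
  expect_equal(M2$family, "molar")
  expect_equal(M2$position, 2L)

  # case carries the arcade; round-trips through the code field
  for (code in all_locus_codes()) {
    expect_equal(parse_locus(code)$code, code)
  }
  expect_equal(parse_locus("p2")$arcade, "lower")
  expect_equal(parse_locus("P2")$arcade, "upper")
})

test_that("invalid locus codes are rejected with the offending code named", {
  expect_error(parse_locus("p5"), "p5")
  expect_error(parse_locus("p1"), "premolar positions")
  expect_error(parse_locus("m4"), "molar positions")
  expect_error(parse_locus("q2"), "malformed")
  expect_error(parse_locus("m"), "malformed")
  expect_error(parse_locus(c("m1", "m2")), "single")
})

test_that("default age class table honours the published anchor correlations", {
  tab <- default_age_classes()
  expect_equal(nrow(tab), 17L)
  get <- function(id) tab[tab$class_id == id, ]

  expect_equal(get("I")$start_years, 1.5 / 12)     # I begins at 1.5 months
  expect_equal(get("II")$end_years, 4 / 12)        # II ends at 4 months
  expect_equal(get("IV")$start_years, 1)           # IV = 1-1.5 y
  expect_equal(get("IV")$end_years, 1.5)
  expect_equal(get("V")$end_years, 3)              # V ends at 3 y (weaning)
  expect_equal(get("VI")$start_years, 3)           # VI-VII = 3-4 y
  expect_equal(get("VII")$end_years, 4)
  expect_equal(get("VIII")$end_years, 7)           # VIII ends at 7 y
  expect_equal(get("IX")$start_years, 7)           # IX = 7-9 y
  expect_equal(get("IX")$end_years, 9)
  expect_equal(get("X")$end_years, 11)             # X ends at 11 y
  expect_equal(get("XVI")$end_years, 40)           # lifespan terminus

  # classes tile [0, lifespan] with positive durations
  expect_equal(tab$start_years[1], 0)
  expect_true(all(tab$end_years > tab$start_years))
  expect_equal(tab$start_years[-1], tab$end_years[-17])
})

test_that("ontogenetic stages partition the age classes", {
  ids <- age_class_ids()
  stages <- stage_of(ids)
  expect_equal(stages[ids %in% c("0", "I", "II", "III", "IV", "V")],
               rep("juvenile", 6))
  expect_equal(stages[ids %in% c("VI", "VII", "VIII")], rep("subadult", 3))
  expect_equal(stages[ids %in% c("IX", "X", "XI", "XII", "XIII", "XIV",
                                 "XV", "XVI")], rep("adult", 8))
  expect_true(all(stages %in% c("juvenile", "subadult", "adult")))
  expect_error(stage_of("XVII"), "unknown age class")
})

test_that("lifespan fractions match the published percent-of-lifespan spans", {
  # classes I and II combined span 0.31 to 0.83% of the 40-year lifespan
  fr <- lifespan_fraction(c("I", "II"))
  expect_equal(fr$start_pct[1], 0.3125, tolerance = 1e-9)
  expect_equal(fr$end_pct[2], 0.8333333, tolerance = 1e-6)
  # class IV spans 2.5 to 3.75%
  fr4 <- lifespan_fraction("IV")
  expect_equal(fr4$start_pct, 2.5)
  expect_equal(fr4$end_pct, 3.75)
  # terminal class ends at 100%
  expect_equal(lifespan_fraction("XVI")$end_pct, 100)
  # monotone in class order
  all_fr <- lifespan_fraction(age_class_ids())
  expect_true(all(diff(all_fr$start_pct) > 0))
  expect_true(all(diff(all_fr$end_pct) > 0))
})

test_that("default wear-age lookup satisfies the eruption constraints", {
  lk <- default_wear_age_lookup()
  expect_equal(nrow(lk), 200L)  # 20 loci x 10 stages

  # every key maps to a non-empty contiguous class set (validated on read,
  # re-checked here through the public accessor)
  ids <- age_class_ids()
  for (i in seq_len(nrow(lk))) {
    cls <- age_classes_for(lk$locus[i], lk$wear_stage[i], lk)
    expect_gte(length(cls), 1L)
    expect_true(all(diff(match(cls, ids)) == 1L))
  }

  # first permanent molars erupt at the juvenile/subadult boundary
  expect_equal(age_classes_for("m1", 1, lk), "VI")
  expect_equal(age_classes_for("M1", 1, lk), "VI")
  # third molars are in place by class VIII and wear out at the terminus
  expect_equal(age_classes_for("m3", 1, lk), "VIII")
  expect_true("XVI" %in% age_classes_for("m3", 10, lk))
  # milk teeth are never functional beyond class VII
  milk <- grep("^[dD]", unique(lk$locus), value = TRUE)
  for (loc in milk) {
    classes <- unlist(lapply(1:10, function(s) age_classes_for(loc, s, lk)))
    expect_lte(max(match(classes, ids)) - 1L, 7L)
  }
  # wear is monotone in age: class windows never move backwards
  for (loc in unique(lk$locus)) {
    starts <- vapply(1:10, function(s) {
      min(match(age_classes_for(loc, s, lk), ids))
    }, numeric(1))
    expect_true(all(diff(starts) >= 0))
  }
})

test_that("packaged lookup CSV is identical to the in-code builder", {
  shipped <- default_wear_age_lookup()
  built <- build_wear_age_lookup()
  expect_equal(as.data.frame(shipped), as.data.frame(built))
})

test_that("lookup gaps and invalid stages are reported", {
  lk <- toy_lookup()
  expect_equal(age_classes_for("m1", 1, lk), c("V", "VI"))
  expect_error(age_classes_for("m1", 3, lk), "m1.*stage 3")
  expect_error(age_classes_for("m1", 0, lk), "1-10")
  expect_error(age_classes_for("m1", 11, lk), "1-10")
})
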