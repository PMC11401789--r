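test_that("hypsodonty index classifies crown height against width", {
  hi <- hypsodonty_index(c(1.31, 1.55, 2.6) * 30, rep(30, 3))
  expect_equal(hi$index, c(1.31, 1.55, 2.6))
  expect_equal(hi$class, c("brachyodont", "mesodont", "hypsodont"))
  # height equal to width: index 1, low-crowned
  expect_equal(hypsodonty_index(25, 25)$index, 1)
  expect_error(hypsodonty_index(30, 0), "width_mm")
  expect_error(hypsodonty_index(-1, 30), "crown_height_mm")
})

test_that("mesowear eligibility is upper molars at average wear only", {
  expect_true(mesowear_eligible(tooth(locus = "M2", wear = 5)))
  expect_false(mesowear_eligible(tooth(locus = "M1", wear = 8)))   # too worn
  expect_false(mesowear_eligible(tooth(locus = "M1", wear = 3)))   # too fresh
  expect_false(mesowear_eligible(tooth(locus = "m2", wear = 5)))   # lower
  expect_false(mesowear_eligible(tooth(locus = "P4", wear = 5)))   # premolar
  expect_false(mesowear_eligible(tooth(locus = "D3", wear = 5)))   # milk tooth
  expect_false(mesowear_eligible(tooth(locus = "M2", wear = 5, damaged = TRUE)))
  expect_false(mesowear_eligible(tooth(locus = "M2", wear = NA)))
})

test_that("hypoplasia eligibility excludes very worn and damaged teeth", {
  expect_false(hypoplasia_eligible(tooth(wear = 9)))
  expect_false(hypoplasia_eligible(tooth(wear = 10)))
  expect_true(hypoplasia_eligible(tooth(wear = 5)))
  expect_false(hypoplasia_eligible(tooth(wear = 3, damaged = TRUE)))
  expect_true(hypoplasia_eligible(tooth(wear = NA)))  # unscored wear kept
})

test_that("score summaries report n, mean and sample sd per group", {
  s <- summarize_scores(c(1, 2, 2, 2), rep("a", 4))
  expect_equal(s$n, 4L)
  expect_equal(s$mean, 1.75)
  expect_equal(s$sd, sd(c(1, 2, 2, 2)))
  # a single score has no sample sd
  one <- summarize_scores(3, "a")
  expect_true(is.na(one$sd))
  # empty input: empty frame, no groups invented
  expect_equal(nrow(summarize_scores(numeric(0), character(0))), 0L)
})

test_that("mesowear summary deduplicates specimens preferring second molars", {
  rec <- assemblage(
    tooth("A", locus = "M1", wear = 5, mesowear_score = 0L),
    tooth("A", locus = "M2", wear = 5, mesowear_score = 2L),  # preferred
    tooth("B", locus = "M3", wear = 6, mesowear_score = 1L),
    tooth("C", locus = "M2", wear = 4, mesowear_score = 3L)
  )
  s <- mesowear_summary(rec)
  expect_equal(s$n, 3L)
  expect_equal(s$mean, mean(c(2, 1, 3)))
  # duplicating an already-counted tooth's specimen changes nothing
  rec_dup <- rbind(rec, tooth("A", locus = "M3", wear = 5, mesowear_score = 6L))
  expect_equal(mesowear_summary(rec_dup)$mean, s$mean)
})

test_that("moments of generated mesowear scores are recovered", {
  set.seed(11)
  n <- 16
  scores <- rbinom(n, 6, 1.75 / 6)
  s <- summarize_scores(scores, rep("sp", n))
  # binomial mean 1.75, sd ~0.85; the summary must match the sample exactly
  expect_equal(s$mean, mean(scores))
  expect_equal(s$sd, sd(scores))
  expect_lt(abs(s$mean - 1.75), 3 * sqrt(6 * (1.75 / 6) * (1 - 1.75 / 6) / n))
})

test_that("prevalence reproduces counts, frequencies and marginals", {
  counts <- load_fixture("table4_hypoplasia")
  rec <- expand_hypoplasia_counts(counts)
  rec <- rec[hypoplasia_eligible(rec), ]
  tab <- prevalence(rec, by = "locus")

  total <- tab[tab$group == "TOTAL", ]
  expect_equal(total$affected, 79)
  expect_equal(total$n, 466)
  expect_equal(total$frequency, 100 * 79 / 466)
  # per-locus marginals sum to the total
  body <- tab[tab$group != "TOTAL", ]
  expect_equal(sum(body$affected), total$affected)
  expect_equal(sum(body$n), total$n)
  # frequencies recompute exactly from counts and stay in [0, 100]
  expect_equal(body$frequency, 100 * body$affected / body$n)
  expect_true(all(body$frequency >= 0 & body$frequency <= 100))

  # adding an ineligible tooth (very worn) then filtering changes nothing
  rec2 <- rbind(rec, tooth("worn", locus = "p3", wear = 9, hypoplasia_n = 1L))
  rec2 <- rec2[hypoplasia_eligible(rec2), ]
  expect_equal(prevalence(rec2, by = "locus"), tab)
})

test_that("two-group rank comparison agrees with a first-principles H", {
  # identical groups carry no rank signal
  expect_equal(rank_compare(c(1, 2, 3), c(1, 2, 3))$H, 0)
  # degenerate: all pooled values equal
  d <- rank_compare(c(2, 2), c(2, 2, 2))
  expect_equal(d$H, 0)
  expect_equal(d$p, 1)
  # completely separated groups: H from the exhaustive rank formula
  a <- c(1, 2, 3); b <- c(10, 11, 12)
  expect_equal(rank_compare(a, b)$H, brute_force_kw(a, b))
  # tied data: tie-corrected H still matches
  a2 <- c(1, 2, 2, 5); b2 <- c(2, 3, 3)
  expect_equal(rank_compare(a2, b2)$H, brute_force_kw(a2, b2))
})

test_that("rank test holds its nominal type-I error rate", {
  set.seed(202)
  reps <- 1000
  p <- replicate(reps, {
    rank_compare(rnorm(10), rnorm(10))$p
  })
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("DMTA summaries split by species and facet", {
  rec <- rbind(
    data.frame(specimen_id = sprintf("G%d", 1:4), species = "sp1",
               dmta_facet = "grinding", dmta_neweplsar = c(1.5, 1.7, 1.8, 1.6),
               dmta_asfc = c(1.7, 1.8, 1.6, 1.7), dmta_hasfc9 = 0.3,
               dmta_hasfc81 = 0.6, stringsAsFactors = FALSE),
    data.frame(specimen_id = "S1", species = "sp1",
               dmta_facet = "shearing", dmta_neweplsar = 1.9,
               dmta_asfc = 1.0, dmta_hasfc9 = 0.3, dmta_hasfc81 = 0.5,
               stringsAsFactors = FALSE)
  )
  s <- dmta_summary(rec)
  gr <- s[s$facet == "grinding" & s$variable == "neweplsar", ]
  expect_equal(gr$n, 4L)
  expect_equal(gr$mean, mean(c(1.5, 1.7, 1.8, 1.6)))
  sh <- s[s$facet == "shearing" & s$variable == "asfc", ]
  expect_equal(sh$n, 1L)
  expect_true(is.na(sh$sd))
})
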