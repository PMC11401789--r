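test_that("isolated teeth get equal weight over their admissible classes", {
  lk <- toy_lookup()
  # one tooth mapping to two classes: 1/2 each
  a <- assign_ages(tooth(locus = "m1", wear = 1), lookup = lk)
  expect_equal(nrow(a), 2L)
  expect_equal(sort(a$class_id), c("V", "VI"))
  expect_equal(a$weight, c(0.5, 0.5))
  # one tooth mapping to a single class: weight 1
  b <- assign_ages(tooth(locus = "m1", wear = 2), lookup = lk)
  expect_equal(b$class_id, "IX")
  expect_equal(b$weight, 1)
})

test_that("associated teeth intersect their class sets into one individual", {
  lk <- toy_lookup()
  rec <- assemblage(
    tooth(specimen_id = "S1", locus = "m2", wear = 1, association_id = "G"),
    tooth(specimen_id = "S2", locus = "m2", wear = 2, association_id = "G")
  )
  a <- assign_ages(rec, lookup = lk)  # {VI,VII} * {VII,VIII} -> {VII}
  expect_equal(length(unique(a$individual_id)), 1L)
  expect_equal(a$class_id, "VII")
  expect_equal(a$weight, 1)

  # incompatible association is an error naming the members
  bad <- assemblage(
    tooth(specimen_id = "S1", locus = "m1", wear = 2, association_id = "G"),
    tooth(specimen_id = "S2", locus = "m2", wear = 1, association_id = "G")
  )
  expect_error(assign_ages(bad, lookup = lk), "incompatible.*S1.*S2")
})

test_that("unresolvable wear stages raise a lookup-gap error", {
  expect_error(assign_ages(tooth(locus = "m1", wear = 9), lookup = toy_lookup()),
               "no wear-age lookup entry.*m1 stage 9")
})

test_that("mortality curves conserve weight and divide by class duration", {
  lk <- toy_lookup()
  # three individuals all in IX: point mass
  rec <- assemblage(tooth("A", locus = "m3", wear = 1),
                    tooth("B", locus = "m3", wear = 1),
                    tooth("C", locus = "m3", wear = 1))
  cv <- build_curve(assign_ages(rec, lookup = lk))
  expect_equal(cv$raw[cv$class_id == "IX"], 3)
  expect_equal(sum(cv$raw), 3)
  expect_equal(attr(cv, "n_individuals"), 3L)
  # corrected = raw / duration for every class (IX spans 7-9 y: 3/2 per yr)
  expect_equal(cv$corrected, cv$raw / (cv$end_years - cv$start_years))
  expect_equal(cv$corrected[cv$class_id == "IX"], 1.5)

  # mixed fractional weights still sum to the number of individuals
  rec4 <- assemblage(tooth("A", locus = "m1", wear = 1),
                     tooth("B", locus = "m2", wear = 1),
                     tooth("C", locus = "m2", wear = 2),
                     tooth("D", locus = "m3", wear = 1))
  cv4 <- build_curve(assign_ages(rec4, lookup = lk))
  expect_equal(sum(cv4$raw), 4)
  expect_error(build_curve(assign_ages(tooth(wear = NA))), "empty")
})

test_that("age structure routes fractional weight through the stages", {
  lk <- toy_lookup()
  # all weight on a juvenile class
  s1 <- age_structure(data.frame(individual_id = "i", class_id = "IV",
                                 weight = 1))
  expect_equal(unname(s1), c(100, 0, 0))
  # half-juvenile, half-subadult individual
  s2 <- age_structure(data.frame(individual_id = "i",
                                 class_id = c("V", "VI"),
                                 weight = c(0.5, 0.5)))
  expect_equal(unname(s2), c(50, 50, 0))
  # percentages always sum to 100
  rec <- assemblage(tooth("A", locus = "m1", wear = 1),
                    tooth("B", locus = "m3", wear = 1))
  expect_equal(sum(age_structure(assign_ages(rec, lookup = lk))), 100)
})

test_that("curve comparison matches a brute-force KS statistic", {
  lk <- toy_lookup()
  recA <- assemblage(tooth("A", locus = "m3", wear = 1),
                     tooth("B", locus = "m3", wear = 1))
  recB <- assemblage(tooth("C", locus = "m2", wear = 1),
                     tooth("D", locus = "m3", wear = 1))
  cvA <- build_curve(assign_ages(recA, lookup = lk))
  cvB <- build_curve(assign_ages(recB, lookup = lk))

  same <- compare_curves(cvA, cvA)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)

  both <- compare_curves(cvA, cvB)
  expect_equal(both$D, brute_force_ks(cvA$corrected, cvB$corrected))
  expect_true(both$p >= 0 && both$p <= 1)

  # disjoint point masses on distinct corrected values give D = 1
  x <- data.frame(class_id = c("a", "b"), corrected = c(1, 1), raw = 1)
  y <- data.frame(class_id = c("a", "b"), corrected = c(2, 2), raw = 1)
  expect_equal(compare_curves(x, y)$D, 1)
})

test_that("MNI counts sided elements and applies eruption incompatibility", {
  # empty assemblage
  empty <- tooth()[0, ]
  expect_equal(mni(empty)$overall, 0L)

  # most abundant sided element: 3 left m1 vs 2 right m1
  rec <- assemblage(
    tooth("A", locus = "m1", side = "left"), tooth("B", locus = "m1", side = "left"),
    tooth("C", locus = "m1", side = "left"), tooth("D", locus = "m1", side = "right"),
    tooth("E", locus = "m1", side = "right")
  )
  expect_equal(mni(rec, groups = list())$simple, 3L)
  expect_equal(mni(rec, groups = list())$overall, 3L)

  # eruption incompatibility, group b: no individual bears milk teeth and a
  # fourth premolar in one functioning row, so 2 left P4 + 2 left D4 +
  # 1 right D4 force at least 2 + max(2, 1) = 4 individuals
  rec_b <- assemblage(
    tooth("A", locus = "P4", side = "left"), tooth("B", locus = "P4", side = "left"),
    tooth("C", locus = "D4", side = "left"), tooth("D", locus = "D4", side = "left"),
    tooth("E", locus = "D4", side = "right")
  )
  res <- mni(rec_b)
  expect_equal(res$simple, 2L)
  expect_equal(unname(res$by_group["b"]), 4)
  expect_equal(res$overall, 4L)

  # associated teeth count once; unknown sides join no sided maximum
  rec_assoc <- assemblage(
    tooth("A", locus = "m1", side = "left", association_id = "G"),
    tooth("A", locus = "m2", side = "left", association_id = "G"),
    tooth("B", locus = "m1", side = "unknown")
  )
  expect_equal(mni(rec_assoc, groups = list())$simple, 1L)
})
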