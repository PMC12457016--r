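test_that("the coarse maternal relatedness scheme assigns each category", {
  p <- relatedness_pedigree()
  expect_equal(relatedness(p, "A", "GM"), 0.5)     # mother-offspring
  expect_equal(relatedness(p, "A", "B"), 0.25)     # maternal sisters
  expect_equal(relatedness(p, "GM", "C"), 0.25)    # grandmother-granddaughter
  expect_equal(relatedness(p, "A", "D"), 0.125)    # aunt-niece
  expect_equal(relatedness(p, "C", "D"), 0.0625)   # first cousins
  expect_equal(relatedness(p, "E", "D"), 0.03125)  # beyond first cousins
  expect_equal(relatedness(p, "U", "V"), 0)        # both mothers unknown
  expect_equal(relatedness(p, "A", "U"), 0)        # undetectable
})

test_that("relatedness is symmetric and confined to the scheme's values", {
  allowed <- c(0, 0.03125, 0.0625, 0.125, 0.25, 0.5)
  set.seed(3)
  for (rep in 1:5) {
    n <- 12
    ids <- paste0("x", seq_len(n))
    mother <- rep(NA_character_, n)
    for (k in 3:n) {
      if (runif(1) < 0.8) mother[k] <- ids[sample.int(k - 1, 1)]
    }
    p <- pedigree(data.frame(id = ids, mother_id = mother))
    for (draw in 1:20) {
      ij <- sample(ids, 2)
      r1 <- relatedness(p, ij[1], ij[2])
      expect_identical(r1, relatedness(p, ij[2], ij[1]))
      expect_true(r1 %in% allowed)
    }
  }
})

test_that("pedigree construction rejects maternal cycles", {
  expect_error(pedigree(data.frame(id = c("a", "b"), mother_id = c("b", "a"))),
               "cycle")
})

test_that("reproductive state follows the gestation and dependency rules", {
  fission_day <- as.Date("2020-06-01")
  ind <- rbind(mk_individuals("F1"), mk_individuals(c("I1", "I2")))
  mk_ds <- function(birth, death = NA) {
    behavior_dataset(ind, births = data.frame(
      mother_id = "F1", infant_id = "I1", birth_date = as.Date(birth),
      death_date = as.Date(death), stringsAsFactors = FALSE))
  }
  # birth 100 days after fission: inside the 176-day gestation window
  st <- reproductive_state(mk_ds(fission_day + 100), "F1", fission_day)
  expect_true(st$pregnant); expect_false(st$lactating); expect_true(st$at_risk)
  # birth 177 days after: not yet pregnant
  expect_false(reproductive_state(mk_ds(fission_day + 177), "F1",
                                  fission_day)$pregnant)
  # infant aged 400 days and alive: no longer nursing
  st <- reproductive_state(mk_ds(fission_day - 400), "F1", fission_day)
  expect_false(st$lactating); expect_false(st$at_risk)
  # infant born 90 days before fission but died at 60 days old
  st <- reproductive_state(mk_ds(fission_day - 90, fission_day - 30), "F1",
                           fission_day)
  expect_false(st$lactating); expect_false(st$at_risk)
  # birth exactly on the fission date counts as lactation, not pregnancy
  st <- reproductive_state(mk_ds(fission_day), "F1", fission_day)
  expect_false(st$pregnant); expect_true(st$lactating)
  # no births at all
  ds0 <- behavior_dataset(mk_individuals("F1"))
  expect_false(reproductive_state(ds0, "F1", fission_day)$at_risk)
})

test_that("residency needs seven consecutive sole observation days", {
  ind <- rbind(mk_individuals("F1"),
               mk_individuals(c("M1", "M2"), sex = "male"))
  # observation days with gaps: consecutive means consecutive census days
  days <- as.Date("2020-01-01") +
    c(0, 3, 5, 9, 12, 16, 20, 23, 27, 30, 33, 37, 40, 44, 47, 51, 54, 58)
  mk_census <- function(male_days) {
    rbind(census_rows(days, "P", "F1"),
          do.call(rbind, lapply(names(male_days), function(m)
            census_rows(male_days[[m]], "P", m))))
  }
  # sole for exactly 7 observation days: resident, backdated to day 1
  ds <- behavior_dataset(ind, census = mk_census(list(M1 = days[1:7])))
  tl <- residency_timeline(ds, "P")
  expect_equal(nrow(tl), 1)
  expect_equal(tl$male_id, "M1")
  expect_equal(tl$start_date, days[1])
  # sole for 6 days, then a second male appears: never resident
  ds <- behavior_dataset(ind, census = mk_census(
    list(M1 = days[1:7], M2 = days[7])))
  expect_equal(nrow(residency_timeline(ds, "P")), 0)
  # resident then absent 7 consecutive observation days: interval closes on
  # the last day he was present
  ds <- behavior_dataset(ind, census = mk_census(list(M1 = days[1:8])))
  tl <- residency_timeline(ds, "P")
  expect_equal(nrow(tl), 1)
  expect_equal(tl$end_date, days[8])
  # still present at the last census: tenure open-ended
  ds <- behavior_dataset(ind, census = mk_census(list(M1 = days)))
  tl <- residency_timeline(ds, "P")
  expect_true(is.na(tl$end_date))
  expect_equal(resident_at(ds, "P", days[10]), "M1")
})

test_that("residency intervals never overlap within a group", {
  ind <- rbind(mk_individuals("F1"),
               mk_individuals(c("M1", "M2"), sex = "male"))
  days <- as.Date("2020-01-01") + seq(0, 120, by = 3)
  census <- rbind(
    census_rows(days, "P", "F1"),
    census_rows(days[1:10], "P", "M1"),    # M1 resident, then vanishes
    census_rows(days[18:41], "P", "M2"))   # M2 takes over
  ds <- behavior_dataset(ind, census = census)
  tl <- residency_timeline(ds, "P")
  expect_equal(tl$male_id, c("M1", "M2"))
  expect_true(all(tl$start_date[-1] > tl$end_date[-nrow(tl)]))
})
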