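test_that("dyadic rates follow their definitions", {
  ind <- mk_individuals(c("F1", "F2"))
  w <- as.Date(c("2019-01-01", "2019-12-31"))
  scans <- rbind(
    scan_rows("F1", "2019-03-01", 10, "social_groom", partner = "F2"),
    scan_rows("F1", "2019-03-01", 90, "feed", minute0 = 10),
    scan_rows("F2", "2019-04-01", 10, "social_groom", partner = "F1"),
    scan_rows("F2", "2019-04-01", 90, "rest", minute0 = 10))
  ds <- behavior_dataset(ind, focal_scans = scans)
  r <- dyad_rates(ds, "F1", "F2", w)
  expect_equal(r$G_ij, 20 / 200)  # grooming over combined focal time
  expect_equal(r$R_ij, 0)         # no proximity records at all
  expect_equal(r$R_ji, 0)
  expect_false(r$single_focal)
  # order of the pair does not matter
  r2 <- dyad_rates(ds, "F2", "F1", w)
  expect_equal(r2$G_ij, r$G_ij)

  # single-focal dyad: only the followed member's proximity rate is defined
  scans1 <- rbind(
    scan_rows("F1", "2019-03-01", 30, "rest", prox = "F2"),
    scan_rows("F1", "2019-03-01", 90, "feed", minute0 = 30))
  ds1 <- behavior_dataset(ind, focal_scans = scans1)
  r1 <- dyad_rates(ds1, "F1", "F2", w)
  expect_true(r1$single_focal)
  expect_equal(r1$R_ij, 30 / 120)
  expect_true(is.na(r1$R_ji))
  # a dyad with no focal data at all cannot be indexed
  expect_error(dyad_rates(ds1, "F1", "F2", as.Date(c("2021-01-01", "2021-12-31"))),
               "neither member")
})

test_that("only resting proximity enters the index by default", {
  ind <- mk_individuals(c("F1", "F2"))
  w <- as.Date(c("2019-01-01", "2019-12-31"))
  scans <- rbind(
    scan_rows("F1", "2019-03-01", 50, "feed", prox = "F2"),   # 7 m radius
    scan_rows("F1", "2019-03-01", 50, "rest", prox = "F2", minute0 = 50),
    scan_rows("F2", "2019-03-02", 100, "feed"))
  ds <- behavior_dataset(ind, focal_scans = scans)
  expect_equal(dyad_rates(ds, "F1", "F2", w)$R_ij, 50 / 100)
  expect_equal(dyad_rates(ds, "F1", "F2", w, rest_only = FALSE)$R_ij, 100 / 100)
})

test_that("DSI weights and zero-median handling behave as specified", {
  med <- list(G_med = 0.02, R_med = 0.05)
  at_median <- list(i_id = "a", j_id = "b", G_ij = 0.02, R_ij = 0.05,
                    R_ji = 0.05, single_focal = FALSE)
  expect_identical(compute_dsi(at_median, med), 1)
  doubled <- list(G_ij = 0.04, R_ij = 0.1, R_ji = 0.1, single_focal = FALSE)
  expect_identical(compute_dsi(doubled, med), 2)
  single <- list(G_ij = 0.04, R_ij = 0.05, R_ji = NA_real_, single_focal = TRUE)
  expect_equal(compute_dsi(single, med), 0.5 * 2 + 0.5 * 1)

  zero_g <- list(G_med = 0, R_med = 0.05)
  expect_error(compute_dsi(at_median, zero_g), "G_med")
  # fallback renormalises the remaining weights to sum to 1
  expect_equal(compute_dsi(at_median, zero_g, on_zero_median = "drop_term"), 1)
  expect_equal(compute_dsi(doubled, zero_g, on_zero_median = "drop_term"), 2)
})

test_that("DSI is invariant to rescaling all grooming rates in a group", {
  set.seed(1)
  n <- 10
  rates <- data.frame(
    i_id = paste0("a", 1:n), j_id = paste0("b", 1:n),
    G_ij = runif(n, 0, 0.05), R_ij = runif(n, 0, 0.1),
    R_ji = runif(n, 0, 0.1), single_focal = FALSE)
  med <- group_medians(rates)
  dsi <- vapply(seq_len(n), function(k) compute_dsi(rates[k, ], med), numeric(1))
  for (c_scale in c(0.25, 3, 17)) {
    scaled <- rates
    scaled$G_ij <- scaled$G_ij * c_scale
    med_s <- group_medians(scaled)
    dsi_s <- vapply(seq_len(n), function(k) compute_dsi(scaled[k, ], med_s),
                    numeric(1))
    expect_equal(dsi_s, dsi, tolerance = 1e-12)
  }
  # the grooming component has median exactly 1 by construction
  expect_equal(median(rates$G_ij / med$G_med), 1)
})

test_that("consistency classes follow the two-year threshold rule", {
  cls <- classify_consistency(c(1.5, 0.5, 1.5, 1.0, 1.0),
                              c(2.0, 0.2, 0.5, 1.0, 1.5))
  expect_equal(as.character(cls$consistency),
               c("consistently_strong", "consistently_weak", "inconsistent",
                 "consistently_weak",  # exactly at threshold binned weak
                 "inconsistent"))
  expect_equal(cls$dummy_strong, c(1L, 0L, 0L, 0L, 0L))
  expect_equal(cls$dummy_weak, c(0L, 1L, 0L, 1L, 0L))
  expect_true(all(cls$dummy_strong + cls$dummy_weak <= 1))
})

test_that("eligibility requires half the pre-fission year as an adult", {
  onset <- as.Date("2020-01-01")
  fis <- one_fission(onset = onset)
  adultdates <- c(full = onset - 800,
                  half = onset - 183,      # exactly half of the 365-day window
                  late = onset - 100)      # 27% of the window
  ind <- mk_individuals(names(adultdates), adult = as.Date(adultdates))
  ind$birth_date <- as.Date("2005-01-01")
  days <- seq(onset - 730, onset, by = 7)
  ds <- behavior_dataset(ind, census = census_rows(days, "P", ind$id),
                         fissions = fis)
  expect_setequal(eligible_females(ds, fis), c("full", "half"))
})

test_that("sociality table classifies a symmetric group as uniformly weak", {
  ds <- symmetric_group_dataset()
  fis <- ds$fissions[1, ]
  tab <- sociality_table(ds, fis)
  expect_equal(nrow(tab), choose(4, 2))  # 4 eligible females -> 6 dyads
  expect_equal(tab$dsi_y1, rep(1, 6))
  expect_equal(tab$dsi_y2, rep(1, 6))
  # DSI exactly 1 in both years bins with the weak side by convention
  expect_true(all(tab$consistency == "consistently_weak"))
})

test_that("females without focal data contribute via partners' follows", {
  ds <- symmetric_group_dataset()
  fis <- ds$fissions[1, ]
  # F4 becomes adult early in the pre-fission year: eligible for year 1
  # (covers > half) but was not a focal subject in year 2
  ds$individuals$adult_from[ds$individuals$id == "F4"] <-
    as.Date(fis$subgrouping_onset) - 360
  ds$focal_scans <- ds$focal_scans[!(ds$focal_scans$focal_id == "F4" &
    ds$focal_scans$date < as.Date(fis$subgrouping_onset) - 365), ]
  tab <- sociality_table(ds, fis)
  expect_equal(nrow(tab), 6)
  f4 <- tab[tab$i_id == "F4" | tab$j_id == "F4", ]
  expect_true(all(is.finite(f4$dsi_y2)))
  expect_true(all(f4$dsi_y2 > 0))  # partners still recorded her
})

test_that("female-male DSI weights grooming and proximity equally", {
  ds <- symmetric_group_dataset()
  fis <- ds$fissions[1, ]
  onset <- as.Date(fis$subgrouping_onset)
  # give each female some male-directed behaviour in year 1; F1 twice the
  # grooming of the others, identical proximity
  extra <- list()
  for (f in paste0("F", 1:4)) {
    g <- if (f == "F1") 8 else 4
    extra[[f]] <- rbind(
      scan_rows(f, onset - 100, g, "social_groom", partner = "M1",
                minute0 = 500),
      scan_rows(f, onset - 100, 6, "rest", prox = "M1", minute0 = 600),
      # filler so every female has identical focal minutes
      scan_rows(f, onset - 100, 12 - g, "feed", minute0 = 700))
  }
  ds$focal_scans <- rbind(ds$focal_scans, do.call(rbind, extra))
  md <- male_dsi(ds, fis, resident_male = "M1")
  expect_equal(nrow(md), 4)
  base <- md$dsi_with_resident[md$female_id == "F2"]
  expect_equal(base, 1)  # at both medians
  f1 <- md$dsi_with_resident[md$female_id == "F1"]
  # equal focal minutes, so F1's grooming ratio is 2 and the proximity
  # ratio 1: DSI = 0.5 * 2 + 0.5 * 1
  expect_equal(f1, 1.5)
})
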