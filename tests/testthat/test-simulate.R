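small_cfg <- function(seed = 1, focal_minutes = 240, ...) {
  sim_config(seed = seed, n_groups = 2, females_per_group = 8,
             n_matrilines = 3, focal_minutes_per_female_year = focal_minutes,
             obs_days_per_year = 80, ...)
}

test_that("the generator is deterministic under a fixed seed", {
  s1 <- simulate_study(small_cfg(5))
  s2 <- simulate_study(small_cfg(5))
  expect_identical(s1$dataset, s2$dataset)
  expect_identical(s1$truth$dyads, s2$truth$dyads)
  s3 <- simulate_study(small_cfg(6))
  expect_false(identical(s1$dataset$focal_scans, s3$dataset$focal_scans))
})

test_that("emitted datasets satisfy every schema invariant", {
  for (mode in c("choice_first", "dyad_target")) {
    sim <- simulate_study(small_cfg(9), mode = mode)
    expect_silent(validate_dataset(sim$dataset))
    # one resident male per group with a qualifying tenure at fission
    for (g in unique(sim$truth$males$group_id)) {
      res <- resident_at(sim$dataset, g, sim$dataset$fissions$fission_date[1])
      expect_equal(res, sim$truth$males$resident_id[
        sim$truth$males$group_id == g])
    }
  }
})

test_that("configs that cannot generate data are rejected", {
  expect_error(sim_config(focal_minutes_per_female_year = 10), "too small")
  expect_error(sim_config(frac_strong = 0.8, frac_weak = 0.5), "exceed")
  expect_error(sim_config(p_groom = 0.6, p_rest = 0.3, p_feed = 0.3), "sum")
  expect_error(sim_config(females_per_group = 3), "females per group")
})

test_that("without upsets the hierarchy is recovered exactly", {
  cfg <- small_cfg(12, upset_prob = 0, agonistic_rate = 6)
  sim <- simulate_population(cfg)
  g <- "G01"
  fem <- sim$truth$females[sim$truth$females$group_id == g, ]
  m <- build_contest_matrix(sim$dataset, g, 2017,
                            until = sim$truth$dates$fission, ids = fem$id)
  h <- isi_order(m, seed = 1)
  expect_equal(h$I, 0L)
  expect_equal(unname(h$ranks[fem$id]), fem$latent_rank)
})

test_that("the at-risk fraction tracks its target within binomial error", {
  at_risk <- unlist(lapply(1:6, function(s) {
    simulate_truth(sim_config(seed = 100 + s))$females$at_risk
  }))
  n <- length(at_risk)  # 6 studies x 75 females
  expect_lt(abs(mean(at_risk) - 0.41), 3 * sqrt(0.41 * 0.59 / n))
})

test_that("true DSI classes separate the DSI estimates from the records", {
  sim <- simulate_study(small_cfg(33, focal_minutes = 420))
  fis <- sim$dataset$fissions[1, ]
  soc <- sociality_table(sim$dataset, fis)
  tr <- sim$truth$dyads[sim$truth$dyads$group_id == fis$parent_group_id, ]
  key <- paste(soc$i_id, soc$j_id)
  m <- match(key, paste(tr$i_id, tr$j_id))
  agree <- mean(
    (tr$class[m] == "strong" & soc$consistency == "consistently_strong") |
    (tr$class[m] == "weak" & soc$consistency == "consistently_weak") |
    (tr$class[m] == "inconsistent" & soc$consistency == "inconsistent"))
  expect_gt(agree, 0.7)
})

test_that("dyad-level Bernoulli outcomes follow the generating law", {
  cfg <- sim_config(seed = 77, beta = c(
    intercept = log(0.8), dummy_strong = 0, dummy_weak = 0, relatedness = 0,
    risk_match = 0, relatedness_x_riskmatch = 0, rankdist_z = 0))
  rate <- mean(vapply(1:20, function(r) {
    tr <- simulate_truth(sim_config(seed = 77 + r, beta = cfg$beta))
    persistence_rate(simulate_dyad_outcomes(tr))
  }, numeric(1)))
  expect_equal(rate, plogis(log(0.8)), tolerance = 0.02)
})

test_that("strong ties are co-assigned far above baseline in dyad-target mode", {
  cfg <- sim_config(seed = 3, n_groups = 1, beta = c(
    intercept = log(0.5), dummy_strong = log(8), dummy_weak = 0,
    relatedness = 0, risk_match = 0, relatedness_x_riskmatch = 0,
    rankdist_z = 0))
  tr <- simulate_truth(cfg)
  rates <- vapply(1:40, function(r) {
    fis <- simulate_fission(cfg, tr, mode = "dyad_target", seed = 9000 + r)
    d <- truth_persistence_dataset(tr, fis$assignments)
    c(strong = mean(d$persisted[d$dummy_strong == 1]),
      other = mean(d$persisted[d$dummy_strong == 0]))
  }, c(strong = 0, other = 0))
  expect_gt(mean(rates["strong", ]) - mean(rates["other", ]), 0.15)
})

test_that("choice-first assignments follow the conditional-logit law", {
  # resident-male main effect only: P(join his group) = 3.63/4.63 at any DSI
  with_male <- unlist(lapply(1:8, function(r) {
    cfg <- sim_config(seed = 8 + r, n_groups = 5, females_per_group = 12,
                      n_matrilines = 4,
                      gamma_at_risk = c(resident_present = log(3.63),
                                        resident_x_dsi = 0),
                      gamma_not_at_risk = c(resident_present = log(3.63),
                                            resident_x_dsi = 0),
                      min_daughter = 0)
    tr <- simulate_truth(cfg)
    fis <- simulate_fission(cfg, tr, mode = "choice_first")
    side <- setNames(fis$assignments$daughter, fis$assignments$individual_id)
    male_side <- setNames(fis$fissions$resident_male_daughter,
                          fis$fissions$event_id)
    fem <- tr$females
    ev <- paste0("FIS-", fem$group_id)
    side[fem$id] == male_side[ev]
  }))
  p <- mean(with_male)
  n <- length(with_male)
  expect_equal(p, 3.63 / 4.63, tolerance = 3 * sqrt(0.78 * 0.22 / n))
})

test_that("stand-alone choice data reproduce their generating coefficients", {
  d <- simulate_choice_data(2000, seed = 10)
  f <- fit_conditional_logit(d)
  expect_equal(f$coefficients$estimate[1], log(3.63), tolerance = 0.2)
  expect_identical(simulate_choice_data(50, seed = 2),
                   simulate_choice_data(50, seed = 2))
})
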