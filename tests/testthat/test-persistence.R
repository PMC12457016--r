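# Small end-to-end persistence dataset: 4 females split 2/2 with known
# covariates, built through the real pipeline stages.
four_female_pdat <- function() {
  ds <- symmetric_group_dataset()
  # make F2 the daughter of F1 so one dyad is kin
  ds$individuals$mother_id[ds$individuals$id == "F2"] <- "F1"
  ds$individuals$birth_date[ds$individuals$id == "F1"] <- as.Date("1995-01-01")
  fis <- ds$fissions[1, ]
  # F1 and F2 at risk (recent birth), F3 and F4 not
  ds$births <- data.frame(
    mother_id = c("F1", "F2"), infant_id = c("I1", "I2"),
    birth_date = as.Date(fis$fission_date) - 50, death_date = as.Date(NA),
    stringsAsFactors = FALSE)
  ds$individuals <- rbind(ds$individuals, mk_individuals(
    c("I1", "I2"), birth = as.Date(fis$fission_date) - 50,
    mother = c("F1", "F2"), adult = NA))
  ds$agonistic <- data.frame(
    date = as.Date(fis$fission_date) - 10,
    winner_id = c("F1", "F1", "F2", "F1", "F2", "F3"),
    loser_id = c("F2", "F3", "F3", "F4", "F4", "F4"),
    group_id = "P", stringsAsFactors = FALSE)
  soc <- sociality_table(ds, fis)
  h <- isi_order(build_contest_matrix(
    ds, "P", as.integer(format(fis$fission_date, "%Y")),
    until = fis$fission_date, ids = paste0("F", 1:4)), seed = 1)
  st <- female_states(ds, fis)
  build_persistence_dataset(soc, setNames(list(h), fis$event_id), st,
                            pedigree(ds$individuals), ds)
}

test_that("the persistence dataset encodes dyads, outcomes and covariates", {
  d <- four_female_pdat()
  expect_equal(nrow(d), 6)            # 4 females -> 6 within-group dyads
  expect_equal(sum(d$persisted), 2)   # a 2/2 split keeps 2 ties
  kin <- d[d$i_id == "F1" & d$j_id == "F2", ]
  expect_equal(kin$relatedness, 0.5)
  expect_equal(kin$risk_match, 1L)    # both at risk
  expect_equal(kin$relatedness_x_riskmatch, 0.5)
  mixed <- d[d$i_id == "F1" & d$j_id == "F3", ]
  expect_equal(mixed$risk_match, 0L)  # one at risk, one not
  expect_equal(mixed$relatedness_x_riskmatch, 0)
  # perfect transitive contest data: rank distances reflect the F1>F2>F3>F4
  # order, pooled Z-scores have mean 0
  expect_equal(d$rankdist[d$i_id == "F1" & d$j_id == "F4"], 3)
  expect_equal(mean(d$rankdist_z), 0, tolerance = 1e-12)
})

test_that("an intercept-only fit reproduces the empirical persistence rate", {
  tr <- simulate_truth(sim_config(seed = 21, n_groups = 2,
                                  females_per_group = 10))
  d <- simulate_dyad_outcomes(tr)
  f0 <- fit_persistence(d, terms = character(0))
  expect_equal(plogis(f0$coefficients$estimate[1]), persistence_rate(d),
               tolerance = 1e-9)
  expect_equal(persistence_rate(d), mean(d$persisted))
  expect_error(persistence_rate(d[0, ]), "empty")
})

test_that("Newton estimates match an independent glm fit exactly", {
  tr <- simulate_truth(sim_config(seed = 31))
  d <- simulate_dyad_outcomes(tr)
  f <- fit_persistence(d)
  g <- stats::glm(persisted ~ dummy_strong + dummy_weak + relatedness +
                    risk_match + relatedness_x_riskmatch + rankdist_z,
                  binomial, data = d)
  expect_equal(f$coefficients$estimate, unname(coef(g)), tolerance = 1e-8)
  expect_equal(f$coefficients$se, unname(sqrt(diag(vcov(g)))),
               tolerance = 1e-5)
  expect_equal(f$AIC, AIC(g), tolerance = 1e-8)
  expect_equal(f$coefficients$odds_ratio, exp(f$coefficients$estimate))
  expect_equal(f$AIC, 2 * length(f$terms) - 2 * f$logLik)
})

test_that("estimates are invariant to row order and fission relabelling", {
  tr <- simulate_truth(sim_config(seed = 41))
  d <- simulate_dyad_outcomes(tr)
  f1 <- fit_persistence(d)
  set.seed(1)
  d2 <- d[sample.int(nrow(d)), ]
  f2 <- fit_persistence(d2)
  expect_equal(f2$coefficients$estimate, f1$coefficients$estimate,
               tolerance = 1e-9)
  d3 <- d
  d3$fission_id <- paste0("relabelled-", d3$fission_id)
  f3 <- fit_persistence(d3)
  expect_equal(f3$coefficients$estimate, f1$coefficients$estimate)
})

test_that("rank-deficient designs and separation are diagnosed, not fitted", {
  tr <- simulate_truth(sim_config(seed = 51, n_groups = 2,
                                  females_per_group = 8))
  d <- simulate_dyad_outcomes(tr)
  d$dup <- d$dummy_strong
  expect_error(fit_persistence(d, terms = c("dummy_strong", "dup")),
               "collinear")
  d$sep <- d$persisted  # perfectly predictive covariate
  expect_error(fit_persistence(d, terms = "sep"), "separation")
  expect_error(fit_persistence(d, terms = "nonexistent"), "not present")
})

test_that("AIC comparison selects the true model under strong effects", {
  cfg <- sim_config(seed = 61, beta = c(
    intercept = 0, dummy_strong = log(6), dummy_weak = log(0.3),
    relatedness = 0, risk_match = log(3), relatedness_x_riskmatch = 0,
    rankdist_z = 0))
  tr <- simulate_truth(cfg)
  d <- simulate_dyad_outcomes(tr)
  full <- fit_persistence(d)
  null <- fit_persistence(d, terms = character(0))
  tab <- compare_models(null = null, full = full)
  expect_equal(attr(tab, "selected"), "full")
  expect_equal(tab$dAIC[1], 0)
  # identical models differ by exactly zero
  tab2 <- compare_models(a = full, b = full)
  expect_equal(tab2$dAIC, c(0, 0))
  # fits on different datasets refuse to be compared
  d_small <- d[1:100, ]
  expect_error(compare_models(full, fit_persistence(d_small)),
               "different sizes")
})

test_that("refitting the model to consistent partitions amplifies homophily", {
  # same-group membership is transitive, so partition-constrained
  # assignments cannot follow the independent dyadic law; the nodematch
  # (risk homophily) effect measured from such partitions overshoots the
  # generating coefficient. This is why recovery tests draw dyad outcomes
  # directly from the Bernoulli law instead.
  est <- vapply(1:25, function(r) {
    cfg <- sim_config(seed = 7000 + r)
    tr <- simulate_truth(cfg)
    fis <- simulate_fission(cfg, tr, mode = "dyad_target")
    d <- truth_persistence_dataset(tr, fis$assignments)
    f <- tryCatch(fit_persistence(d), error = function(e) NULL)
    if (is.null(f)) NA_real_ else
      f$coefficients$estimate[f$coefficients$term == "risk_match"]
  }, numeric(1))
  expect_gt(mean(est, na.rm = TRUE), log(1.78) + 0.5)
})
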