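#' Configuration for the synthetic study generator
#'
#' Defines a synthetic multi-group study emulating the structure of the
#' field data: several pre-fission groups of parous females organised in
#' matrilines, two annual focal-follow windows with kin- and
#' tie-class-structured grooming/proximity rates, a latent dominance
#' hierarchy generating agonistic outcomes with occasional upsets, birth
#' timelines inducing pregnancy/lactation at fission, one resident male per
#' group, and ground-truth coefficients for the edge-persistence and
#' group-choice models.
#'
#' Defaults mirror the study conditions: 5 fissions of 15 parous females
#' each (~525 within-group dyads), a 41% at-risk fraction, gestation of 176
#' days, and persistence/choice coefficients at the scale of the published
#' estimates. The relatedness-by-risk interaction defaults to a moderate
#' `log(4)`: the published point estimate for that term is only weakly
#' identified (very large odds ratio with a very large standard error), so
#' a moderate value keeps the generator's dyad-level law well conditioned.
#'
#' @param seed integer; fixes all randomness downstream.
#' @param n_groups number of pre-fission groups (= fission events).
#' @param females_per_group parous females per group.
#' @param n_matrilines founding matrilines per group.
#' @param start_date first day of the earlier annual window.
#' @param fission_lag_days days from subgrouping onset to fission completion.
#' @param obs_days_per_year census (observation) days per year.
#' @param focal_minutes_per_female_year focal scan minutes per female per
#'   annual window.
#' @param p_groom,p_rest,p_feed per-minute activity probabilities (movement
#'   takes the remainder).
#' @param strong_mult,weak_mult affinity multipliers for consistently
#'   strong/weak dyads (inconsistent dyads take the strong multiplier in one
#'   year and the weak one in the other).
#' @param frac_strong,frac_weak fractions of dyads in each consistency
#'   class; the remainder is inconsistent.
#' @param kin_coef affinity increases by `1 + kin_coef * relatedness`.
#' @param prox_base per-minute probability scale of resting within 1 m of a
#'   given partner.
#' @param male_affinity_sdlog spread (log scale) of female-resident male
#'   affinity across females.
#' @param agonistic_rate expected contests per dyad per year.
#' @param upset_prob probability a contest is won by the lower-ranking
#'   opponent.
#' @param at_risk_frac target fraction of females pregnant or lactating at
#'   fission.
#' @param gestation_days,infant_dependency_days reproductive constants.
#' @param visitor_prob per observation day probability a visiting male is
#'   censused after the resident's qualifying sole period.
#' @param frac_late_adults fraction of females whose first parity falls
#'   inside the pre-fission year (they may fail the eligibility rule).
#' @param infant_mortality probability that a not-at-risk female carries a
#'   recent birth record whose infant died before fission (exercising the
#'   lactation-ends-at-death rule).
#' @param beta named ground-truth persistence coefficients: `intercept`,
#'   `dummy_strong`, `dummy_weak`, `relatedness`, `risk_match`,
#'   `relatedness_x_riskmatch`, `rankdist_z` (log-odds scale).
#' @param gamma_at_risk,gamma_not_at_risk named ground-truth choice
#'   coefficients `resident_present` and `resident_x_dsi` (log-odds scale)
#'   for the two risk strata.
#' @param split_frac_range range the larger daughter group's share of
#'   females is drawn from at each fission (default `c(0.65, 0.82)`, the
#'   observed range in the study population).
#' @param min_daughter minimum females per daughter group.
#' @param metropolis_sweeps Metropolis sweeps (per female) when the
#'   partition sampler cannot enumerate exactly.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_groups = 5L,
                       females_per_group = 15L,
                       n_matrilines = 5L,
                       start_date = as.Date("2015-10-01"),
                       fission_lag_days = 30L,
                       obs_days_per_year = 150L,
                       focal_minutes_per_female_year = 400L,
                       p_groom = 0.10, p_rest = 0.35, p_feed = 0.40,
                       strong_mult = 3, weak_mult = 0.35,
                       frac_strong = 0.30, frac_weak = 0.40,
                       kin_coef = 4,
                       prox_base = 0.02,
                       male_affinity_sdlog = 0.5,
                       agonistic_rate = 2.5,
                       upset_prob = 0.1,
                       at_risk_frac = 0.41,
                       gestation_days = 176L,
                       infant_dependency_days = 365L,
                       visitor_prob = 0.15,
                       frac_late_adults = 0,
                       infant_mortality = 0.1,
                       beta = c(intercept = log(0.81),
                                dummy_strong = log(1.80),
                                dummy_weak = log(1.41),
                                relatedness = log(1.23),
                                risk_match = log(1.78),
                                relatedness_x_riskmatch = log(4),
                                rankdist_z = log(0.98)),
                       gamma_at_risk = c(resident_present = log(3.63),
                                         resident_x_dsi = log(1.25)),
                       gamma_not_at_risk = c(resident_present = log(1.36),
                                             resident_x_dsi = log(0.86)),
                       split_frac_range = c(0.65, 0.82),
                       min_daughter = 2L,
                       metropolis_sweeps = 400L) {
  cfg <- as.list(environment())
  cfg$start_date <- as.Date(start_date)
  probs <- c(p_groom, p_rest, p_feed, frac_strong, frac_weak, at_risk_frac,
             upset_prob, visitor_prob, frac_late_adults)
  if (any(probs < 0 | probs > 1) || p_groom + p_rest + p_feed > 1)
    stop("activity/class probabilities must lie in [0, 1] and sum below 1",
         call. = FALSE)
  if (frac_strong + frac_weak > 1)
    stop("frac_strong + frac_weak must not exceed 1", call. = FALSE)
  if (focal_minutes_per_female_year < 30)
    stop("focal_minutes_per_female_year too small to form follows",
         call. = FALSE)
  if (females_per_group < 4 || n_matrilines < 1 ||
      n_matrilines > females_per_group)
    stop("need >= 4 females per group and 1 <= n_matrilines <= females_per_group",
         call. = FALSE)
  stopifnot(all(c("intercept", .persistence_terms) %in% names(beta)))
  structure(cfg, class = "sim_config")
}

# Key dates of the simulated study: two annual windows, subgrouping onset,
# fission completion.
sim_dates <- function(cfg) {
  t0 <- cfg$start_date
  onset <- t0 + 730
  list(y2 = c(t0, t0 + 364), y1 = c(t0 + 365, t0 + 729),
       onset = onset, fission = onset + cfg$fission_lag_days)
}

#' Simulate the latent ground truth of a synthetic study
#'
#' Draws everything the behavioural records will be generated from, without
#' emitting any records: matriline pedigrees, dyad consistency classes and
#' affinities for both annual windows, latent dominance ranks, female
#' reproductive states at fission, and female-resident male affinities.
#' This is the fast path used by parameter-recovery simulations; use
#' [simulate_population()] to materialise the full record set.
#'
#' @param cfg a [sim_config()].
#' @return object of class `sim_truth`: list with `config`, `dates`,
#'   `individuals` (with `group_id`, `matriline`, `latent_rank`), `females`
#'   (per-female states and male affinities), `dyads` (per-dyad classes,
#'   relatedness, affinities, `rankdist_z`), and `males` (resident/visitor
#'   ids per group).
#' @export
simulate_truth <- function(cfg) {
  set.seed(cfg$seed)
  dates <- sim_dates(cfg)
  groups <- sprintf("G%02d", seq_len(cfg$n_groups))

  ind_rows <- list()
  female_rows <- list()
  dyad_rows <- list()
  male_rows <- list()

  for (g in groups) {
    nf <- cfg$females_per_group
    ids <- sprintf("%s-F%02d", g, seq_len(nf))
    matriline <- integer(nf)
    mother <- rep(NA_character_, nf)
    birth <- as.Date(rep(NA, nf))
    matriline[seq_len(cfg$n_matrilines)] <- seq_len(cfg$n_matrilines)
    birth[seq_len(cfg$n_matrilines)] <-
      cfg$start_date - round(stats::runif(cfg$n_matrilines, 8000, 10000))
    for (k in seq.int(cfg$n_matrilines + 1, nf)) {
      m <- sample.int(k - 1, 1)
      mother[k] <- ids[m]
      matriline[k] <- matriline[m]
      # daughters born 6-12 years after their mother, but early enough that
      # every female is a parous adult before the study window
      birth[k] <- min(birth[m] + round(stats::runif(1, 365 * 6, 365 * 12)),
                      cfg$start_date - 365 * 7)
    }
    adult_from <- pmin(birth + round(stats::runif(nf, 365 * 6, 365 * 8)),
                       cfg$start_date - 30)
    n_late <- round(cfg$frac_late_adults * nf)
    if (n_late > 0) {
      late <- sample.int(nf, n_late)
      # first parity lands inside the pre-fission year
      adult_from[late] <- dates$y1[1] + sample.int(360, n_late, replace = TRUE)
    }

    latent_rank <- sample.int(nf)
    risk <- stats::runif(nf) < cfg$at_risk_frac
    pregnant <- risk & stats::runif(nf) < 0.5
    lactating <- risk & !pregnant
    male_aff <- stats::rlnorm(nf, 0, cfg$male_affinity_sdlog)
    dsi_male_true <- male_aff / stats::median(male_aff)

    ind_rows[[g]] <- data.frame(
      id = ids, sex = "female", birth_date = birth, mother_id = mother,
      adult_from = adult_from, group_id = g, matriline = matriline,
      latent_rank = latent_rank, stringsAsFactors = FALSE)
    female_rows[[g]] <- data.frame(
      id = ids, group_id = g, at_risk = risk, pregnant = pregnant,
      lactating = lactating, male_affinity = male_aff,
      dsi_male_true = dsi_male_true, latent_rank = latent_rank,
      stringsAsFactors = FALSE)
    male_rows[[g]] <- data.frame(
      group_id = g, resident_id = sprintf("%s-M01", g),
      visitor_id = sprintf("%s-M02", g), stringsAsFactors = FALSE)

    ped <- pedigree(data.frame(id = ids, mother_id = mother,
                               stringsAsFactors = FALSE))
    pair <- utils::combn(ids, 2)
    nd <- ncol(pair)
    cls <- sample(c("strong", "weak", "inconsistent"), nd, replace = TRUE,
                  prob = c(cfg$frac_strong, cfg$frac_weak,
                           1 - cfg$frac_strong - cfg$frac_weak))
    hi_year1 <- stats::runif(nd) < 0.5  # which year an inconsistent tie is high
    mult_y1 <- ifelse(cls == "strong", cfg$strong_mult,
                      ifelse(cls == "weak", cfg$weak_mult,
                             ifelse(hi_year1, cfg$strong_mult, cfg$weak_mult)))
    mult_y2 <- ifelse(cls == "strong", cfg$strong_mult,
                      ifelse(cls == "weak", cfg$weak_mult,
                             ifelse(hi_year1, cfg$weak_mult, cfg$strong_mult)))
    rel <- vapply(seq_len(nd), function(k)
      relatedness(ped, pair[1, k], pair[2, k]), numeric(1))
    kin_gain <- 1 + cfg$kin_coef * rel
    rank_of <- stats::setNames(latent_rank, ids)
    dyad_rows[[g]] <- data.frame(
      group_id = g, i_id = pair[1, ], j_id = pair[2, ],
      class = cls, relatedness = rel,
      affinity_y1 = mult_y1 * kin_gain, affinity_y2 = mult_y2 * kin_gain,
      rankdist = abs(rank_of[pair[1, ]] - rank_of[pair[2, ]]),
      stringsAsFactors = FALSE)
  }

  dyads <- do.call(rbind, dyad_rows)
  rownames(dyads) <- NULL
  dyads$rankdist_z <- standardize_rankdist(dyads$rankdist)
  females <- do.call(rbind, female_rows)
  rownames(females) <- NULL
  risk_of <- stats::setNames(females$at_risk, females$id)
  dyads$dummy_strong <- as.integer(dyads$class == "strong")
  dyads$dummy_weak <- as.integer(dyads$class == "weak")
  dyads$risk_match <- as.integer(risk_of[dyads$i_id] == risk_of[dyads$j_id])
  dyads$relatedness_x_riskmatch <- dyads$relatedness * dyads$risk_match

  structure(list(
    config = cfg, dates = dates,
    individuals = do.call(rbind, ind_rows),
    females = females, dyads = dyads,
    males = do.call(rbind, male_rows),
    beta = cfg$beta, gamma_at_risk = cfg$gamma_at_risk,
    gamma_not_at_risk = cfg$gamma_not_at_risk), class = "sim_truth")
}

#' Materialise a synthetic behavioural dataset from the ground truth
#'
#' Emits the full record set a field team would have produced under the
#' latent truth: individual roster with pedigree, census on evenly spaced
#' observation days (resident male sole at first, visiting males later),
#' minute-by-minute focal scans over both annual windows with grooming
#' partners and resting-proximity sets drawn from the dyad affinities,
#' agonistic records drawn from the latent hierarchy with upsets, and birth
#' records realising each female's reproductive state at fission.
#'
#' @param cfg a [sim_config()].
#' @param truth optionally a pre-computed [simulate_truth()] result for
#'   `cfg`.
#' @return list with `dataset` (a validated [behavior_dataset()], without
#'   fission tables — see [simulate_fission()]) and `truth`.
#' @export
simulate_population <- function(cfg, truth = NULL) {
  truth <- truth %||% simulate_truth(cfg)
  set.seed(cfg$seed + 1L)
  dates <- truth$dates
  groups <- unique(truth$individuals$group_id)

  individuals <- truth$individuals[, c("id", "sex", "birth_date", "mother_id",
                                       "adult_from")]
  males <- truth$males
  male_ind <- data.frame(
    id = c(males$resident_id, males$visitor_id), sex = "male",
    birth_date = as.Date(cfg$start_date) - 365 * 10, mother_id = NA_character_,
    adult_from = as.Date(cfg$start_date) - 365 * 3, stringsAsFactors = FALSE)
  individuals <- rbind(individuals, male_ind)

  span_days <- as.numeric(dates$fission - cfg$start_date)
  n_obs <- round(cfg$obs_days_per_year * span_days / 365)
  obs_days <- cfg$start_date + round(seq(0, span_days, length.out = n_obs))
  obs_days <- unique(obs_days)

  census_rows <- list()
  scan_rows <- list()
  ag_rows <- list()
  birth_rows <- list()

  for (g in groups) {
    fem <- truth$females[truth$females$group_id == g, ]
    res <- males$resident_id[males$group_id == g]
    vis <- males$visitor_id[males$group_id == g]
    # census: all females every observation day; resident male always
    # present (sole for the first 10 days, so he qualifies); a visitor male
    # appears sporadically afterwards
    vis_days <- obs_days[-seq_len(10)][
      stats::runif(length(obs_days) - 10) < cfg$visitor_prob]
    ids_per_day <- lapply(seq_along(obs_days), function(k) {
      c(fem$id, res, if (obs_days[k] %in% vis_days) vis)
    })
    census_rows[[g]] <- data.frame(
      date = rep(obs_days, lengths(ids_per_day)),
      group_id = g, individual_id = unlist(ids_per_day),
      stringsAsFactors = FALSE)

    dy <- truth$dyads[truth$dyads$group_id == g, ]
    aff <- function(year) {
      a <- matrix(0, nrow(fem), nrow(fem), dimnames = list(fem$id, fem$id))
      v <- if (year == 1) dy$affinity_y1 else dy$affinity_y2
      a[cbind(dy$i_id, dy$j_id)] <- v
      a[cbind(dy$j_id, dy$i_id)] <- v
      a
    }
    male_w <- stats::setNames(fem$male_affinity, fem$id)

    for (year in 1:2) {
      w <- if (year == 1) dates$y1 else dates$y2
      wdays <- obs_days[obs_days >= w[1] & obs_days <= w[2]]
      A <- aff(year)
      for (f in fem$id) {
        n_follow <- max(1L, round(cfg$focal_minutes_per_female_year / 30))
        adult <- truth$individuals$adult_from[truth$individuals$id == f]
        fdays_pool <- wdays[wdays >= adult]  # only adults are focal subjects
        if (!length(fdays_pool)) next
        fdays <- sample(fdays_pool, min(n_follow, length(fdays_pool)))
        n_min <- 30L * length(fdays)
        day_of <- rep(fdays, each = 30L)
        minute <- rep(0:29, length(fdays))
        p_move <- 1 - cfg$p_groom - cfg$p_rest - cfg$p_feed
        act <- sample(c("social_groom", "rest", "feed", "move"), n_min,
                      replace = TRUE,
                      prob = c(cfg$p_groom, cfg$p_rest, cfg$p_feed, p_move))
        partner <- rep(NA_character_, n_min)
        prox <- rep("", n_min)
        g_idx <- which(act == "social_groom")
        if (length(g_idx)) {
          cand <- c(setdiff(fem$id, f), res)
          wts <- c(A[f, setdiff(fem$id, f)], male_w[[f]])
          partner[g_idx] <- sample(cand, length(g_idx), replace = TRUE,
                                   prob = wts)
        }
        r_idx <- which(act == "rest")
        if (length(r_idx)) {
          cand <- c(setdiff(fem$id, f), res)
          p_prox <- pmin(0.85, cfg$prox_base * c(A[f, setdiff(fem$id, f)],
                                                 male_w[[f]]))
          hit <- matrix(stats::runif(length(r_idx) * length(cand)),
                        length(r_idx)) < rep(p_prox, each = length(r_idx))
          prox[r_idx] <- apply(hit, 1, function(h) join_ids(cand[h]))
        }
        f_idx <- which(act == "feed")
        if (length(f_idx)) {
          # 7 m feeding-proximity partners: recorded but unused by the index
          with_part <- f_idx[stats::runif(length(f_idx)) < 0.3]
          if (length(with_part))
            prox[with_part] <- sample(setdiff(fem$id, f), length(with_part),
                                      replace = TRUE)
        }
        scan_rows[[paste(g, year, f)]] <- data.frame(
          focal_id = f, date = day_of, minute_index = minute, activity = act,
          partner_id = partner, proximity_ids = prox, stringsAsFactors = FALSE)
      }
    }

    # agonistic contests from the latent order, throughout the study span
    rank_of <- stats::setNames(fem$latent_rank, fem$id)
    n_con <- stats::rpois(nrow(dy), cfg$agonistic_rate * span_days / 365)
    con_k <- rep(seq_len(nrow(dy)), n_con)
    if (length(con_k)) {
      hi <- ifelse(rank_of[dy$i_id[con_k]] < rank_of[dy$j_id[con_k]],
                   dy$i_id[con_k], dy$j_id[con_k])
      lo <- ifelse(hi == dy$i_id[con_k], dy$j_id[con_k], dy$i_id[con_k])
      upset <- stats::runif(length(con_k)) < cfg$upset_prob
      ag_rows[[g]] <- data.frame(
        date = sample(obs_days, length(con_k), replace = TRUE),
        winner_id = ifelse(upset, lo, hi),
        loser_id = ifelse(upset, hi, lo),
        group_id = g, stringsAsFactors = FALSE)
    }

    # births realising each female's state at the fission date
    fd <- dates$fission
    for (k in seq_len(nrow(fem))) {
      f <- fem$id[k]
      infant <- function(tag) sprintf("%s-I%s", f, tag)
      if (fem$pregnant[k]) {
        birth_rows[[paste(f, "p")]] <- data.frame(
          mother_id = f, infant_id = infant("p"),
          birth_date = fd + sample.int(cfg$gestation_days, 1),
          death_date = as.Date(NA), stringsAsFactors = FALSE)
      } else if (fem$lactating[k]) {
        birth_rows[[paste(f, "l")]] <- data.frame(
          mother_id = f, infant_id = infant("l"),
          birth_date = fd - sample.int(cfg$infant_dependency_days, 1) + 1,
          death_date = as.Date(NA), stringsAsFactors = FALSE)
      } else if (stats::runif(1) < cfg$infant_mortality) {
        # not at risk despite a recent birth: the infant died before fission
        bd <- fd - sample(120:300, 1)
        birth_rows[[paste(f, "d")]] <- data.frame(
          mother_id = f, infant_id = infant("d"), birth_date = bd,
          death_date = bd + sample.int(90, 1),
          stringsAsFactors = FALSE)
      } else if (stats::runif(1) < 0.5) {
        # a not-at-risk female may still have an older, independent infant
        birth_rows[[paste(f, "o")]] <- data.frame(
          mother_id = f, infant_id = infant("o"),
          birth_date = fd - sample(400:900, 1),
          death_date = as.Date(NA), stringsAsFactors = FALSE)
      }
    }
  }

  births <- do.call(rbind, birth_rows)
  infant_ind <- data.frame(
    id = births$infant_id, sex = sample(c("female", "male"),
                                        nrow(births), replace = TRUE),
    birth_date = births$birth_date, mother_id = births$mother_id,
    adult_from = as.Date(NA), stringsAsFactors = FALSE)
  individuals <- rbind(individuals, infant_ind)

  ds <- behavior_dataset(
    individuals = individuals,
    focal_scans = do.call(rbind, scan_rows),
    agonistic = do.call(rbind, ag_rows),
    census = do.call(rbind, census_rows),
    births = births)
  list(dataset = ds, truth = truth)
}

# Per-dyad linear predictor of the ground-truth persistence law.
truth_linear_predictor <- function(truth) {
  dy <- truth$dyads
  b <- truth$beta
  b[["intercept"]] +
    b[["dummy_strong"]] * dy$dummy_strong +
    b[["dummy_weak"]] * dy$dummy_weak +
    b[["relatedness"]] * dy$relatedness +
    b[["risk_match"]] * dy$risk_match +
    b[["relatedness_x_riskmatch"]] * dy$relatedness_x_riskmatch +
    b[["rankdist_z"]] * dy$rankdist_z
}

# Sample a bipartition of one group with |A| = k fixed, from the law
# P(assignment) proportional to exp(sum over same-side dyads of theta), the
# partition Gibbs measure whose couplings are the dyadic persistence
# log-odds. Without the size constraint this measure is degenerate
# (couplings at realistic scale drive everyone into one group); the split
# size is therefore a separate draw, matching the unbalanced daughter sizes
# field fissions show. Exact enumeration when the number of k-subsets is
# small enough; Metropolis over side-swapping pairs otherwise.
sample_bipartition <- function(theta, k, n_sweeps = 400L, max_enum = 2e5) {
  n <- nrow(theta)
  stopifnot(k >= 1, k <= n - 1)
  if (choose(n, k) <= max_enum) {
    combs <- utils::combn(n, k)
    S <- matrix(-1, n, ncol(combs))
    S[cbind(as.vector(combs),
            rep(seq_len(ncol(combs)), each = k))] <- 1
    # sum_{i<j} theta y_ij = const + s' Theta s / 4 with s in {-1, 1}^n
    q <- colSums(S * (theta %*% S)) / 4
    pick <- sample.int(ncol(combs), 1, prob = exp(q - max(q)))
    side <- rep("B", n)
    side[combs[, pick]] <- "A"
    return(side)
  }
  side <- rep(FALSE, n)
  side[sample.int(n, k)] <- TRUE
  for (s in seq_len(n_sweeps * n)) {
    i <- sample(which(side), 1)
    j <- sample(which(!side), 1)
    prop <- side
    prop[c(i, j)] <- c(FALSE, TRUE)
    dq <- part_logweight(theta, prop) - part_logweight(theta, side)
    if (dq >= 0 || stats::runif(1) < exp(dq)) side <- prop
  }
  ifelse(side, "A", "B")
}

part_logweight <- function(theta, side) {
  s <- ifelse(side, 1, -1)
  sum(s * (theta %*% s)) / 4
}

#' Draw dyad-level persistence outcomes from the independent Bernoulli law
#'
#' The estimator-validation arm of the generator: each within-group dyad's
#' `persisted` indicator is drawn independently from
#' \eqn{\mathrm{Bernoulli}(\mathrm{logit}^{-1}(\beta'x))} with the
#' ground-truth coefficients and true covariates. These outcomes are
#' deliberately *not* constrained to form a consistent partition — no
#' partition can induce independent dyadic outcomes, because same-group
#' membership is transitive — so this is the data-generating process the
#' persistence model itself assumes, and the right benchmark for parameter
#' recovery and confidence-interval calibration. Use [simulate_fission()]
#' for realistic, partition-consistent assignments.
#'
#' @param truth a [simulate_truth()] result.
#' @param seed RNG seed (default `truth$config$seed + 2`).
#' @return a `persistence_dataset` data frame (as
#'   [build_persistence_dataset()] produces, from true covariates).
#' @export
simulate_dyad_outcomes <- function(truth, seed = NULL) {
  set.seed(seed %||% (truth$config$seed + 2L))
  dy <- truth$dyads
  eta <- truth_linear_predictor(truth)
  out <- data.frame(
    fission_id = paste0("FIS-", dy$group_id),
    i_id = dy$i_id, j_id = dy$j_id,
    persisted = as.integer(stats::runif(nrow(dy)) < stats::plogis(eta)),
    dummy_strong = dy$dummy_strong, dummy_weak = dy$dummy_weak,
    relatedness = dy$relatedness, risk_match = dy$risk_match,
    relatedness_x_riskmatch = dy$relatedness_x_riskmatch,
    rankdist = dy$rankdist, rankdist_z = dy$rankdist_z,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("persistence_dataset", class(out))
  out
}

#' Simulate fission events over a synthetic population
#'
#' Two generating modes make the dyadic-independence approximation of the
#' persistence model explicit:
#'
#' * `"dyad_target"`: the split size is drawn first (larger daughter's
#'   share uniform on `split_frac_range`, as observed in field fissions);
#'   group composition is then sampled from the partition Gibbs measure
#'   that weights each within-group dyad by the ground-truth persistence
#'   odds \eqn{\exp(\beta'x)} when its members end up together — exactly,
#'   by enumerating all size-k bipartitions, at typical group sizes. This
#'   targets the dyadic logistic law as closely as any consistent partition
#'   can; because same-group membership is transitive, the induced dyadic
#'   outcomes are *not* independent, and refitting the persistence model to
#'   such partitions amplifies homophily effects. Parameter-recovery checks
#'   therefore use [simulate_dyad_outcomes()], which draws outcomes from
#'   the independent Bernoulli law itself.
#' * `"choice_first"`: each female independently picks a daughter group from
#'   the conditional-logit law with the ground-truth choice coefficients
#'   (her risk stratum's `gamma`, applied to resident-male presence and its
#'   interaction with her true male DSI). Realistic for the choice models;
#'   dyadic persistence effects are then only those induced indirectly.
#'
#' @param cfg a [sim_config()].
#' @param truth a [simulate_truth()] result for `cfg`.
#' @param mode `"dyad_target"` or `"choice_first"`.
#' @param seed seed for the assignment draw (default `cfg$seed + 2`).
#' @return list with `fissions` and `assignments` data frames (the schemas
#'   of [behavior_dataset()]).
#' @export
simulate_fission <- function(cfg, truth,
                             mode = c("dyad_target", "choice_first"),
                             seed = NULL) {
  mode <- match.arg(mode)
  set.seed(seed %||% (cfg$seed + 2L))
  dates <- truth$dates
  groups <- unique(truth$females$group_id)
  theta_all <- truth_linear_predictor(truth)

  fission_rows <- list()
  assign_rows <- list()
  for (g in groups) {
    fem <- truth$females[truth$females$group_id == g, ]
    ids <- fem$id
    res <- truth$males$resident_id[truth$males$group_id == g]
    ev <- paste0("FIS-", g)
    if (mode == "dyad_target") {
      dy <- truth$dyads[truth$dyads$group_id == g, ]
      theta <- matrix(0, length(ids), length(ids),
                      dimnames = list(ids, ids))
      th <- theta_all[truth$dyads$group_id == g]
      theta[cbind(dy$i_id, dy$j_id)] <- th
      theta[cbind(dy$j_id, dy$i_id)] <- th
      frac <- stats::runif(1, cfg$split_frac_range[1], cfg$split_frac_range[2])
      k <- max(cfg$min_daughter,
               min(length(ids) - cfg$min_daughter, round(frac * length(ids))))
      side <- sample_bipartition(theta, k, cfg$metropolis_sweeps)
      male_side <- sample(c("A", "B"), 1)
    } else {
      # resident male's daughter drawn first; each female then chooses
      male_side <- sample(c("A", "B"), 1)
      gma <- truth$gamma_at_risk
      gmn <- truth$gamma_not_at_risk
      eta <- ifelse(fem$at_risk,
                    gma[["resident_present"]] +
                      gma[["resident_x_dsi"]] * fem$dsi_male_true,
                    gmn[["resident_present"]] +
                      gmn[["resident_x_dsi"]] * fem$dsi_male_true)
      with_male <- stats::runif(nrow(fem)) < stats::plogis(eta)
      side <- ifelse(with_male, male_side, setdiff(c("A", "B"), male_side))
      counts <- table(factor(side, c("A", "B")))
      if (min(counts) < cfg$min_daughter) {
        big <- names(counts)[which.max(counts)]
        small <- setdiff(c("A", "B"), big)
        need <- cfg$min_daughter - counts[[small]]
        side[sample(which(side == big), need)] <- small
      }
    }
    names(side) <- ids
    fission_rows[[g]] <- data.frame(
      event_id = ev, parent_group_id = g,
      subgrouping_onset = dates$onset, fission_date = dates$fission,
      resident_male_daughter = male_side, stringsAsFactors = FALSE)
    assign_rows[[g]] <- data.frame(
      event_id = ev, individual_id = c(ids, res),
      daughter = c(unname(side), male_side), stringsAsFactors = FALSE)
  }
  fissions <- do.call(rbind, fission_rows)
  assignments <- do.call(rbind, assign_rows)
  rownames(fissions) <- NULL
  rownames(assignments) <- NULL
  list(fissions = fissions, assignments = assignments)
}

#' Simulate a complete synthetic study
#'
#' [simulate_truth()], [simulate_population()] and [simulate_fission()] in
#' one call: a validated [behavior_dataset()] including fission tables,
#' ready for [run_pipeline()], plus the generating truth.
#'
#' @param cfg a [sim_config()].
#' @param mode assignment mode, see [simulate_fission()].
#' @return list with `dataset` and `truth`.
#' @export
simulate_study <- function(cfg, mode = c("choice_first", "dyad_target")) {
  mode <- match.arg(mode)
  pop <- simulate_population(cfg)
  fis <- simulate_fission(cfg, pop$truth, mode)
  ds <- pop$dataset
  ds$fissions <- fis$fissions
  ds$assignments <- fis$assignments
  validate_dataset(ds)
  list(dataset = ds, truth = pop$truth)
}

#' Ground-truth persistence dataset
#'
#' Builds the dyad-level design exactly as [build_persistence_dataset()]
#' would, but from the generator's latent covariates (true consistency
#' classes, latent ranks, true risk states) and given daughter assignments.
#' Used to test the estimator under its own assumptions, free of
#' measurement noise from the behavioural records.
#'
#' @param truth a [simulate_truth()] result.
#' @param assignments assignments data frame from [simulate_fission()].
#' @return a `persistence_dataset` data frame.
#' @export
truth_persistence_dataset <- function(truth, assignments) {
  dy <- truth$dyads
  side <- stats::setNames(assignments$daughter, assignments$individual_id)
  out <- data.frame(
    fission_id = paste0("FIS-", dy$group_id),
    i_id = dy$i_id, j_id = dy$j_id,
    persisted = as.integer(side[dy$i_id] == side[dy$j_id]),
    dummy_strong = dy$dummy_strong, dummy_weak = dy$dummy_weak,
    relatedness = dy$relatedness, risk_match = dy$risk_match,
    relatedness_x_riskmatch = dy$relatedness_x_riskmatch,
    rankdist = dy$rankdist, rankdist_z = dy$rankdist_z,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("persistence_dataset", class(out))
  out
}

#' Simulate a stand-alone conditional-logit choice dataset
#'
#' Light-weight generator for testing the choice estimator under its own
#' assumptions: `n` females, each with a lognormal true DSI with the
#' resident male (median 1), choosing between the resident male's daughter
#' group and the other from the conditional-logit law with coefficients
#' `gamma`.
#'
#' @param n number of females (choice sets).
#' @param gamma named coefficients `resident_present`, `resident_x_dsi`.
#' @param seed RNG seed.
#' @param dsi_sdlog spread of the true DSI (log scale).
#' @return a `choice_dataset` data frame.
#' @export
simulate_choice_data <- function(n, gamma = c(resident_present = log(3.63),
                                              resident_x_dsi = log(1.25)),
                                 seed = 1L, dsi_sdlog = 0.6) {
  set.seed(seed)
  dsi <- stats::rlnorm(n, 0, dsi_sdlog)
  dsi <- dsi / stats::median(dsi)
  eta <- gamma[["resident_present"]] + gamma[["resident_x_dsi"]] * dsi
  with_male <- stats::runif(n) < stats::plogis(eta)
  id <- sprintf("f%04d", rep(seq_len(n), each = 2))
  resident <- rep(c(1L, 0L), n)
  out <- data.frame(
    choice_id = id, fission_id = "SIM", female_id = id,
    alternative = rep(c("A", "B"), n),
    chosen = as.integer(ifelse(rep(with_male, each = 2), resident == 1L,
                               resident == 0L)),
    resident_present = resident,
    dsi_with_resident = rep(dsi, each = 2),
    resident_x_dsi = resident * rep(dsi, each = 2),
    stringsAsFactors = FALSE)
  class(out) <- c("choice_dataset", class(out))
  out
}
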