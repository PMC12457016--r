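# Small programmatic fixtures shared across test files. Everything is built
# in code; no fixture files on disk.

mk_individuals <- function(ids, sex = "female",
                           birth = as.Date("2000-01-01"),
                           mother = NA_character_,
                           adult = as.Date("2010-01-01")) {
  n <- length(ids)
  data.frame(id = ids, sex = rep_len(sex, n),
             birth_date = rep_len(as.Date(birth), n),
             mother_id = rep_len(mother, n),
             adult_from = rep_len(as.Date(adult), n),
             stringsAsFactors = FALSE)
}

# n consecutive focal-scan minutes of one activity on one day
scan_rows <- function(focal, date, n, activity, partner = NA_character_,
                      prox = "", minute0 = 0L) {
  data.frame(focal_id = focal, date = as.Date(date),
             minute_index = minute0 + seq_len(n) - 1L, activity = activity,
             partner_id = partner, proximity_ids = prox,
             stringsAsFactors = FALSE)
}

census_rows <- function(dates, group, ids) {
  expand <- expand.grid(date = as.Date(dates), individual_id = ids,
                        stringsAsFactors = FALSE)
  data.frame(date = expand$date, group_id = group,
             individual_id = expand$individual_id, stringsAsFactors = FALSE)
}

one_fission <- function(event = "FX", group = "P",
                        onset = as.Date("2020-01-01"), lag = 30,
                        male_daughter = "A") {
  data.frame(event_id = event, parent_group_id = group,
             subgrouping_onset = as.Date(onset),
             fission_date = as.Date(onset) + lag,
             resident_male_daughter = male_daughter, stringsAsFactors = FALSE)
}

# A fully symmetric 4-female group: every ordered pair has `g` grooming
# minutes and `r` resting minutes with the partner in proximity, observed in
# the focal's own follows, in both annual windows. All dyads then have
# identical rates, so every ratio to the group median is 1.
symmetric_group_dataset <- function(g = 6, r = 9, fill_rest = 30) {
  ids <- paste0("F", 1:4)
  onset <- as.Date("2020-01-01")
  fis <- one_fission(onset = onset)
  scans <- list()
  for (win_start in c(onset - 365, onset - 730)) {
    for (f in ids) {
      others <- setdiff(ids, f)
      day <- win_start + 10
      blocks <- list()
      m0 <- 0L
      for (p in others) {
        blocks <- c(blocks, list(
          scan_rows(f, day, g, "social_groom", partner = p, minute0 = m0),
          scan_rows(f, day, r, "rest", prox = p, minute0 = m0 + g)))
        m0 <- m0 + g + r
      }
      blocks <- c(blocks, list(
        scan_rows(f, day, fill_rest, "feed", minute0 = m0)))
      scans[[paste(f, win_start)]] <- do.call(rbind, blocks)
    }
  }
  obs_days <- seq(onset - 730, fis$fission_date, by = 7)
  behavior_dataset(
    individuals = rbind(mk_individuals(ids),
                        mk_individuals("M1", sex = "male")),
    focal_scans = do.call(rbind, scans),
    census = census_rows(obs_days, "P", c(ids, "M1")),
    fissions = fis,
    assignments = data.frame(event_id = "FX",
                             individual_id = c(ids, "M1"),
                             daughter = c("A", "A", "B", "B", "A"),
                             stringsAsFactors = FALSE))
}

# Pedigree fixture covering every relatedness category:
#   GM is the matriarch; A and B are her daughters (sisters);
#   C = A's daughter, D = B's daughter (C, D are first cousins);
#   E = C's daughter; U, V are unrelated with unknown mothers.
relatedness_pedigree <- function() {
  ind <- data.frame(
    id = c("GM", "A", "B", "C", "D", "E", "U", "V"),
    mother_id = c(NA, "GM", "GM", "A", "B", "C", NA, NA),
    stringsAsFactors = FALSE)
  pedigree(ind)
}

# Paired binary-choice dataset: n females, k of whom choose the alternative
# bearing the attribute. The conditional-logit MLE for the attribute
# coefficient has the closed form log(k / (n - k)).
paired_binary_choices <- function(n, k) {
  id <- sprintf("f%03d", rep(seq_len(n), each = 2))
  has_attr <- rep(c(1L, 0L), n)
  chose_attr <- rep(seq_len(n) <= k, each = 2)
  data.frame(
    choice_id = id,
    chosen = as.integer(ifelse(chose_attr, has_attr == 1L, has_attr == 0L)),
    attr = has_attr, stringsAsFactors = FALSE)
}

# Bernoulli log-likelihood used by grid-search oracles, written directly
# from the definition (independent of the package's fitting code).
bernoulli_loglik <- function(beta, design, y) {
  eta <- drop(design %*% beta)
  sum(y * eta - log(1 + exp(eta)))
}

# Refining dense grid search over a 2-parameter Bernoulli likelihood.
grid_search_2par <- function(design, y, lo = -5, hi = 5) {
  centers <- c(0, 0)
  half <- (hi - lo) / 2
  for (stage in 1:4) {
    g1 <- seq(centers[1] - half, centers[1] + half, length.out = 51)
    g2 <- seq(centers[2] - half, centers[2] + half, length.out = 51)
    grid <- as.matrix(expand.grid(g1, g2))
    ll <- apply(grid, 1, function(b) bernoulli_loglik(b, design, y))
    centers <- grid[which.max(ll), ]
    step <- g1[2] - g1[1]
    half <- 2 * step
  }
  centers
}

# All permutations of 1..n, generated by simple recursion (independent of
# the package's enumeration code).
perms_recursive <- function(n) {
  if (n == 1) return(list(1L))
  shorter <- perms_recursive(n - 1)
  out <- vector("list", n * length(shorter))
  k <- 1L
  for (p in shorter) {
    for (pos in 0:(n - 1)) {
      out[[k]] <- append(p, n, after = pos)
      k <- k + 1L
    }
  }
  out
}

# (I, SI) of an ordering computed straight from the definition.
isi_value <- function(wins, ord) {
  n <- length(ord)
  w <- wins[ord, ord]
  I <- 0L; SI <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (w[j, i] > w[i, j]) {
        I <- I + 1L
        SI <- SI + (j - i)
      }
    }
  }
  c(I = I, SI = SI)
}

random_contest_matrix <- function(n, n_contests = 30) {
  ids <- paste0("id", seq_len(n))
  wins <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (k in seq_len(n_contests)) {
    pair <- sample.int(n, 2)
    wins[pair[1], pair[2]] <- wins[pair[1], pair[2]] + 1L
  }
  wins
}
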