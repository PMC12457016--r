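#' Annual analysis windows for a fission event
#'
#' Tie strength is measured over the full year before the onset of
#' subgrouping (`y1`), and tie consistency by comparison with the year
#' before that (`y2`). Windows are 365-day closed intervals: `y1` ends the
#' day before subgrouping onset and `y2` covers days 366-730 before onset.
#'
#' @param fission one row of the `fissions` table (data frame or list).
#' @param window_days window length in days (default 365).
#' @return list with `Date` intervals `y1 = c(start, end)` and `y2`.
#' @export
fission_windows <- function(fission, window_days = 365) {
  onset <- as.Date(fission$subgrouping_onset)
  list(y1 = c(onset - window_days, onset - 1),
       y2 = c(onset - 2 * window_days, onset - window_days - 1))
}

#' Females eligible for dyadic analysis
#'
#' All parous (adult) females censused in the parent group during the
#' window, excluding any female who was followable for less than half of the
#' year — e.g. one who had her first infant, becoming an adult, more than
#' halfway through the window. Coverage is the fraction of window days on or
#' after her `adult_from` date; exclusion applies iff coverage < 0.5
#' strictly, so exactly half the year is included.
#'
#' @param ds a [behavior_dataset()].
#' @param fission one row of the `fissions` table.
#' @param window date interval; defaults to the year before subgrouping
#'   onset.
#' @param min_coverage minimum followable fraction of the window
#'   (default 0.5).
#' @return sorted character vector of female ids.
#' @export
eligible_females <- function(ds, fission, window = NULL, min_coverage = 0.5) {
  w <- window %||% fission_windows(fission)$y1
  members <- group_members(ds, fission$parent_group_id, w)
  ind <- ds$individuals
  ind <- ind[ind$id %in% members & ind$sex == "female", , drop = FALSE]
  ind <- ind[!is.na(ind$adult_from) & ind$adult_from <= w[2], , drop = FALSE]
  if (!nrow(ind)) return(character(0))
  ndays <- as.numeric(w[2] - w[1]) + 1
  start <- pmax(ind$adult_from, w[1])
  coverage <- (as.numeric(w[2] - start) + 1) / ndays
  sort(ind$id[coverage >= min_coverage])
}

# Aggregate focal-scan counts inside a window once, for reuse across dyads:
# focal minutes per id, grooming minutes per ordered (focal, partner) pair,
# and resting-within-1m minutes per ordered (focal, partner) pair.
window_scan_summary <- function(ds, window, rest_only = TRUE) {
  fs <- ds$focal_scans
  fs <- fs[fs$date >= window[1] & fs$date <= window[2], , drop = FALSE]
  focal_minutes <- table(fs$focal_id)
  gr <- fs[fs$activity == "social_groom" & !is.na(fs$partner_id), , drop = FALSE]
  groom <- if (nrow(gr)) {
    as.data.frame(table(focal = gr$focal_id, partner = gr$partner_id),
                  stringsAsFactors = FALSE)
  } else data.frame(focal = character(), partner = character(), Freq = integer())
  groom <- groom[groom$Freq > 0, , drop = FALSE]
  px <- if (rest_only) fs[fs$activity == "rest", , drop = FALSE] else
    fs[fs$activity != "move", , drop = FALSE]
  px <- px[nzchar(px$proximity_ids), , drop = FALSE]
  prox <- if (nrow(px)) {
    parts <- strsplit(px$proximity_ids, ";", fixed = TRUE)
    long <- data.frame(focal = rep(px$focal_id, lengths(parts)),
                       partner = unlist(parts), stringsAsFactors = FALSE)
    as.data.frame(table(focal = long$focal, partner = long$partner),
                  stringsAsFactors = FALSE)
  } else data.frame(focal = character(), partner = character(), Freq = integer())
  prox <- prox[prox$Freq > 0, , drop = FALSE]
  list(focal_minutes = focal_minutes, groom = groom, prox = prox)
}

lookup_count <- function(df, focal, partner) {
  hit <- df$Freq[df$focal == focal & df$partner == partner]
  if (length(hit)) sum(hit) else 0L
}

dyad_rates_from_summary <- function(sm, i, j) {
  fm <- function(id) {
    v <- sm$focal_minutes[id]
    if (is.na(v)) 0L else as.integer(v)
  }
  f_i <- fm(i); f_j <- fm(j)
  if (f_i == 0 && f_j == 0)
    stop(sprintf("dyad (%s, %s): neither member has focal minutes in the window",
                 i, j), call. = FALSE)
  groom <- lookup_count(sm$groom, i, j) + lookup_count(sm$groom, j, i)
  single <- xor(f_i == 0, f_j == 0)
  g_denom <- f_i + f_j
  r_ij <- if (f_i > 0) lookup_count(sm$prox, i, j) / f_i else NA_real_
  r_ji <- if (f_j > 0) lookup_count(sm$prox, j, i) / f_j else NA_real_
  data.frame(i_id = i, j_id = j,
             G_ij = groom / g_denom,
             R_ij = r_ij, R_ji = r_ji,
             focal_minutes_i = f_i, focal_minutes_j = f_j,
             single_focal = single, stringsAsFactors = FALSE)
}

#' Dyadic interaction rates within a window
#'
#' `G_ij` is the total time the pair spent grooming, observed in either
#' member's focal follows, divided by their combined focal observation time.
#' `R_ij` is the rate at which `i` rested within 1 m of `j` per minute of
#' `i`'s own focal time (and `R_ji` vice versa); the two proximity rates are
#' kept separate because they are not symmetrical measures. When only one
#' member contributed focal data (`single_focal`), only that member's
#' proximity rate is defined and the grooming denominator is that member's
#' minutes alone.
#'
#' @param ds a [behavior_dataset()].
#' @param i,j distinct individual ids.
#' @param window closed date interval `c(start, end)`.
#' @param rest_only use only resting-within-1m scans for proximity (the
#'   default; feeding proximity uses a 7 m radius and is not part of the
#'   index).
#' @return one-row data frame with columns `i_id`, `j_id`, `G_ij`, `R_ij`,
#'   `R_ji`, `focal_minutes_i`, `focal_minutes_j`, `single_focal`.
#' @export
dyad_rates <- function(ds, i, j, window, rest_only = TRUE) {
  stopifnot(i != j)
  if (!all(c(i, j) %in% ds$individuals$id))
    stop("unknown individual id", call. = FALSE)
  sm <- window_scan_summary(ds, window, rest_only)
  dyad_rates_from_summary(sm, i, j)
}

# Rates for all unordered pairs of `females` within a window.
group_dyad_rates <- function(ds, females, window, rest_only = TRUE) {
  sm <- window_scan_summary(ds, window, rest_only)
  pairs <- utils::combn(sort(females), 2)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(k)
    dyad_rates_from_summary(sm, pairs[1, k], pairs[2, k])))
}

#' Group-median normalisers for the dyadic sociality index
#'
#' `G_med` is the median grooming rate over all included dyads; `R_med` is
#' the median over the pooled set of directed proximity rates (both
#' `R_ij` and `R_ji` of every dyad; undefined single-focal terms excluded).
#' A single pooled proximity median is used because the index divides both
#' directed terms by one normaliser.
#'
#' @param rates data frame of [dyad_rates()] rows for the included dyads.
#' @return list with `G_med` and `R_med`.
#' @export
group_medians <- function(rates) {
  r_pool <- c(rates$R_ij, rates$R_ji)
  list(G_med = stats::median(rates$G_ij),
       R_med = stats::median(r_pool[!is.na(r_pool)]))
}

#' Dyadic sociality index
#'
#' Composite affiliative tie strength for a female pair, combining grooming
#' and resting-in-proximity rates each normalised by its group median:
#' \deqn{DSI = \frac{1}{2}\frac{G_{ij}}{G_{med}} +
#'   \frac{1}{4}\left(\frac{R_{ij}}{R_{med}} + \frac{R_{ji}}{R_{med}}\right)}
#' A score of 1 means the dyad groomed and rested in proximity exactly as
#' much as the median dyad of its group; >1 means more. When the dyad was
#' observed through a single member's follows, the lone proximity term takes
#' weight one-half instead of one-quarter.
#'
#' A zero median leaves its term undefined; by default this is an error. With
#' `on_zero_median = "drop_term"` the affected term is dropped and the
#' remaining weights are renormalised to sum to 1.
#'
#' @param rates one row of [dyad_rates()] output (or a compatible list).
#' @param medians list with `G_med`, `R_med` (see [group_medians()]).
#' @param on_zero_median `"error"` (default) or `"drop_term"`.
#' @return non-negative numeric DSI value.
#' @export
compute_dsi <- function(rates, medians, on_zero_median = c("error", "drop_term")) {
  on_zero_median <- match.arg(on_zero_median)
  single <- isTRUE(rates$single_focal)
  r_terms <- if (single) {
    r <- c(rates$R_ij, rates$R_ji)
    r[!is.na(r)]
  } else c(rates$R_ij, rates$R_ji)
  weights <- if (single) c(0.5, 0.5) else c(0.5, 0.25, 0.25)
  values <- c(rates$G_ij, r_terms)
  meds <- c(medians$G_med, rep(medians$R_med, length(r_terms)))
  which_med <- c("G_med", rep("R_med", length(r_terms)))

  zero <- meds <= 0
  if (any(zero)) {
    if (on_zero_median == "error")
      stop(sprintf("zero group median (%s): DSI undefined for dyad (%s, %s)",
                   paste(unique(which_med[zero]), collapse = ", "),
                   rates$i_id %||% "?", rates$j_id %||% "?"), call. = FALSE)
    weights <- weights[!zero]
    if (!length(weights))
      stop("all group medians are zero: DSI undefined", call. = FALSE)
    weights <- weights / sum(weights)
    values <- values[!zero]
    meds <- meds[!zero]
  }
  sum(weights * values / meds)
}

#' Classify tie consistency across two annual windows
#'
#' A tie is consistently strong if its DSI exceeded the threshold in both
#' years, consistently weak if it did not exceed the threshold in either
#' year, and inconsistent if it exceeded the threshold in exactly one year.
#' A DSI exactly at the threshold (measure-zero in field data, common in
#' synthetic fixtures) counts as not-above, i.e. bins with the weak side, so
#' the classification is total. Inconsistent ties are the reference class:
#' both dummies are 0.
#'
#' @param dsi_y1,dsi_y2 DSI in the year before subgrouping onset and the
#'   year before that; vectorised.
#' @param threshold class boundary (default 1, i.e. the group median).
#' @return data frame with columns `consistency` (factor: `inconsistent`,
#'   `consistently_strong`, `consistently_weak`), `dummy_strong`,
#'   `dummy_weak`.
#' @export
classify_consistency <- function(dsi_y1, dsi_y2, threshold = 1) {
  strong <- dsi_y1 > threshold & dsi_y2 > threshold
  weak <- dsi_y1 <= threshold & dsi_y2 <= threshold
  cls <- ifelse(strong, "consistently_strong",
                ifelse(weak, "consistently_weak", "inconsistent"))
  data.frame(
    consistency = factor(cls, levels = c("inconsistent", "consistently_strong",
                                         "consistently_weak")),
    dummy_strong = as.integer(strong),
    dummy_weak = as.integer(weak))
}

#' Dyadic sociality table for a fission event
#'
#' One row per eligible female dyad of the parent group, with the DSI in the
#' year before subgrouping onset (`dsi_y1`), the DSI the year before that
#' (`dsi_y2`), and the consistency class with its model dummies. Eligibility
#' is decided on the `y1` window only; the `y2` DSI is computed under
#' relaxed rules, so a female with no focal data in `y2` (e.g. not yet
#' adult) contributes through her partners' follows via the single-focal
#' variant.
#'
#' @param ds a [behavior_dataset()].
#' @param fission one row of the `fissions` table.
#' @param threshold consistency-class boundary (default 1).
#' @param on_zero_median passed to [compute_dsi()].
#' @param window_days annual window length (default 365).
#' @return data frame with columns `fission_id`, `i_id`, `j_id`, `dsi_y1`,
#'   `dsi_y2`, `consistency`, `dummy_strong`, `dummy_weak`.
#' @export
sociality_table <- function(ds, fission, threshold = 1,
                            on_zero_median = c("error", "drop_term"),
                            window_days = 365) {
  on_zero_median <- match.arg(on_zero_median)
  w <- fission_windows(fission, window_days)
  females <- eligible_females(ds, fission, w$y1)
  if (length(females) < 2)
    stop(sprintf("fission %s: fewer than 2 eligible females", fission$event_id),
         call. = FALSE)
  dsi_for_window <- function(window) {
    rates <- group_dyad_rates(ds, females, window)
    med <- group_medians(rates)
    vapply(seq_len(nrow(rates)), function(k)
      compute_dsi(rates[k, ], med, on_zero_median), numeric(1))
  }
  rates1 <- group_dyad_rates(ds, females, w$y1)
  med1 <- group_medians(rates1)
  dsi1 <- vapply(seq_len(nrow(rates1)), function(k)
    compute_dsi(rates1[k, ], med1, on_zero_median), numeric(1))
  dsi2 <- dsi_for_window(w$y2)
  cls <- classify_consistency(dsi1, dsi2, threshold)
  cbind(data.frame(fission_id = fission$event_id,
                   i_id = rates1$i_id, j_id = rates1$j_id,
                   dsi_y1 = dsi1, dsi_y2 = dsi2,
                   stringsAsFactors = FALSE),
        cls)
}

#' Female DSI with the resident male
#'
#' Males are not focal subjects, so a female's tie to the resident male is
#' measured from her follows only, with grooming and resting in proximity
#' weighted equally (the single-focal variant), and normalised by the median
#' grooming and proximity rates across all female-resident male dyads of the
#' pre-fission group in the same window.
#'
#' @param ds a [behavior_dataset()].
#' @param fission one row of the `fissions` table.
#' @param resident_male id of the resident male; if `NULL`, determined from
#'   the census via [residency_timeline()] at the fission date.
#' @param window date interval; defaults to the year before subgrouping
#'   onset.
#' @param on_zero_median passed to [compute_dsi()].
#' @return data frame with columns `fission_id`, `female_id`, `male_id`,
#'   `dsi_with_resident`.
#' @export
male_dsi <- function(ds, fission, resident_male = NULL, window = NULL,
                     on_zero_median = c("error", "drop_term")) {
  on_zero_median <- match.arg(on_zero_median)
  w <- window %||% fission_windows(fission)$y1
  if (is.null(resident_male)) {
    resident_male <- resident_at(ds, fission$parent_group_id,
                                 as.Date(fission$fission_date))
    if (is.na(resident_male))
      stop(sprintf("fission %s: no resident male at fission date",
                   fission$event_id), call. = FALSE)
  }
  females <- eligible_females(ds, fission, fission_windows(fission)$y1)
  sm <- window_scan_summary(ds, w)
  rows <- lapply(females, function(f) {
    f_min <- sm$focal_minutes[f]
    f_min <- if (is.na(f_min)) 0L else as.integer(f_min)
    if (f_min == 0)
      stop(sprintf("female %s has no focal minutes in window", f), call. = FALSE)
    data.frame(female_id = f,
               G = lookup_count(sm$groom, f, resident_male) / f_min,
               R = lookup_count(sm$prox, f, resident_male) / f_min,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  med <- list(G_med = stats::median(tab$G), R_med = stats::median(tab$R))
  dsi <- vapply(seq_len(nrow(tab)), function(k) {
    compute_dsi(list(i_id = tab$female_id[k], j_id = resident_male,
                     G_ij = tab$G[k], R_ij = tab$R[k], R_ji = NA_real_,
                     single_focal = TRUE),
                med, on_zero_median)
  }, numeric(1))
  data.frame(fission_id = fission$event_id, female_id = tab$female_id,
             male_id = resident_male, dsi_with_resident = dsi,
             stringsAsFactors = FALSE)
}
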