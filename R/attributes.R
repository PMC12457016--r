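#' Maternal pedigree
#'
#' Relatedness is computed from recorded mother links only (paternity
#' unknown in the study system). A `pedigree` is the named vector of mother
#' ids, checked for cycles.
#'
#' @param individuals the `individuals` table of a [behavior_dataset()] (or
#'   a data frame with `id` and `mother_id`).
#' @return named character vector mapping each id to its mother id (`NA` if
#'   unknown), of class `pedigree`.
#' @export
pedigree <- function(individuals) {
  p <- stats::setNames(individuals$mother_id, individuals$id)
  for (id in names(p)) {
    seen <- character(0)
    cur <- id
    while (!is.na(p[cur] %||% NA_character_) && cur %in% names(p)) {
      if (cur %in% seen) stop(sprintf("pedigree cycle involving %s", id),
                              call. = FALSE)
      seen <- c(seen, cur)
      cur <- p[[cur]]
      if (!cur %in% names(p)) break
    }
  }
  structure(p, class = "pedigree")
}

# Maternal ancestor chain of an id: named integer vector of generation
# depths, starting at the individual itself (depth 0).
maternal_ancestors <- function(p, id) {
  depth <- c(stats::setNames(0L, id))
  cur <- id
  while (cur %in% names(p) && !is.na(p[[cur]])) {
    cur <- p[[cur]]
    depth <- c(depth, stats::setNames(length(depth), cur))
  }
  depth
}

#' Maternal relatedness coefficient
#'
#' Assigns the study's coarse relatedness scheme from recorded maternal
#' links: mother-offspring dyads 0.5; maternal sisters and
#' grandmother-granddaughter dyads 0.25; aunt-niece dyads 0.125; first
#' cousins 0.0625; any detectable more distant maternal-line relationship
#' 0.03125. Unrelated pairs, and pairs whose relationship is undetectable
#' from the recorded links, score 0. When several maternal paths exist the
#' closest relationship wins.
#'
#' The scheme equals `0.5^(d_i + d_j)` where `d_i`, `d_j` are the
#' generations from each individual up to their most recent common maternal
#' ancestor, floored at 0.03125 for detectable relatives.
#'
#' @param p a [pedigree()].
#' @param i,j distinct individual ids.
#' @return relatedness coefficient in `{0, 0.03125, 0.0625, 0.125, 0.25, 0.5}`.
#' @export
relatedness <- function(p, i, j) {
  stopifnot(i != j)
  anc_i <- maternal_ancestors(p, i)
  anc_j <- maternal_ancestors(p, j)
  common <- intersect(names(anc_i), names(anc_j))
  if (!length(common)) return(0)
  total <- anc_i[common] + anc_j[common]
  d <- min(total)
  if (d >= 5) 0.03125 else 0.5^d
}

#' Reproductive state of a female at a date
#'
#' From birth records: a female is pregnant if she gives birth within the
#' gestation period after the date (176 days in the study species), and
#' lactating if she has a living infant under one year old on the date (an
#' infant that died earlier ends lactation at its death). A female is at
#' risk of infanticide if she is pregnant or lactating — she has, or will
#' soon have, a dependent vulnerable infant. A birth falling exactly on the
#' date counts as lactation, not pregnancy.
#'
#' @param ds a [behavior_dataset()].
#' @param female female id.
#' @param date the reference date (e.g. the fission date).
#' @param gestation_days gestation length (default 176).
#' @param infant_dependency_days age below which an infant makes its mother
#'   lactating (default 365).
#' @return one-row data frame with `female_id`, `date`, `pregnant`,
#'   `lactating`, `at_risk`.
#' @export
reproductive_state <- function(ds, female, date, gestation_days = 176,
                               infant_dependency_days = 365) {
  date <- as.Date(date)
  br <- ds$births[ds$births$mother_id == female, , drop = FALSE]
  pregnant <- any(br$birth_date > date & br$birth_date <= date + gestation_days)
  age <- as.numeric(date - br$birth_date)
  alive <- is.na(br$death_date) | br$death_date > date
  lactating <- any(age >= 0 & age < infant_dependency_days & alive)
  data.frame(female_id = female, date = date, pregnant = pregnant,
             lactating = lactating, at_risk = pregnant || lactating,
             stringsAsFactors = FALSE)
}

#' Resident-male tenure intervals for a group
#'
#' A male becomes resident once he has been the sole male in the group for
#' at least seven consecutive observation days (days with a census record,
#' which can span more than one calendar week); his tenure is backdated to
#' the first day of that qualifying run. He loses resident status after
#' being entirely absent from the group for seven consecutive observation
#' days; the interval closes on the last observation day he was present.
#' At most one male is resident at a time.
#'
#' @param ds a [behavior_dataset()].
#' @param group group id.
#' @param run_days observation days required to gain (as sole male) or lose
#'   (as complete absence) residency (default 7).
#' @return data frame with `group_id`, `male_id`, `start_date`, `end_date`
#'   (`NA` while tenure is ongoing at the last census).
#' @export
residency_timeline <- function(ds, group, run_days = 7) {
  days <- observation_days(ds, group)
  males <- ds$individuals$id[ds$individuals$sex == "male"]
  cs <- ds$census[ds$census$group_id == group &
                    ds$census$individual_id %in% males, , drop = FALSE]
  present <- split(cs$individual_id, as.character(cs$date))

  out <- data.frame(group_id = character(), male_id = character(),
                    start_date = as.Date(character()),
                    end_date = as.Date(character()),
                    stringsAsFactors = FALSE)
  resident <- NA_character_
  res_start <- as.Date(NA)
  last_present <- as.Date(NA)
  absence <- 0L
  sole_id <- NA_character_   # candidate on a current sole-male run
  sole_run_start <- as.Date(NA)
  sole_len <- 0L

  for (k in seq_along(days)) {
    d <- days[k]
    here <- present[[as.character(d)]] %||% character(0)
    if (is.na(resident)) {
      if (length(here) == 1) {
        if (!is.na(sole_id) && sole_id == here) {
          sole_len <- sole_len + 1L
        } else {
          sole_id <- here
          sole_run_start <- d
          sole_len <- 1L
        }
        if (sole_len >= run_days) {
          resident <- sole_id
          res_start <- sole_run_start
          last_present <- d
          absence <- 0L
          sole_id <- NA_character_
          sole_len <- 0L
        }
      } else {
        sole_id <- NA_character_
        sole_len <- 0L
      }
    } else {
      if (resident %in% here) {
        last_present <- d
        absence <- 0L
      } else {
        absence <- absence + 1L
        if (absence >= run_days) {
          out <- rbind(out, data.frame(
            group_id = group, male_id = resident, start_date = res_start,
            end_date = last_present, stringsAsFactors = FALSE))
          resident <- NA_character_
          absence <- 0L
          # a sole-male run by another male may already be underway during
          # the absence window; rewind and rescan those days as candidates
          sole_id <- NA_character_
          sole_len <- 0L
        }
      }
    }
  }
  if (!is.na(resident)) {
    out <- rbind(out, data.frame(
      group_id = group, male_id = resident, start_date = res_start,
      end_date = as.Date(NA), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Resident male of a group on a date
#'
#' @param ds a [behavior_dataset()].
#' @param group group id.
#' @param date date of interest.
#' @param run_days see [residency_timeline()].
#' @return the resident male's id, or `NA` if none.
#' @export
resident_at <- function(ds, group, date, run_days = 7) {
  tl <- residency_timeline(ds, group, run_days)
  date <- as.Date(date)
  hit <- tl$start_date <= date & (is.na(tl$end_date) | tl$end_date >= date)
  if (any(hit)) tl$male_id[which(hit)[1]] else NA_character_
}

#' Female reproductive states at a fission
#'
#' Convenience wrapper: [reproductive_state()] for every eligible female of
#' a fission's parent group, evaluated at the fission date.
#'
#' @param ds a [behavior_dataset()].
#' @param fission one row of the `fissions` table.
#' @param females female ids; default: [eligible_females()] for the event.
#' @param gestation_days,infant_dependency_days see [reproductive_state()].
#' @return data frame with one row per female plus a `fission_id` column.
#' @export
female_states <- function(ds, fission, females = NULL, gestation_days = 176,
                          infant_dependency_days = 365) {
  females <- females %||% eligible_females(ds, fission)
  st <- do.call(rbind, lapply(females, function(f)
    reproductive_state(ds, f, fission$fission_date, gestation_days,
                       infant_dependency_days)))
  cbind(data.frame(fission_id = fission$event_id, stringsAsFactors = FALSE), st)
}
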