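#' Behavioural observation dataset
#'
#' A `behavior_dataset` bundles the tabular record types produced by a
#' long-term field study of individually recognised, group-living primates:
#' an individual roster with maternal pedigree links, minute-by-minute focal
#' follow scans, agonistic interactions with clear winners and losers, daily
#' group censuses, birth records, and annotations of permanent group-fission
#' events with daughter-group assignments.
#'
#' All components are plain data frames; dates are `Date` (day resolution)
#' and unknown values are `NA`. On disk each component is a UTF-8 CSV with a
#' header, unknown values written as empty fields, and set-valued columns
#' (proximity partners) joined with `";"`.
#'
#' @param individuals data frame with columns `id`, `sex` (`"female"` or
#'   `"male"`), `birth_date`, `mother_id`, `adult_from` (date of first
#'   parity for females; the date from which an individual can be a focal
#'   subject).
#' @param focal_scans data frame with columns `focal_id`, `date`,
#'   `minute_index` (integer >= 0), `activity` (`"feed"`, `"move"`,
#'   `"social_groom"`, `"rest"`), `partner_id` (grooming partner; `NA`
#'   unless grooming), `proximity_ids` (`";"`-joined ids of animals within
#'   the activity-specific radius; empty when moving).
#' @param agonistic data frame with columns `date`, `winner_id`, `loser_id`,
#'   `group_id`. Only interactions with a clear outcome are recorded.
#' @param census long-format data frame with columns `date`, `group_id`,
#'   `individual_id`: one row per animal present in a group on an
#'   observation day.
#' @param births data frame with columns `mother_id`, `infant_id`,
#'   `birth_date`, `death_date` (`NA` if the infant survived the study).
#' @param fissions data frame with columns `event_id`, `parent_group_id`,
#'   `subgrouping_onset`, `fission_date`, `resident_male_daughter`
#'   (`"A"` or `"B"`).
#' @param assignments data frame with columns `event_id`, `individual_id`,
#'   `daughter` (`"A"` or `"B"`): which daughter group each animal joined.
#' @param validate validate invariants (default `TRUE`).
#' @return an object of class `behavior_dataset`.
#' @seealso [read_dataset()], [write_dataset()], [simulate_population()]
#' @export
behavior_dataset <- function(individuals, focal_scans = NULL, agonistic = NULL,
                             census = NULL, births = NULL, fissions = NULL,
                             assignments = NULL, validate = TRUE) {
  empty <- function(...) {
    cols <- list(...)
    as.data.frame(cols, stringsAsFactors = FALSE)[0, , drop = FALSE]
  }
  ds <- structure(list(
    individuals = individuals,
    focal_scans = focal_scans %||% empty(
      focal_id = character(), date = as.Date(character()),
      minute_index = integer(), activity = character(),
      partner_id = character(), proximity_ids = character()),
    agonistic = agonistic %||% empty(
      date = as.Date(character()), winner_id = character(),
      loser_id = character(), group_id = character()),
    census = census %||% empty(
      date = as.Date(character()), group_id = character(),
      individual_id = character()),
    births = births %||% empty(
      mother_id = character(), infant_id = character(),
      birth_date = as.Date(character()), death_date = as.Date(character())),
    fissions = fissions %||% empty(
      event_id = character(), parent_group_id = character(),
      subgrouping_onset = as.Date(character()),
      fission_date = as.Date(character()),
      resident_male_daughter = character()),
    assignments = assignments %||% empty(
      event_id = character(), individual_id = character(),
      daughter = character())
  ), class = "behavior_dataset")
  rownames(ds$individuals) <- NULL
  for (nm in names(ds)) rownames(ds[[nm]]) <- NULL
  if (validate) validate_dataset(ds)
  ds
}

#' @export
print.behavior_dataset <- function(x, ...) {
  cat("<behavior_dataset>\n")
  cat(sprintf("  individuals: %d (%d females, %d males)\n",
              nrow(x$individuals), sum(x$individuals$sex == "female"),
              sum(x$individuals$sex == "male")))
  cat(sprintf("  focal scan minutes: %d\n", nrow(x$focal_scans)))
  cat(sprintf("  agonistic records:  %d\n", nrow(x$agonistic)))
  cat(sprintf("  census rows:        %d (%d groups)\n", nrow(x$census),
              length(unique(x$census$group_id))))
  cat(sprintf("  births:             %d\n", nrow(x$births)))
  cat(sprintf("  fission events:     %d\n", nrow(x$fissions)))
  invisible(x)
}

#' Validate a behavioural dataset
#'
#' Checks every documented schema invariant: unique individual ids, legal
#' enum values, foreign keys that resolve (scan partners, mothers, census
#' members, fission assignments), grooming partners present only on grooming
#' scans, no proximity partners while moving, winners distinct from losers,
#' infant death dates not before birth, fission dates not before subgrouping
#' onset, and daughter assignments restricted to animals recorded in the
#' parent group's census.
#'
#' @param ds a [behavior_dataset()].
#' @return `ds`, invisibly; otherwise an error naming the table, offending
#'   row numbers and the violated invariant.
#' @export
validate_dataset <- function(ds) {
  ind <- ds$individuals
  if (anyDuplicated(ind$id))
    stop_invalid("individuals", which(duplicated(ind$id)), "duplicate id")
  if (!all(ind$sex %in% c("female", "male")))
    stop_invalid("individuals", which(!ind$sex %in% c("female", "male")),
                 "sex must be 'female' or 'male'")
  bad <- !is.na(ind$birth_date) & !is.na(ind$adult_from) &
    ind$birth_date > ind$adult_from
  if (any(bad))
    stop_invalid("individuals", which(bad), "birth_date after adult_from")
  known_mother <- !is.na(ind$mother_id)
  bad <- known_mother & !(ind$mother_id %in% ind$id)
  if (any(bad))
    stop_invalid("individuals", which(bad),
                 sprintf("unresolved mother_id: %s",
                         paste(unique(ind$mother_id[bad]), collapse = ", ")))

  ids <- ind$id
  fs <- ds$focal_scans
  if (nrow(fs)) {
    if (!all(fs$focal_id %in% ids))
      stop_invalid("focal_scans", which(!fs$focal_id %in% ids),
                   "unresolved focal_id")
    if (any(fs$minute_index < 0))
      stop_invalid("focal_scans", which(fs$minute_index < 0),
                   "negative minute_index")
    acts <- c("feed", "move", "social_groom", "rest")
    if (!all(fs$activity %in% acts))
      stop_invalid("focal_scans", which(!fs$activity %in% acts),
                   "unknown activity")
    bad <- !is.na(fs$partner_id) & fs$activity != "social_groom"
    if (any(bad))
      stop_invalid("focal_scans", which(bad),
                   "partner_id set on a non-grooming scan")
    bad <- !is.na(fs$partner_id) & !(fs$partner_id %in% ids)
    if (any(bad))
      stop_invalid("focal_scans", which(bad), "unresolved partner_id")
    has_prox <- !is.na(fs$proximity_ids) & nzchar(fs$proximity_ids)
    bad <- has_prox & fs$activity == "move"
    if (any(bad))
      stop_invalid("focal_scans", which(bad),
                   "proximity partners recorded while moving")
    prox_ids <- unique(unlist(lapply(fs$proximity_ids[has_prox], split_ids)))
    if (!all(prox_ids %in% ids))
      stop(sprintf("invalid focal_scans: unresolved proximity ids: %s",
                   paste(setdiff(prox_ids, ids), collapse = ", ")),
           call. = FALSE)
  }

  ag <- ds$agonistic
  if (nrow(ag)) {
    if (any(ag$winner_id == ag$loser_id))
      stop_invalid("agonistic", which(ag$winner_id == ag$loser_id),
                   "winner_id equals loser_id")
    bad <- !(ag$winner_id %in% ids) | !(ag$loser_id %in% ids)
    if (any(bad))
      stop_invalid("agonistic", which(bad), "unresolved winner/loser id")
  }

  cs <- ds$census
  if (nrow(cs)) {
    if (!all(cs$individual_id %in% ids))
      stop_invalid("census", which(!cs$individual_id %in% ids),
                   "unresolved individual_id")
    key <- paste(cs$date, cs$group_id, cs$individual_id)
    if (anyDuplicated(key))
      stop_invalid("census", which(duplicated(key)),
                   "individual listed twice on one group-day")
  }

  br <- ds$births
  if (nrow(br)) {
    if (!all(br$mother_id %in% ids))
      stop_invalid("births", which(!br$mother_id %in% ids),
                   "unresolved mother_id")
    bad <- !is.na(br$death_date) & br$death_date < br$birth_date
    if (any(bad))
      stop_invalid("births", which(bad), "death_date before birth_date")
  }

  fi <- ds$fissions
  if (nrow(fi)) {
    if (anyDuplicated(fi$event_id))
      stop_invalid("fissions", which(duplicated(fi$event_id)),
                   "duplicate event_id")
    bad <- fi$fission_date < fi$subgrouping_onset
    if (any(bad))
      stop_invalid("fissions", which(bad),
                   "fission_date before subgrouping_onset")
    if (!all(fi$resident_male_daughter %in% c("A", "B")))
      stop_invalid("fissions", which(!fi$resident_male_daughter %in% c("A", "B")),
                   "resident_male_daughter must be 'A' or 'B'")
  }

  as_ <- ds$assignments
  if (nrow(as_)) {
    if (!all(as_$event_id %in% fi$event_id))
      stop_invalid("assignments", which(!as_$event_id %in% fi$event_id),
                   "unresolved event_id")
    if (!all(as_$daughter %in% c("A", "B")))
      stop_invalid("assignments", which(!as_$daughter %in% c("A", "B")),
                   "daughter must be 'A' or 'B'")
    if (!all(as_$individual_id %in% ids))
      stop_invalid("assignments", which(!as_$individual_id %in% ids),
                   "unresolved individual_id")
    for (k in seq_len(nrow(fi))) {
      ev <- fi$event_id[k]
      grp <- fi$parent_group_id[k]
      members <- unique(cs$individual_id[cs$group_id == grp])
      assigned <- as_$individual_id[as_$event_id == ev]
      missing <- setdiff(assigned, members)
      if (length(missing))
        stop(sprintf(
          "invalid assignments: ids assigned in event %s never censused in parent group %s: %s",
          ev, grp, paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  invisible(ds)
}

# on-disk component files and their date columns
.ds_files <- list(
  individuals = c("birth_date", "adult_from"),
  focal_scans = "date",
  agonistic = "date",
  census = "date",
  births = c("birth_date", "death_date"),
  fissions = c("subgrouping_onset", "fission_date"),
  assignments = character(0)
)

#' Read a behavioural dataset from a directory of CSV files
#'
#' Expects the file set written by [write_dataset()]: `individuals.csv`,
#' `focal_scans.csv`, `agonistic.csv`, `census.csv`, `births.csv`,
#' `fissions.csv` and `assignments.csv`. Missing optional files are treated
#' as empty tables; `individuals.csv` is required. Dates must be ISO-8601;
#' unknown values must be empty fields (or one of `na_aliases`) — any other
#' unparseable value is an error naming the file.
#'
#' @param dir directory containing the CSV files.
#' @param na_aliases strings accepted as unknown values (default: the empty
#'   field only, so sentinels like `"NA"` are caught rather than silently
#'   coerced).
#' @return a validated [behavior_dataset()].
#' @export
read_dataset <- function(dir, na_aliases = "") {
  read_one <- function(name) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) {
      if (name == "individuals")
        stop(sprintf("required file missing: %s", path), call. = FALSE)
      return(NULL)
    }
    df <- utils::read.csv(path, colClasses = "character",
                          na.strings = character(0),
                          stringsAsFactors = FALSE)
    for (col in names(df)) {
      if (col %in% .ds_files[[name]]) {
        df[[col]] <- tryCatch(
          parse_date_strict(df[[col]], col, na_aliases),
          error = function(e) stop(sprintf("%s: %s", path, conditionMessage(e)),
                                   call. = FALSE))
      } else if (col == "minute_index") {
        df[[col]] <- as.integer(df[[col]])
      } else {
        df[[col]][df[[col]] %in% na_aliases] <- NA_character_
      }
    }
    if (name == "focal_scans" && nrow(df))
      df$proximity_ids[is.na(df$proximity_ids)] <- ""
    df
  }
  parts <- lapply(names(.ds_files), read_one)
  names(parts) <- names(.ds_files)
  behavior_dataset(parts$individuals, parts$focal_scans, parts$agonistic,
                   parts$census, parts$births, parts$fissions,
                   parts$assignments)
}

#' Write a behavioural dataset to a directory of CSV files
#'
#' Emits the same UTF-8 CSV schemas [read_dataset()] consumes: ISO-8601
#' dates, unknown values as empty fields, proximity-partner sets joined with
#' `";"`. The round trip `read_dataset(write_dataset(ds, d))` reproduces
#' `ds` exactly.
#'
#' @param ds a [behavior_dataset()].
#' @param dir destination directory (created if absent).
#' @return the vector of file paths written, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (name in names(.ds_files)) {
    df <- ds[[name]]
    out <- df
    for (col in names(out)) {
      if (inherits(out[[col]], "Date")) out[[col]] <- format(out[[col]], "%Y-%m-%d")
      out[[col]][is.na(out[[col]])] <- ""
    }
    path <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Observation days for a group
#'
#' An observation day is a day on which the group was censused — residency
#' rules ("seven consecutive observation days") count these, not calendar
#' days, because monitoring has gaps.
#'
#' @param ds a [behavior_dataset()].
#' @param group_id group identifier.
#' @param window closed date interval as `c(start, end)`; `NULL` for all
#'   records.
#' @return ascending vector of census `Date`s for the group in the window.
#' @export
observation_days <- function(ds, group_id, window = NULL) {
  if (!group_id %in% ds$census$group_id)
    stop(sprintf("unknown group: %s", group_id), call. = FALSE)
  d <- unique(ds$census$date[ds$census$group_id == group_id])
  if (!is.null(window)) d <- d[d >= window[1] & d <= window[2]]
  sort(d)
}

# Members of a group censused at least once inside a window.
group_members <- function(ds, group_id, window = NULL) {
  cs <- ds$census[ds$census$group_id == group_id, , drop = FALSE]
  if (!is.null(window))
    cs <- cs[cs$date >= window[1] & cs$date <= window[2], , drop = FALSE]
  unique(cs$individual_id)
}
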