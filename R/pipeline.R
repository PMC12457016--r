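#' Pipeline run configuration
#'
#' Collects every biological constant of the analysis as a named,
#' overridable default: 365-day annual windows, 176-day gestation, one-year
#' infant dependency, the seven-observation-day residency rule, and the
#' DSI threshold of 1 (the group median) for consistency classes. These are
#' biological choices a reuser of the pipeline will want to change for
#' another study system, so none of them is a literal in the stage code.
#'
#' @param input_dir directory of CSV files for [read_dataset()] (mutually
#'   exclusive with `dataset`).
#' @param dataset an in-memory [behavior_dataset()].
#' @param window_days annual window length (default 365).
#' @param gestation_days pregnancy lookahead before a birth (default 176).
#' @param dependency_days infant age below which the mother is lactating
#'   (default 365).
#' @param residency_days consecutive observation days to gain/lose resident
#'   male status (default 7).
#' @param dsi_threshold consistency-class boundary (default 1).
#' @param persistence_terms covariates of the full persistence model.
#' @param choice_terms covariates of the conditional-logit choice models.
#' @param seed seed for the hierarchy search (and any other stochastic
#'   stage).
#' @param output_dir if non-`NULL`, intermediate tables and the rendered
#'   report are written here.
#' @return list of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, dataset = NULL,
                       window_days = 365,
                       gestation_days = 176,
                       dependency_days = 365,
                       residency_days = 7,
                       dsi_threshold = 1,
                       persistence_terms = .persistence_terms,
                       choice_terms = c("resident_present", "resident_x_dsi"),
                       seed = 1L,
                       output_dir = NULL) {
  if (is.null(input_dir) == is.null(dataset))
    stop("provide exactly one of input_dir or dataset", call. = FALSE)
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop(sprintf("input_dir does not exist: %s", input_dir), call. = FALSE)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full post-fission tie-persistence pipeline
#'
#' Executes every stage in order — data validation, per-fission dyadic
#' sociality and consistency classes, I&SI hierarchies up to each fission
#' date, reproductive states and resident-male DSIs, the pooled dyadic
#' persistence model (full vs intercept-only, compared by AIC), and the two
#' conditional-logit group-choice models (at-risk and not-at-risk females).
#' The run is deterministic given the configuration and inputs.
#'
#' @param cfg a [run_config()].
#' @return object of class `run_report`: list with `per_fission` counts,
#'   `persistence` (dataset, rate, fits, AIC table), `choice` (datasets and
#'   fits or the reason a stratum was not estimable), and `provenance`
#'   (seed, config hash, package version).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  ds <- cfg$dataset %||% read_dataset(cfg$input_dir)
  validate_dataset(ds)
  if (!nrow(ds$fissions))
    stop("dataset contains no fission events", call. = FALSE)
  ped <- pedigree(ds$individuals)

  soc_all <- list(); states_all <- list(); mdsi_all <- list()
  hierarchies <- list(); per_fission <- list()
  for (k in seq_len(nrow(ds$fissions))) {
    fe <- ds$fissions[k, ]
    ev <- fe$event_id
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e)
        stop(sprintf("fission %s, stage %s: %s", ev, what,
                     conditionMessage(e)), call. = FALSE))
    }
    soc <- stage("sociality", sociality_table(
      ds, fe, threshold = cfg$dsi_threshold, window_days = cfg$window_days))
    females <- sort(unique(c(soc$i_id, soc$j_id)))
    st <- stage("attributes", female_states(
      ds, fe, females, cfg$gestation_days, cfg$dependency_days))
    resident <- stage("residency", resident_at(
      ds, fe$parent_group_id, fe$fission_date, cfg$residency_days))
    if (is.na(resident))
      stop(sprintf("fission %s: no resident male at fission date", ev),
           call. = FALSE)
    md <- stage("male DSI", male_dsi(
      ds, fe, resident,
      window = fission_windows(fe, cfg$window_days)$y1))
    year <- as.integer(format(as.Date(fe$fission_date), "%Y"))
    cm <- stage("dominance", build_contest_matrix(
      ds, fe$parent_group_id, year, until = fe$fission_date, ids = females))
    hierarchies[[ev]] <- stage("dominance", isi_order(cm, seed = cfg$seed))
    soc_all[[ev]] <- soc
    states_all[[ev]] <- st
    mdsi_all[[ev]] <- md
    per_fission[[ev]] <- data.frame(
      fission_id = ev, group_id = fe$parent_group_id,
      n_eligible_females = length(females),
      n_dyads = nrow(soc),
      n_at_risk = sum(st$at_risk),
      hierarchy_I = hierarchies[[ev]]$I,
      stringsAsFactors = FALSE)
  }
  soc_all <- do.call(rbind, soc_all)
  states_all <- do.call(rbind, states_all)
  mdsi_all <- do.call(rbind, mdsi_all)

  pdat <- build_persistence_dataset(soc_all, hierarchies, states_all, ped, ds)
  fit_full <- fit_persistence(pdat, cfg$persistence_terms)
  fit_null <- fit_persistence(pdat, character(0))
  aic_tab <- compare_models(null = fit_null, full = fit_full)

  cdat <- build_choice_datasets(states_all, mdsi_all, ds)
  fit_choice <- function(d) {
    if (!nrow(d)) return(list(fit = NULL, note = "no females in stratum"))
    tryCatch(list(fit = fit_conditional_logit(d, cfg$choice_terms), note = NULL),
             error = function(e) list(fit = NULL, note = conditionMessage(e)))
  }
  choice_fits <- list(at_risk = fit_choice(cdat$at_risk),
                      not_at_risk = fit_choice(cdat$not_at_risk))

  report <- structure(list(
    per_fission = do.call(rbind, per_fission),
    sociality = soc_all,
    states = states_all,
    male_dsi = mdsi_all,
    persistence = list(dataset = pdat, rate = persistence_rate(pdat),
                       fit = fit_full, null_fit = fit_null, aic = aic_tab),
    choice = list(datasets = cdat, fits = choice_fits),
    provenance = list(seed = cfg$seed, config_hash = object_md5(strip_data(cfg)),
                      package_version = as.character(utils::packageVersion("fissionties")))),
    class = "run_report")
  rownames(report$per_fission) <- NULL

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(soc_all, file.path(cfg$output_dir, "dyads.csv"),
                     row.names = FALSE)
    utils::write.csv(mdsi_all, file.path(cfg$output_dir, "male_dsi.csv"),
                     row.names = FALSE)
    utils::write.csv(states_all, file.path(cfg$output_dir, "female_states.csv"),
                     row.names = FALSE)
    utils::write.csv(pdat, file.path(cfg$output_dir, "persistence.csv"),
                     row.names = FALSE)
    writeLines(render_report(report, "markdown"),
               file.path(cfg$output_dir, "report.md"))
  }
  report
}

# md5 of an arbitrary R object via its serialised bytes (version 3 fixed so
# hashes are comparable across sessions).
object_md5 <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  con <- file(tmp, "wb")
  serialize(x, con, version = 3)
  close(con)
  unname(tools::md5sum(tmp))
}

# configuration without the (possibly large) in-memory dataset
strip_data <- function(cfg) {
  cfg$dataset <- NULL
  cfg
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  print(x$per_fission, row.names = FALSE)
  cat(sprintf("\nEdge persistence rate: %.3f over %d dyads\n",
              x$persistence$rate, nrow(x$persistence$dataset)))
  print(x$persistence$fit)
  invisible(x)
}

md_table <- function(df) {
  cells <- vapply(df, function(col) format(col, trim = TRUE), character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

#' Render a pipeline report
#'
#' Markdown output mirrors the structure of a results section: per-fission
#' counts, the persistence-model coefficient table with `odds ratio`,
#' `s.e.` and `p` columns, the AIC comparison, and one coefficient table
#' per choice stratum (marked not-estimable when a stratum was empty or the
#' fit failed). JSON output is a faithful machine-readable export that
#' parses and round-trips.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param format `"markdown"` or `"json"`.
#' @return character vector of lines (markdown) or a JSON string.
#' @export
render_report <- function(report, format = c("markdown", "json")) {
  format <- match.arg(format)
  coefs_md <- function(fit) {
    tab <- data.frame(
      predictor = fit$coefficients$term,
      `odds ratio` = sprintf("%.2f", fit$coefficients$odds_ratio),
      s.e. = sprintf("%.2f", fit$coefficients$se),
      p = sprintf("%.3g", fit$coefficients$p),
      check.names = FALSE)
    md_table(tab)
  }
  if (format == "markdown") {
    lines <- c(
      "# Post-fission tie persistence and group choice",
      "",
      "## Fissions",
      "",
      md_table(report$per_fission),
      "",
      sprintf("Overall edge persistence rate: %.1f%% (%d of %d dyads).",
              100 * report$persistence$rate,
              sum(report$persistence$dataset$persisted),
              nrow(report$persistence$dataset)),
      "",
      "## Edge persistence model",
      "",
      coefs_md(report$persistence$fit),
      "",
      "(s.e. on the log-odds scale.)",
      "",
      "### AIC comparison",
      "",
      md_table(transform(report$persistence$aic,
                         logLik = sprintf("%.2f", logLik),
                         AIC = sprintf("%.1f", AIC),
                         dAIC = sprintf("%.1f", dAIC))),
      "")
    for (stratum in c("at_risk", "not_at_risk")) {
      title <- sprintf("## Group choice: %s females", gsub("_", " ", stratum))
      entry <- report$choice$fits[[stratum]]
      lines <- c(lines, title, "")
      if (is.null(entry$fit)) {
        lines <- c(lines, sprintf("Not estimable: %s", entry$note), "")
      } else {
        lines <- c(lines, coefs_md(entry$fit),
                   sprintf("(n = %d females)", entry$fit$n_choices), "")
      }
    }
    lines <- c(lines, "## Provenance", "",
               sprintf("- seed: %s", report$provenance$seed),
               sprintf("- config hash: %s", report$provenance$config_hash),
               sprintf("- fissionties version: %s",
                       report$provenance$package_version))
    lines
  } else {
    fit_json <- function(fit) {
      if (is.null(fit)) return(NULL)
      list(coefficients = fit$coefficients, logLik = fit$logLik,
           AIC = fit$AIC)
    }
    choice_json <- function(entry) {
      out <- fit_json(entry$fit)
      if (!is.null(entry$note)) out <- c(out, list(note = entry$note))
      out
    }
    payload <- list(
      per_fission = report$per_fission,
      persistence = list(
        rate = report$persistence$rate,
        n_dyads = nrow(report$persistence$dataset),
        fit = fit_json(report$persistence$fit),
        null_fit = fit_json(report$persistence$null_fit),
        aic = report$persistence$aic),
      choice = list(
        at_risk = choice_json(report$choice$fits$at_risk),
        not_at_risk = choice_json(report$choice$fits$not_at_risk)),
      provenance = report$provenance)
    jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  }
}

#' Hash of a rendered report
#'
#' md5 digest of the markdown rendering; two pipeline runs with identical
#' inputs, configuration and seed produce identical hashes.
#'
#' @param report a `run_report`.
#' @return md5 string.
#' @export
report_hash <- function(report) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(render_report(report, "markdown"), tmp)
  unname(tools::md5sum(tmp))
}
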