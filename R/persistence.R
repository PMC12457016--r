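#' Assemble the dyadic edge-persistence dataset
#'
#' One row per eligible female dyad of each fission's parent group (the
#' pre-fission network is the complete graph on eligible females, and the
#' block-diagonal constraint means only within-group dyads exist). A dyad's
#' edge persisted if both females joined the same daughter group. Covariates
#' are the tie-consistency dummies, maternal relatedness, infanticide-risk
#' homophily (`risk_match` = both members share the same at-risk value),
#' their product, and pooled Z-scored rank distance.
#'
#' Rank distance is standardised over all dyads of all fissions jointly,
#' because the persistence model is fitted jointly across fissions.
#'
#' @param sociality data frame: [sociality_table()] rows, possibly for
#'   several fissions (`rbind`ed).
#' @param hierarchies named list of [isi_order()] results, one per fission
#'   event id.
#' @param states data frame: [female_states()] rows for the same fissions.
#' @param ped a [pedigree()].
#' @param ds a [behavior_dataset()] carrying the fission and assignment
#'   tables.
#' @return data frame of class `persistence_dataset` with columns
#'   `fission_id`, `i_id`, `j_id`, `persisted`, `dummy_strong`,
#'   `dummy_weak`, `relatedness`, `risk_match`, `relatedness_x_riskmatch`,
#'   `rankdist`, `rankdist_z`.
#' @export
build_persistence_dataset <- function(sociality, hierarchies, states, ped, ds) {
  fi <- ds$fissions
  as_ <- ds$assignments
  rows <- lapply(seq_len(nrow(sociality)), function(k) {
    r <- sociality[k, ]
    ev <- r$fission_id
    h <- hierarchies[[ev]]
    if (is.null(h))
      stop(sprintf("dyad (%s, %s): no hierarchy for fission %s",
                   r$i_id, r$j_id, ev), call. = FALSE)
    st <- states[states$fission_id == ev, ]
    risk <- stats::setNames(st$at_risk, st$female_id)
    if (!all(c(r$i_id, r$j_id) %in% names(risk)))
      stop(sprintf("dyad (%s, %s): missing reproductive state (fission %s)",
                   r$i_id, r$j_id, ev), call. = FALSE)
    aa <- as_[as_$event_id == ev, ]
    side <- stats::setNames(aa$daughter, aa$individual_id)
    if (!all(c(r$i_id, r$j_id) %in% names(side)))
      stop(sprintf("dyad (%s, %s): missing daughter assignment (fission %s)",
                   r$i_id, r$j_id, ev), call. = FALSE)
    rel <- relatedness(ped, r$i_id, r$j_id)
    rm_ <- as.integer(risk[[r$i_id]] == risk[[r$j_id]])
    data.frame(
      fission_id = ev, i_id = r$i_id, j_id = r$j_id,
      persisted = as.integer(side[[r$i_id]] == side[[r$j_id]]),
      dummy_strong = r$dummy_strong, dummy_weak = r$dummy_weak,
      relatedness = rel, risk_match = rm_,
      relatedness_x_riskmatch = rel * rm_,
      rankdist = rank_distance(h, r$i_id, r$j_id),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rankdist_z <- standardize_rankdist(out$rankdist)
  for (ev in unique(out$fission_id)) {
    sides <- table(ds$assignments$daughter[ds$assignments$event_id == ev &
      ds$assignments$individual_id %in% c(out$i_id, out$j_id)])
    if (any(sides < 2))
      warning(sprintf(
        "fission %s: a daughter group has < 2 eligible females; all its dyads fall in the larger group",
        ev))
  }
  class(out) <- c("persistence_dataset", class(out))
  out
}

.persistence_terms <- c("dummy_strong", "dummy_weak", "relatedness",
                        "risk_match", "relatedness_x_riskmatch", "rankdist_z")

#' Fit the edge-persistence model
#'
#' Maximum-likelihood fit of the dissolution/persistence component of a
#' separable temporal ERGM under a block-diagonal constraint. Because every
#' term is dyad-independent (edge covariates, a nodematch homophily term and
#' their products), the persistence likelihood factorises into independent
#' Bernoulli contributions \eqn{\sum_d [y_d \eta_d - \log(1 + e^{\eta_d})]}
#' with \eqn{\eta} a linear predictor including an intercept (the baseline
#' edge persistence). The fit is by Newton-Raphson on this exact
#' log-likelihood; standard errors come from the observed information.
#'
#' @param d a `persistence_dataset` (or any data frame with a `persisted`
#'   column and the term columns).
#' @param terms character vector of covariate column names; the intercept is
#'   always included. Default: all six standard terms.
#' @param max_iter,tol Newton iteration controls.
#' @return object of class `persistence_fit`: list with `coefficients`
#'   (data frame: term, estimate, se, odds_ratio, or_se, z, p), `logLik`,
#'   `AIC`, `n_dyads`, `converged`, `vcov`, `terms`.
#' @export
fit_persistence <- function(d, terms = .persistence_terms, max_iter = 50,
                            tol = 1e-10) {
  missing_cols <- setdiff(terms, names(d))
  if (length(missing_cols))
    stop(sprintf("terms not present in dataset: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  X <- cbind(`(baseline edge persistence)` = 1,
             as.matrix(d[, terms, drop = FALSE]))
  y <- d$persisted
  fit <- newton_logistic(X, y, max_iter = max_iter, tol = tol)
  out <- coef_table(fit, X)
  out$n_dyads <- length(y)
  structure(out, class = "persistence_fit")
}

# Numerically stable log(1 + exp(x)).
log1pexp <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

# Shared Newton-Raphson maximiser for the Bernoulli log-likelihood
# sum(y * eta - log(1 + exp(eta))), eta = X beta.
newton_logistic <- function(X, y, max_iter = 50, tol = 1e-10) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("design matrix is rank deficient; collinear column(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  beta <- rep(0, ncol(X))
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    grad <- drop(crossprod(X, y - p))
    W <- p * (1 - p)
    H <- crossprod(X * W, X)
    step <- tryCatch(solve(H, grad), error = function(e)
      stop("singular information matrix (possible separation): ",
           conditionMessage(e), call. = FALSE))
    beta <- beta + step
    trace <- c(trace, max(abs(grad)))
    if (max(abs(step)) < tol || max(abs(grad)) < tol) {
      if (max(abs(beta)) > 30)
        stop(sprintf(
          "apparent complete separation: |coefficient| > 30 (iteration trace: %s)",
          paste(signif(trace, 3), collapse = ", ")), call. = FALSE)
      eta <- drop(X %*% beta)
      ll <- sum(y * eta - log1pexp(eta))
      vcov <- solve(crossprod(X * (stats::plogis(eta) * (1 - stats::plogis(eta))), X))
      return(list(beta = beta, vcov = vcov, logLik = ll, converged = TRUE,
                  iterations = it))
    }
  }
  stop(sprintf("Newton iteration did not converge in %d steps (gradient trace: %s)",
               max_iter, paste(signif(utils::tail(trace, 5), 3), collapse = ", ")),
       call. = FALSE)
}

coef_table <- function(fit, X) {
  se <- sqrt(diag(fit$vcov))
  z <- fit$beta / se
  p <- 2 * stats::pnorm(-abs(z))
  k <- length(fit$beta)
  coefs <- data.frame(
    term = colnames(X),
    estimate = fit$beta,
    se = se,
    odds_ratio = exp(fit$beta),
    or_se = exp(fit$beta) * se,  # delta-method SE on the OR scale
    z = z, p = p,
    stringsAsFactors = FALSE, row.names = NULL)
  list(coefficients = coefs, logLik = fit$logLik,
       AIC = 2 * k - 2 * fit$logLik, vcov = fit$vcov,
       converged = fit$converged, terms = colnames(X))
}

#' @export
print.persistence_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<persistence_fit> n = %d dyads, logLik = %.2f, AIC = %.1f\n",
              x$n_dyads, x$logLik, x$AIC))
  print(format_coef_table(x$coefficients, digits), row.names = FALSE)
  cat("Note: s.e. column is on the log-odds scale; or_se is the delta-method\n")
  cat("standard error on the odds-ratio scale.\n")
  invisible(x)
}

format_coef_table <- function(coefs, digits = 3) {
  data.frame(predictor = coefs$term,
             `odds ratio` = signif(coefs$odds_ratio, digits),
             s.e. = signif(coefs$se, digits),
             z = signif(coefs$z, digits),
             p = signif(coefs$p, digits),
             check.names = FALSE)
}

#' Empirical edge-persistence rate
#'
#' The proportion of pre-fission ties whose members joined the same daughter
#' group. Equals the fitted probability of an intercept-only persistence
#' model.
#'
#' @param d a `persistence_dataset`.
#' @return proportion in `[0, 1]`.
#' @export
persistence_rate <- function(d) {
  if (!nrow(d)) stop("empty persistence dataset", call. = FALSE)
  mean(d$persisted)
}

#' Compare persistence models by AIC
#'
#' @param ... named `persistence_fit` objects fitted to the same dataset.
#' @return data frame with `model`, `k`, `logLik`, `AIC`, `dAIC` (difference
#'   from the best model), sorted ascending by AIC; attribute `selected`
#'   names the lowest-AIC model.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    names(fits) <- paste0("model", seq_along(fits))
  ns <- vapply(fits, function(f) f$n_dyads %||% f$n_females, numeric(1))
  if (length(unique(ns)) > 1)
    stop("models were fitted to datasets of different sizes", call. = FALSE)
  tab <- data.frame(
    model = names(fits),
    k = vapply(fits, function(f) length(f$terms), numeric(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    AIC = vapply(fits, function(f) f$AIC, numeric(1)),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$AIC), ]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  attr(tab, "selected") <- tab$model[1]
  tab
}
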