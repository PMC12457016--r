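#' Build conditional-logit choice datasets
#'
#' Each female facing a fission chooses between the two daughter groups, so
#' she contributes two rows sharing a `choice_id` — one per alternative —
#' with `chosen = 1` on the group she actually joined. Alternative
#' attributes are `resident_present` (whether the original group's resident
#' male ended up in that daughter group) and its interaction with the
#' female's DSI with that male. The DSI itself is a property of the
#' decision-maker, constant across her two rows, so it can enter the model
#' only through the interaction.
#'
#' Females are split by infanticide risk at the fission date into two
#' datasets, fitted separately; a female present in two fissions is
#' classified per event and contributes independent choices.
#'
#' @param states data frame from [female_states()] (possibly several
#'   fissions).
#' @param male_dsis data frame from [male_dsi()] for the same fissions.
#' @param ds a [behavior_dataset()] carrying fissions and assignments.
#' @return list with components `at_risk` and `not_at_risk`, each a
#'   `choice_dataset` data frame with columns `choice_id`, `fission_id`,
#'   `female_id`, `alternative`, `chosen`, `resident_present`,
#'   `dsi_with_resident`, `resident_x_dsi`.
#' @export
build_choice_datasets <- function(states, male_dsis, ds) {
  fi <- ds$fissions
  as_ <- ds$assignments
  rows <- lapply(seq_len(nrow(states)), function(k) {
    st <- states[k, ]
    ev <- st$fission_id
    f <- st$female_id
    fe <- fi[fi$event_id == ev, ]
    chosen_side <- as_$daughter[as_$event_id == ev & as_$individual_id == f]
    if (length(chosen_side) != 1)
      stop(sprintf("female %s has no daughter-group assignment in fission %s",
                   f, ev), call. = FALSE)
    dsi <- male_dsis$dsi_with_resident[male_dsis$fission_id == ev &
                                         male_dsis$female_id == f]
    if (length(dsi) != 1)
      stop(sprintf("female %s has no resident-male DSI in fission %s", f, ev),
           call. = FALSE)
    alt <- c("A", "B")
    data.frame(
      choice_id = paste(ev, f, sep = ":"),
      fission_id = ev, female_id = f, alternative = alt,
      chosen = as.integer(alt == chosen_side),
      resident_present = as.integer(alt == fe$resident_male_daughter),
      dsi_with_resident = dsi,
      resident_x_dsi = as.integer(alt == fe$resident_male_daughter) * dsi,
      at_risk = st$at_risk,
      stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  split_one <- function(flag) {
    out <- long[long$at_risk == flag, setdiff(names(long), "at_risk"),
                drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("choice_dataset", class(out))
    out
  }
  list(at_risk = split_one(TRUE), not_at_risk = split_one(FALSE))
}

#' Fit a conditional logit model of group choice
#'
#' Maximises the conditional-logit likelihood
#' \eqn{\prod_c \exp(\eta_{c,\mathrm{chosen}}) / \sum_a \exp(\eta_{c,a})}
#' over choice sets `c` with alternatives `a`. There is no intercept:
#' attributes constant across a female's alternatives cancel out of the
#' likelihood. The fit is by Newton-Raphson on the exact log-likelihood;
#' Wald standard errors come from the observed information.
#'
#' @param d a `choice_dataset` (any data frame with `choice_id`, `chosen`
#'   and the term columns; choice sets may have any number of alternatives,
#'   each with exactly one chosen row).
#' @param terms covariate column names
#'   (default `c("resident_present", "resident_x_dsi")`).
#' @param max_iter,tol Newton iteration controls.
#' @return object of class `choice_fit`: list with `coefficients` (term,
#'   estimate, se, odds_ratio, z, p), `logLik`, `AIC`, `n_choices`,
#'   `converged`, `vcov`, `terms`.
#' @export
fit_conditional_logit <- function(d, terms = c("resident_present", "resident_x_dsi"),
                                  max_iter = 100, tol = 1e-10) {
  missing_cols <- setdiff(terms, names(d))
  if (length(missing_cols))
    stop(sprintf("terms not present in dataset: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  grp <- factor(d$choice_id, levels = unique(d$choice_id))
  sizes <- table(grp)
  if (any(sizes < 2))
    stop("every choice set needs at least 2 alternatives", call. = FALSE)
  one <- tapply(d$chosen, grp, sum)
  if (any(one != 1))
    stop("every choice set must have exactly one chosen alternative",
         call. = FALSE)
  X <- as.matrix(d[, terms, drop = FALSE])
  # drop covariates that never vary within a choice set: they cancel from
  # the likelihood and leave the model unidentified
  varies <- vapply(seq_len(ncol(X)), function(j) {
    any(tapply(X[, j], grp, function(v) max(v) - min(v)) > 0)
  }, logical(1))
  if (!all(varies)) {
    warning(sprintf(
      "dropping alternative-invariant covariate(s) that cancel from the likelihood: %s",
      paste(terms[!varies], collapse = ", ")))
    terms <- terms[varies]
    if (!length(terms))
      stop("no covariate varies within choice sets; model is unidentified",
           call. = FALSE)
    X <- X[, varies, drop = FALSE]
  }
  y <- d$chosen
  idx <- as.integer(grp)
  n_sets <- nlevels(grp)

  loglik_grad_hess <- function(beta) {
    eta <- drop(X %*% beta)
    eta <- eta - ave(eta, idx, FUN = max)  # stabilise softmax per set
    expeta <- exp(eta)
    denom <- as.vector(tapply(expeta, idx, sum))[idx]
    p <- expeta / denom
    ll <- sum(log(p[y == 1]))
    resid <- y - p
    grad <- drop(crossprod(X, resid))
    # Hessian: -sum_c [ sum_a p x x' - (sum_a p x)(sum_a p x)' ]
    H <- crossprod(X * p, X)
    xbar <- rowsum(X * p, idx)            # per-set sum of p * x
    H <- H - crossprod(xbar)
    list(ll = ll, grad = grad, H = H)
  }

  beta <- rep(0, ncol(X))
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    lgh <- loglik_grad_hess(beta)
    step <- tryCatch(solve(lgh$H, lgh$grad), error = function(e)
      stop("singular information matrix (possible separation): ",
           conditionMessage(e), call. = FALSE))
    beta <- beta + step
    trace <- c(trace, max(abs(lgh$grad)))
    if (max(abs(step)) < tol || max(abs(lgh$grad)) < tol) {
      if (max(abs(beta)) > 30)
        stop(sprintf(
          "apparent complete separation: |coefficient| > 30 (iteration trace: %s)",
          paste(signif(trace, 3), collapse = ", ")), call. = FALSE)
      lgh <- loglik_grad_hess(beta)
      vcov <- solve(lgh$H)
      out <- coef_table(list(beta = beta, vcov = vcov, logLik = lgh$ll,
                             converged = TRUE), X)
      out$n_choices <- n_sets
      return(structure(out, class = "choice_fit"))
    }
  }
  stop(sprintf("Newton iteration did not converge in %d steps (gradient trace: %s)",
               max_iter, paste(signif(utils::tail(trace, 5), 3), collapse = ", ")),
       call. = FALSE)
}

#' @export
print.choice_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<choice_fit> n = %d choices, logLik = %.2f, AIC = %.1f\n",
              x$n_choices, x$logLik, x$AIC))
  print(format_coef_table(x$coefficients, digits), row.names = FALSE)
  invisible(x)
}

#' Predicted choice probabilities
#'
#' Softmax of the fitted linear predictor over the alternatives of one
#' choice set; the probabilities sum to 1.
#'
#' @param fit a `choice_fit`.
#' @param covariates matrix or data frame with one row per alternative and
#'   the fitted term columns.
#' @return numeric vector of probabilities, one per alternative.
#' @export
predicted_choice_probability <- function(fit, covariates) {
  terms <- fit$coefficients$term
  X <- as.matrix(as.data.frame(covariates)[, terms, drop = FALSE])
  eta <- drop(X %*% fit$coefficients$estimate)
  eta <- eta - max(eta)
  exp(eta) / sum(exp(eta))
}
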