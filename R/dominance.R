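#' Winner-loser contest matrix for a group-year
#'
#' Aggregates agonistic interactions with clear outcomes (ad libitum and
#' focal records are already pooled in the `agonistic` table) into a square
#' count matrix, `wins[a, b]` = number of contests `a` won against `b`.
#' Records are restricted to the given calendar year and, because hierarchy
#' position should reflect relationships while the group was intact, to
#' dates on or before `until` (normally the fission completion date).
#'
#' @param ds a [behavior_dataset()].
#' @param group group id.
#' @param year calendar year (integer).
#' @param until latest date included (default: end of `year`).
#' @param ids individuals to include; default: all appearing in the filtered
#'   records.
#' @return object of class `contest_matrix`: a list with `ids`, `wins`,
#'   `group_id`, `year`.
#' @export
build_contest_matrix <- function(ds, group, year, until = NULL, ids = NULL) {
  ag <- ds$agonistic[ds$agonistic$group_id == group, , drop = FALSE]
  ag <- ag[as.integer(format(ag$date, "%Y")) == year, , drop = FALSE]
  if (!is.null(until)) ag <- ag[ag$date <= as.Date(until), , drop = FALSE]
  if (is.null(ids)) ids <- sort(unique(c(ag$winner_id, ag$loser_id)))
  ag <- ag[ag$winner_id %in% ids & ag$loser_id %in% ids, , drop = FALSE]
  n <- length(ids)
  wins <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (nrow(ag)) {
    tab <- table(factor(ag$winner_id, ids), factor(ag$loser_id, ids))
    wins <- wins + unclass(tab)
    storage.mode(wins) <- "integer"
  } else {
    warning(sprintf("group %s year %d: no agonistic interactions; hierarchy undefined",
                    group, year))
  }
  structure(list(ids = ids, wins = wins, group_id = group, year = year),
            class = "contest_matrix")
}

# (I, SI) of an ordering: a dyad is inconsistent when the individual ranked
# lower won more contests than the one ranked higher; its strength is the
# rank distance. Ties in wins and unknown relationships are not
# inconsistencies.
order_inconsistencies <- function(wins, ord) {
  w <- wins[ord, ord, drop = FALSE]
  lower_beats_upper <- t(w) > w  # [i, j]: j (ranked below i) beat i more often
  lower_beats_upper[lower.tri(lower_beats_upper, diag = TRUE)] <- FALSE
  idx <- which(lower_beats_upper, arr.ind = TRUE)
  c(I = nrow(idx), SI = if (nrow(idx)) sum(idx[, 2] - idx[, 1]) else 0L)
}

# Lexicographic comparison of (I, SI) pairs: is a strictly better than b?
isi_better <- function(a, b) {
  a[1] < b[1] || (a[1] == b[1] && a[2] < b[2])
}

# David's scores (Dij proportions with the 1/2 correction for unknown
# relationships omitted; simple P-based variant) used only to seed the
# search with a sensible initial order.
davids_score <- function(wins) {
  n <- nrow(wins)
  total <- wins + t(wins)
  P <- ifelse(total > 0, wins / total, 0)
  w1 <- rowSums(P)
  l1 <- colSums(P)
  w2 <- as.vector(P %*% w1)
  l2 <- as.vector(t(P) %*% l1)
  w1 + w2 - l1 - l2
}

# One hill-climbing pass: try all pairwise position swaps, accept the first
# strict improvement, repeat until no swap improves (I, SI).
isi_hillclimb <- function(wins, ord) {
  best <- order_inconsistencies(wins, ord)
  n <- length(ord)
  improved <- TRUE
  while (improved && best["I"] + best["SI"] > 0) {
    improved <- FALSE
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        cand <- ord
        cand[c(a, b)] <- cand[c(b, a)]
        val <- order_inconsistencies(wins, cand)
        if (isi_better(val, best)) {
          ord <- cand
          best <- val
          improved <- TRUE
        }
      }
    }
  }
  list(order = ord, value = best)
}

#' I&SI ordinal dominance hierarchy
#'
#' Finds a linear order of the individuals that minimises, lexicographically,
#' first the number of inconsistencies `I` (dyads in which the lower-ranked
#' individual won the majority of contests) and then their total strength
#' `SI` (the summed rank distances of inconsistent dyads). The search is a
#' two-phase heuristic: an initial order by David's score followed by
#' pairwise-swap hill climbing, repeated from seeded random restarts. For
#' small matrices (n <= 7) the result can be checked against exhaustive
#' enumeration with [isi_exhaustive()].
#'
#' @param m a `contest_matrix` from [build_contest_matrix()], or a square
#'   named count matrix.
#' @param seed integer seed controlling the random restarts; the result is
#'   deterministic given the matrix and seed.
#' @param restarts number of random restarts (default 50).
#' @param max_iter cap on total hill-climbing passes; if exhausted,
#'   `converged` is `FALSE` and the best order found is returned.
#' @return object of class `isi_hierarchy`: list with `order` (ids, rank 1
#'   first), `ranks` (named integer vector), `I`, `SI`, `converged`,
#'   `degeneracy` (number of distinct optima found across restarts), `seed`.
#' @export
isi_order <- function(m, seed = 1L, restarts = 50L, max_iter = 1000L) {
  wins <- if (inherits(m, "contest_matrix")) m$wins else m
  ids <- rownames(wins) %||% as.character(seq_len(nrow(wins)))
  n <- nrow(wins)
  if (n < 2) stop("need at least 2 individuals to rank", call. = FALSE)

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)

  init <- order(-davids_score(wins))
  res <- isi_hillclimb(wins, init)
  best_ord <- res$order
  best_val <- res$value
  optima <- list(paste(best_ord, collapse = ","))
  iter <- 1L
  converged <- TRUE
  for (r in seq_len(restarts)) {
    if (iter >= max_iter) { converged <- FALSE; break }
    res <- isi_hillclimb(wins, sample.int(n))
    iter <- iter + 1L
    key <- paste(res$order, collapse = ",")
    if (isi_better(res$value, best_val)) {
      best_ord <- res$order
      best_val <- res$value
      optima <- list(key)
    } else if (res$value[1] == best_val[1] && res$value[2] == best_val[2] &&
               !key %in% optima) {
      optima <- c(optima, key)
    }
    if (best_val["I"] == 0 && best_val["SI"] == 0) break
  }
  ranks <- integer(n)
  ranks[best_ord] <- seq_len(n)
  names(ranks) <- ids
  structure(list(order = ids[best_ord], ranks = ranks,
                 I = as.integer(best_val["I"]), SI = as.integer(best_val["SI"]),
                 converged = converged, degeneracy = length(optima),
                 seed = seed),
            class = "isi_hierarchy")
}

#' @export
print.isi_hierarchy <- function(x, ...) {
  cat(sprintf("<isi_hierarchy> n = %d, I = %d, SI = %d%s\n", length(x$order),
              x$I, x$SI, if (x$converged) "" else " (search not converged)"))
  cat("  order (top first):", paste(x$order, collapse = " > "), "\n")
  invisible(x)
}

#' Exhaustive I&SI optimum (oracle for small matrices)
#'
#' Enumerates all orderings of at most 8 individuals and returns the
#' lexicographically minimal `(I, SI)`. Intended as an independent check on
#' [isi_order()]; cost is factorial in n.
#'
#' @param m contest matrix (as in [isi_order()]).
#' @return list with `I`, `SI`, and one optimal `order` (ids).
#' @export
isi_exhaustive <- function(m) {
  wins <- if (inherits(m, "contest_matrix")) m$wins else m
  ids <- rownames(wins) %||% as.character(seq_len(nrow(wins)))
  n <- nrow(wins)
  if (n > 8) stop("exhaustive search limited to n <= 8", call. = FALSE)
  perms <- all_permutations(n)
  best_val <- c(I = Inf, SI = Inf)
  best_ord <- NULL
  for (k in seq_len(nrow(perms))) {
    val <- order_inconsistencies(wins, perms[k, ])
    if (isi_better(val, best_val)) {
      best_val <- val
      best_ord <- perms[k, ]
    }
  }
  list(I = as.integer(best_val["I"]), SI = as.integer(best_val["SI"]),
       order = ids[best_ord])
}

# All permutations of 1..n as a matrix (n! rows).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    for (k in seq_len(nrow(sub))) {
      out[row, ] <- append(sub[k, ], n, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

#' Dyadic rank distance and its Z-score standardisation
#'
#' `rank_distance` counts the ordinal rank steps between two individuals in
#' the same hierarchy. `standardize_rankdist` converts pooled distances to
#' Z-scores (mean 0, SD 1) over the full set of dyads entering a model,
#' which eases model convergence without changing the information content.
#'
#' @param h an `isi_hierarchy` from [isi_order()].
#' @param i,j ranked individual ids.
#' @return integer rank distance.
#' @export
rank_distance <- function(h, i, j) {
  if (!all(c(i, j) %in% names(h$ranks)))
    stop(sprintf("unranked individual: %s",
                 paste(setdiff(c(i, j), names(h$ranks)), collapse = ", ")),
         call. = FALSE)
  abs(h$ranks[[i]] - h$ranks[[j]])
}

#' @rdname rank_distance
#' @param d numeric vector of pooled rank distances.
#' @return for `standardize_rankdist`, the vector of Z-scores.
#' @export
standardize_rankdist <- function(d) {
  s <- stats::sd(d)
  if (is.na(s) || s == 0) return(rep(0, length(d)))
  (d - mean(d)) / s
}
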