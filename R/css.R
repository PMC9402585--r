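## Combinatory NOG signature sets (NOG_CSS): choose how many signatures vote
## jointly and the low/high vote cutoffs. Selection is greedy-forward on
## individual low-risk precision with an explicit stopping rule; the
## published breast-cancer cutoffs ship as a preset.

#' CSS selection parameters
#'
#' @param eps_acc minimum low-risk precision improvement (fraction) below
#'   which an added signature counts as "no significant improvement"
#'   (default 0.005, i.e. half a percentage point).
#' @param eps_rec low-risk recall drop (fraction) beyond which an added
#'   signature counts as "significantly dropped recall" (default 0.02).
#' @param recall_floor minimum low-risk recall a cutoff pair must keep
#'   during the LN/HN grid search (default 0.10).
#' @param n_cutoff size of the held-aside cutoff set (default 60).
#' @return parameter list.
#' @export
css_config <- function(eps_acc = 0.005, eps_rec = 0.02, recall_floor = 0.10,
                       n_cutoff = 60L) {
  list(eps_acc = eps_acc, eps_rec = eps_rec, recall_floor = recall_floor,
       n_cutoff = as.integer(n_cutoff))
}

#' Published cutoff presets
#'
#' `er-founding-clone`: M = 18 signatures, LN = 9, HN = 15 (founding
#' clone-based sets for ER+ breast cancer).
#'
#' @param name preset name.
#' @return list with `M`, `LN`, `HN`.
#' @export
css_preset <- function(name = "er-founding-clone") {
  presets <- list(`er-founding-clone` = list(M = 18L, LN = 9L, HN = 15L))
  presets[[name]] %||% stop_fmt("unknown preset '%s'", name)
}

#' Split samples into training and cutoff sets
#'
#' Draws `n_cutoff` samples uniformly without replacement; deterministic
#' per seed.
#'
#' @param sample_ids character vector of sample ids.
#' @param n_cutoff cutoff-set size (default 60; must be < number of
#'   samples).
#' @param seed RNG seed.
#' @return list with `training` and `cutoff` (disjoint id vectors).
#' @export
split_cutoff_set <- function(sample_ids, n_cutoff = 60L, seed = 1L) {
  if (n_cutoff >= length(sample_ids)) {
    stop_fmt("n_cutoff (%d) must be smaller than the number of samples (%d)",
             n_cutoff, length(sample_ids))
  }
  if (n_cutoff == 0L) return(list(training = sample_ids, cutoff = character()))
  cutoff <- with_seed(seed, sample(sample_ids, n_cutoff))
  list(training = setdiff(sample_ids, cutoff), cutoff = cutoff)
}

#' Precision and recall of risk calls
#'
#' Low-risk precision is the fraction of non-recurred samples among the
#' predicted-low group; low-risk recall the fraction of non-recurred
#' samples that are predicted low. The high-risk group is symmetric with
#' recurred samples. Unclassified samples are excluded from the
#' denominators of precision and counted in `n_unclassified`; a group with
#' no prediction has `NA` precision.
#'
#' @param calls risk-call `data.frame` (see [classify_samples()]).
#' @param events named 0/1 vector (sample -> recurrence event).
#' @return list with `low`/`high` (each `precision`, `recall`, `n_predicted`)
#'   and `n_unclassified`.
#' @export
evaluate_risk_calls <- function(calls, events) {
  ev <- events[calls$sample_id]
  if (anyNA(ev)) stop_fmt("events do not cover all called samples")
  grp <- function(call_name, target_event) {
    pred <- calls$call == call_name
    n_pred <- sum(pred)
    list(precision = if (n_pred) mean(ev[pred] == target_event) else NA_real_,
         recall = if (sum(ev == target_event)) {
           sum(pred & ev == target_event) / sum(ev == target_event)
         } else NA_real_,
         n_predicted = n_pred)
  }
  list(low = grp("low", 0L), high = grp("high", 1L),
       n_unclassified = sum(calls$call == "unclassified"))
}

## Evaluate one candidate ordering prefix under the best (LN, HN) pair.
## Votes are computed once; cutoff pairs just re-aggregate counts.
best_cutoffs <- function(vote_mat, events, n_sig, config) {
  low_cnt <- rowSums(vote_mat[, seq_len(n_sig), drop = FALSE] == "low")
  high_cnt <- rowSums(vote_mat[, seq_len(n_sig), drop = FALSE] == "high")
  best <- NULL
  fallback <- NULL
  for (hn in seq_len(n_sig)) {
    for (ln in seq_len(n_sig)) {
      if (ln + hn <= n_sig) next
      call <- ifelse(high_cnt >= hn, "high",
                     ifelse(low_cnt >= ln, "low", "unclassified"))
      evd <- evaluate_risk_calls(
        data.frame(sample_id = names(events), call = call), events)
      cand <- list(ln = ln, hn = hn, precision = evd$low$precision,
                   recall = evd$low$recall, evaluation = evd)
      score <- function(x) if (is.na(x$precision)) -Inf else x$precision
      if (is.null(fallback) || score(cand) > score(fallback)) fallback <- cand
      if (!is.na(cand$recall) && cand$recall >= config$recall_floor) {
        if (is.null(best) || score(cand) > score(best)) best <- cand
      }
    }
  }
  if (is.null(best)) {
    warn_fmt("no (LN, HN) pair reaches low-risk recall >= %g; using best-precision pair",
             config$recall_floor)
    best <- fallback
  }
  best
}

#' Select the number of signatures for a combinatory set
#'
#' Greedy forward selection: candidates are ordered by their individual
#' low-risk precision on the selection cohort; for growing N the top-N set
#' is evaluated under the best (LN, HN) cutoff pair (grid search with
#' LN + HN > N, maximizing low-risk precision subject to a recall floor).
#' Selection stops at the smallest N where adding one more signature
#' improves low-risk precision by less than `eps_acc` while dropping
#' low-risk recall by more than `eps_rec`.
#'
#' @param candidates list of `nog_signature` objects.
#' @param nm normalized netMatrix of the selection cohort (training +
#'   cutoff samples).
#' @param clinical clinical table covering the netMatrix samples.
#' @param config parameters from [css_config()].
#' @param delta centroid shrinkage (default 0).
#' @return object of class `nog_css`: `signatures` (ordered list), `N`,
#'   `M` (= N), `LN`, `HN`, and a selection `trace` data frame.
#' @export
select_n_signatures <- function(candidates, nm, clinical,
                                config = css_config(), delta = 0) {
  if (!length(candidates)) stop_fmt("no candidate signatures")
  cl <- align_clinical(nm, clinical)
  labels <- cl$dfs_event == 1L
  events <- setNames(cl$dfs_event, cl$sample_id)

  ## one vote column per candidate, computed once
  vote_mat <- vapply(candidates, function(sig) {
    mod <- train_centroids(sig, nm, labels, delta)
    vapply(seq_len(ncol(nm)), function(j) vote(nm[, j], mod), character(1L))
  }, character(ncol(nm)))
  vote_mat <- matrix(vote_mat, nrow = ncol(nm))
  rownames(vote_mat) <- colnames(nm)

  solo_prec <- vapply(seq_along(candidates), function(k) {
    call <- ifelse(vote_mat[, k] == "high", "high",
                   ifelse(vote_mat[, k] == "low", "low", "unclassified"))
    p <- evaluate_risk_calls(
      data.frame(sample_id = colnames(nm), call = call), events)$low$precision
    if (is.na(p)) -Inf else p
  }, numeric(1L))
  ord <- order(-solo_prec)
  candidates <- candidates[ord]
  vote_mat <- vote_mat[, ord, drop = FALSE]

  k_max <- length(candidates)
  evals <- vector("list", k_max)
  for (n_sig in seq_len(k_max)) {
    evals[[n_sig]] <- best_cutoffs(vote_mat, events, n_sig, config)
  }
  chosen <- k_max
  for (n_sig in seq_len(k_max - 1L)) {
    d_prec <- evals[[n_sig + 1L]]$precision - evals[[n_sig]]$precision
    d_rec <- evals[[n_sig]]$recall - evals[[n_sig + 1L]]$recall
    if (!is.na(d_prec) && !is.na(d_rec) &&
        d_prec < config$eps_acc && d_rec > config$eps_rec) {
      chosen <- n_sig
      break
    }
  }
  sel <- evals[[chosen]]
  trace <- do.call(rbind, lapply(seq_len(k_max), function(k) {
    data.frame(N = k, LN = evals[[k]]$ln, HN = evals[[k]]$hn,
               low_precision = evals[[k]]$precision,
               low_recall = evals[[k]]$recall)
  }))
  structure(list(signatures = candidates[seq_len(chosen)], N = chosen,
                 M = chosen, LN = sel$ln, HN = sel$hn, trace = trace),
            class = "nog_css")
}

#' @export
print.nog_css <- function(x, ...) {
  cat(sprintf("NOG_CSS: %d signature(s), LN = %d, HN = %d\n", x$N, x$LN, x$HN))
  invisible(x)
}

#' Evaluate a signature set on a cohort
#'
#' Trains the set's centroid models on the cohort labels, classifies every
#' sample, and reports per-group precision/recall.
#'
#' @param css `nog_css`.
#' @param nm normalized netMatrix.
#' @param clinical clinical table covering the netMatrix samples.
#' @param delta centroid shrinkage (default 0).
#' @return list with `calls` and `evaluation`.
#' @export
evaluate_css <- function(css, nm, clinical, delta = 0) {
  cl <- align_clinical(nm, clinical)
  calls <- classify_samples(css, nm, cl$dfs_event == 1L, delta)
  list(calls = calls,
       evaluation = evaluate_risk_calls(calls,
                                        setNames(cl$dfs_event, cl$sample_id)))
}
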