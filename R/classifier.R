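## Per-signature nearest-shrunken-centroid models voting on samples, vote
## aggregation into low/high/unclassified calls, and leave-one-out
## cross-validation. Centroid shrinkage follows the nearest-shrunken-centroid
## scheme (class-vs-overall standardized differences soft-thresholded by
## delta); classification is by correlation of a sample's signature-gene
## profile with the two state centroids, as in intrinsic-subtype
## centroid classifiers, with Euclidean distance available as an option.

#' Train a (shrunken) centroid model for one signature
#'
#' Class centroids over the signature genes. Each gene's class-vs-overall
#' standardized difference `d` is soft-thresholded,
#' `d' = sign(d) max(|d| - delta, 0)`, and the centroid rebuilt from `d'`;
#' `delta = 0` reduces exactly to plain class means, and a `delta` larger
#' than every `|d|` collapses both centroids onto the overall mean.
#'
#' @param signature `nog_signature` (or any list with a `genes` field).
#' @param nm normalized netMatrix containing the signature genes.
#' @param labels logical or 0/1 vector over netMatrix samples
#'   (`TRUE`/1 = recurred); both classes need at least 2 samples.
#' @param delta non-negative shrinkage amount (default 0).
#' @return object of class `centroid_model` with per-class centroids
#'   (`centroid_high` = recurred state, `centroid_low` = non-recurred).
#' @export
train_centroids <- function(signature, nm, labels, delta = 0) {
  if (delta < 0) stop_fmt("delta must be non-negative")
  labels <- as.logical(labels)
  genes <- signature$genes
  miss <- setdiff(genes, rownames(nm))
  if (length(miss)) stop_fmt("netMatrix lacks signature gene(s): %s",
                             paste(head(miss, 5L), collapse = ", "))
  x <- nm[genes, , drop = FALSE]
  n1 <- sum(labels); n0 <- sum(!labels); n <- n1 + n0
  if (n1 < 2L || n0 < 2L) stop_fmt("each class needs >= 2 samples (got %d/%d)",
                                   n0, n1)
  m_all <- rowMeans(x)
  m1 <- rowMeans(x[, labels, drop = FALSE])
  m0 <- rowMeans(x[, !labels, drop = FALSE])
  ## pooled within-class standard deviation per gene
  ss <- rowSums((x[, labels, drop = FALSE] - m1)^2) +
    rowSums((x[, !labels, drop = FALSE] - m0)^2)
  s <- sqrt(ss / (n - 2))
  s0 <- median(s)
  shrink <- function(mk, nk) {
    mfac <- sqrt(1 / nk - 1 / n)
    d <- (mk - m_all) / (mfac * (s + s0))
    d_shr <- sign(d) * pmax(abs(d) - delta, 0)
    m_all + mfac * (s + s0) * d_shr
  }
  structure(list(genes = genes, centroid_high = shrink(m1, n1),
                 centroid_low = shrink(m0, n0), sd = s, s0 = s0,
                 delta = delta, n_high = n1, n_low = n0),
            class = "centroid_model")
}

#' Vote of one centroid model on one sample profile
#'
#' Correlates the sample's signature-gene scores with the two state
#' centroids (Pearson); the closer state wins: the recurred state votes
#' `"high"`, the non-recurred state `"low"`. Ties within `tie_epsilon`, a
#' zero-variance profile, or undefined correlations abstain. With
#' `method = "distance"` the negative Euclidean distance replaces the
#' correlation.
#'
#' @param profile named numeric vector (or netMatrix column) covering the
#'   signature genes.
#' @param model `centroid_model` from [train_centroids()].
#' @param method `"correlation"` (default) or `"distance"`.
#' @param tie_epsilon similarity difference below which the vote abstains.
#' @return `"low"`, `"high"`, or `"abstain"`.
#' @export
vote <- function(profile, model, method = c("correlation", "distance"),
                 tie_epsilon = 1e-6) {
  method <- match.arg(method)
  x <- profile[model$genes]
  if (anyNA(x)) stop_fmt("profile does not cover the signature genes")
  if (method == "correlation") {
    if (sd(x) == 0) return("abstain")
    s_high <- suppressWarnings(cor(x, model$centroid_high))
    s_low <- suppressWarnings(cor(x, model$centroid_low))
    if (is.na(s_high) || is.na(s_low)) return("abstain")
  } else {
    s_high <- -sqrt(sum((x - model$centroid_high)^2))
    s_low <- -sqrt(sum((x - model$centroid_low)^2))
  }
  if (abs(s_high - s_low) < tie_epsilon) return("abstain")
  if (s_high > s_low) "high" else "low"
}

#' Aggregate per-signature votes into a risk call
#'
#' With vote cutoffs LN (low) and HN (high) satisfying `LN + HN > M`, a
#' sample is called high risk when at least HN signatures vote high,
#' otherwise low risk when at least LN vote low, otherwise unclassified.
#' The cutoff constraint makes the two calls mutually exclusive; the
#' high-before-low order is declared for total determinism.
#'
#' @param votes character vector of `"low"`/`"high"`/`"abstain"`, one per
#'   signature.
#' @param ln,hn low-/high-risk vote cutoffs.
#' @return list with `low_votes`, `high_votes`, `abstentions`, `call`.
#' @export
aggregate_votes <- function(votes, ln, hn) {
  low <- sum(votes == "low")
  high <- sum(votes == "high")
  call <- if (high >= hn) "high" else if (low >= ln) "low" else "unclassified"
  list(low_votes = low, high_votes = high,
       abstentions = length(votes) - low - high, call = call)
}

#' Classify every netMatrix sample with a signature set
#'
#' Trains one centroid model per signature on the given labels and lets
#' every model vote on every sample; votes aggregate under the set's
#' LN/HN cutoffs.
#'
#' @param css `nog_css` (or list with `signatures`, `LN`, `HN`).
#' @param nm normalized netMatrix.
#' @param labels logical or 0/1 recurrence labels used for training.
#' @param delta centroid shrinkage (default 0).
#' @param method vote similarity, see [vote()].
#' @return `data.frame` of risk calls: `sample_id`, `low_votes`,
#'   `high_votes`, `abstentions`, `call`.
#' @export
classify_samples <- function(css, nm, labels, delta = 0,
                             method = "correlation") {
  models <- lapply(css$signatures, train_centroids, nm = nm, labels = labels,
                   delta = delta)
  votes <- vapply(models, function(mod) {
    vapply(seq_len(ncol(nm)), function(j) vote(nm[, j], mod, method),
           character(1L))
  }, character(ncol(nm)))
  votes <- matrix(votes, nrow = ncol(nm))
  calls <- lapply(seq_len(ncol(nm)), function(j) {
    aggregate_votes(votes[j, ], css$LN, css$HN)
  })
  data.frame(sample_id = colnames(nm),
             low_votes = vapply(calls, `[[`, integer(1L), "low_votes"),
             high_votes = vapply(calls, `[[`, integer(1L), "high_votes"),
             abstentions = vapply(calls, `[[`, integer(1L), "abstentions"),
             call = vapply(calls, `[[`, character(1L), "call"))
}

#' Leave-one-out cross-validation of a signature set
#'
#' For every sample: every signature's centroid model is retrained on all
#' other samples (the held-out sample never touches its own centroids), the
#' models vote, and votes aggregate under the set's LN/HN cutoffs. Folds in
#' which a training class would drop below 2 samples are skipped with a
#' warning. Precision and recall are computed per risk group from the
#' classified samples.
#'
#' @param css `nog_css` (or list with `signatures`, `LN`, `HN`).
#' @param nm normalized netMatrix.
#' @param clinical clinical table covering the netMatrix samples.
#' @param delta centroid shrinkage (default 0).
#' @param method vote similarity, see [vote()].
#' @return list with `calls` (risk-call `data.frame`) and `evaluation`
#'   (see [evaluate_risk_calls()]).
#' @export
loocv <- function(css, nm, clinical, delta = 0, method = "correlation") {
  cl <- align_clinical(nm, clinical)
  labels <- cl$dfs_event == 1L
  n <- ncol(nm)
  rows <- vector("list", n)
  skipped <- 0L
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), i)
    lab_i <- labels[keep]
    if (sum(lab_i) < 2L || sum(!lab_i) < 2L) {
      skipped <- skipped + 1L
      next
    }
    nm_i <- nm[, keep, drop = FALSE]
    votes <- vapply(css$signatures, function(sig) {
      vote(nm[, i], train_centroids(sig, nm_i, lab_i, delta), method)
    }, character(1L))
    agg <- aggregate_votes(votes, css$LN, css$HN)
    rows[[i]] <- data.frame(sample_id = colnames(nm)[i],
                            low_votes = agg$low_votes,
                            high_votes = agg$high_votes,
                            abstentions = agg$abstentions, call = agg$call)
  }
  if (skipped) warn_fmt("loocv: skipped %d fold(s) with an emptied class", skipped)
  calls <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(calls)) {
    calls <- data.frame(sample_id = character(), low_votes = integer(),
                        high_votes = integer(), abstentions = integer(),
                        call = character())
  }
  events <- setNames(cl$dfs_event, cl$sample_id)
  list(calls = calls, evaluation = evaluate_risk_calls(calls, events))
}
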