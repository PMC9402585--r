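## The modified Multiple Survival Screening (MSS) core: from a labeled
## netMatrix, discover 30-gene network operational gene (NOG) signatures per
## cancer hallmark. Random 30-gene sets drawn from hallmark pools are
## retained when their mean heating score stratifies survival (fuzzy 2-means
## + log-rank) on strictly more than 80% of 200 random sample subsets; gene
## frequency across retained sets ranks the signature.

#' MSS screening parameters
#'
#' The published procedure draws 5e6 random gene sets; the desk-scale
#' default here is 1e4 with the 1000--5000 retention band scaled by
#' `n_random_gene_sets / 5e6`. The algorithm is unchanged by the scale.
#'
#' @param modulated_p per-gene log-rank cutoff for the modulated-gene screen
#'   (default 0.05); also the initial per-subset cutoff of the gene-set
#'   screen.
#' @param n_random_sample_sets number of random sample subsets ("random
#'   netMatrix sets", default 200).
#' @param sample_set_fraction fraction of samples per subset (default 0.60).
#' @param n_random_gene_sets number of random gene sets per hallmark
#'   (default 1e4; published scale 5e6).
#' @param gene_set_size genes per random set (default 30).
#' @param pass_fraction a set is retained when it passes on strictly more
#'   than this fraction of the sample subsets (default 0.80).
#' @param retained_min,retained_max retention band at the published 5e6
#'   scale (defaults 1000 and 5000): below the (scaled) minimum the hallmark
#'   is discarded; above the (scaled) maximum the cutoff is tightened.
#' @param signature_size genes per signature (default 30).
#' @param fuzzifier fuzzy c-means fuzzifier m (default 2).
#' @param pool_range expected hallmark pool size range; pools outside it are
#'   kept with a warning (default 100--200).
#' @return parameter list.
#' @export
mss_config <- function(modulated_p = 0.05, n_random_sample_sets = 200L,
                       sample_set_fraction = 0.60,
                       n_random_gene_sets = 10000L, gene_set_size = 30L,
                       pass_fraction = 0.80, retained_min = 1000L,
                       retained_max = 5000L, signature_size = 30L,
                       fuzzifier = 2, pool_range = c(100L, 200L)) {
  check_fraction(modulated_p, "modulated_p", lo_open = TRUE, hi_open = TRUE)
  check_fraction(sample_set_fraction, "sample_set_fraction", lo_open = TRUE)
  check_fraction(pass_fraction, "pass_fraction", lo_open = TRUE, hi_open = TRUE)
  if (retained_min >= retained_max) stop_fmt("retained_min must be < retained_max")
  if (fuzzifier <= 1) stop_fmt("fuzzifier must exceed 1")
  list(modulated_p = modulated_p,
       n_random_sample_sets = as.integer(n_random_sample_sets),
       sample_set_fraction = sample_set_fraction,
       n_random_gene_sets = as.integer(n_random_gene_sets),
       gene_set_size = as.integer(gene_set_size),
       pass_fraction = pass_fraction,
       retained_min = as.integer(retained_min),
       retained_max = as.integer(retained_max),
       signature_size = as.integer(signature_size),
       fuzzifier = fuzzifier, pool_range = as.integer(pool_range))
}

#' Fuzzy two-class bipartition of a score vector
#'
#' Fuzzy c-means with k = 2, deterministic: centers start at the 25th/75th
#' percentiles, samples are hard-assigned to the cluster of maximal
#' membership. Cluster 1 is the low-score state, cluster 2 the high-score
#' state.
#'
#' @param values numeric vector (at least two distinct values).
#' @param m fuzzifier (default 2).
#' @return list with `cluster` (1/2 per value), `centers` (ascending) and
#'   `membership` (membership of the high cluster).
#' @export
fuzzy_bipartition <- function(values, m = 2) {
  if (length(values) < 2L) stop_fmt("fuzzy_bipartition needs >= 2 values")
  res <- .fcm2_cpp(as.numeric(values), m)
  if (!isTRUE(res$ok)) stop_fmt("degenerate clustering: all values identical")
  d1 <- abs(values - res$centers[1L])
  d2 <- abs(values - res$centers[2L])
  u_high <- ifelse(d1 == 0 & d2 == 0, 0.5,
                   ifelse(d2 == 0, 1, ifelse(d1 == 0, 0,
                          1 / (1 + (d2 / d1)^(2 / (m - 1))))))
  list(cluster = res$cluster, centers = res$centers, membership = u_high)
}

#' Two-group log-rank test P value
#'
#' Standard log-rank chi-square comparison of the survival of two disjoint
#' sample groups, via `survival::survdiff`.
#'
#' @param groupA,groupB character vectors of sample ids (non-empty,
#'   disjoint).
#' @param clinical clinical table with `sample_id`, `dfs_time`, `dfs_event`.
#' @return the log-rank P value.
#' @export
logrank_p <- function(groupA, groupB, clinical) {
  if (!length(groupA) || !length(groupB)) stop_fmt("both groups must be non-empty")
  if (length(intersect(groupA, groupB))) stop_fmt("groups overlap")
  ids <- c(groupA, groupB)
  cl <- clinical[match(ids, clinical$sample_id), ]
  if (anyNA(cl$sample_id)) stop_fmt("clinical table does not cover both groups")
  if (!any(cl$dfs_event == 1L)) stop_fmt("no events")
  grp <- rep(c("A", "B"), c(length(groupA), length(groupB)))
  fit <- survival::survdiff(survival::Surv(cl$dfs_time, cl$dfs_event) ~ grp)
  as.numeric(pchisq(fit$chisq, df = 1L, lower.tail = FALSE))
}

## Align a clinical table with netMatrix columns, erroring on gaps.
align_clinical <- function(nm, clinical) {
  cl <- clinical[match(colnames(nm), clinical$sample_id), ]
  if (anyNA(cl$sample_id)) {
    stop_fmt("clinical table does not cover netMatrix sample(s): %s",
             paste(head(setdiff(colnames(nm), clinical$sample_id), 5L),
                   collapse = ", "))
  }
  cl
}

#' Modulated genes of a netMatrix
#'
#' Per gene: fuzzy bipartition of its heating scores across samples, then a
#' log-rank test between the two clusters; genes with P < `modulated_p` are
#' modulated. Degenerate (constant) genes are skipped with a message.
#'
#' @param nm normalized netMatrix (genes x samples).
#' @param clinical clinical table covering the netMatrix samples.
#' @param config parameters from [mss_config()].
#' @return character vector of modulated genes.
#' @export
find_modulated_genes <- function(nm, clinical, config = mss_config()) {
  cl <- align_clinical(nm, clinical)
  if (!any(cl$dfs_event == 1L)) stop_fmt("no events")
  p <- .row_fuzzy_logrank_cpp(nm, cl$dfs_time, cl$dfs_event, config$fuzzifier)
  if (anyNA(p)) {
    message(sprintf("find_modulated_genes: skipped %d degenerate gene(s)",
                    sum(is.na(p))))
  }
  rownames(nm)[!is.na(p) & p < config$modulated_p]
}

#' Hallmark gene pools
#'
#' Intersects the modulated genes with each hallmark gene set. Empty pools
#' skip the hallmark with a warning; pools outside the expected size range
#' (100--200 at the published scale) are kept with a warning.
#'
#' @param modulated character vector from [find_modulated_genes()].
#' @param hallmarks named list of hallmark gene sets (see [read_gmt()]).
#' @param config parameters from [mss_config()].
#' @return named list (hallmark -> pool gene vector), skipped hallmarks
#'   absent.
#' @export
collect_hallmark_pools <- function(modulated, hallmarks,
                                   config = mss_config()) {
  pools <- lapply(hallmarks, function(set) sort(intersect(modulated, set)))
  empty <- lengths(pools) == 0L
  if (any(empty)) {
    warn_fmt("empty pool; hallmark(s) skipped: %s",
             paste(names(pools)[empty], collapse = ", "))
  }
  pools <- pools[!empty]
  off <- lengths(pools) < config$pool_range[1L] |
    lengths(pools) > config$pool_range[2L]
  if (any(off)) {
    warn_fmt("pool size outside [%d, %d] for hallmark(s): %s",
             config$pool_range[1L], config$pool_range[2L],
             paste(sprintf("%s (%d)", names(pools)[off], lengths(pools)[off]),
                   collapse = ", "))
  }
  pools
}

#' Screen random gene sets against random sample subsets
#'
#' Draws `n_random_gene_sets` sets of `gene_set_size` genes uniformly
#' without replacement from the pool and `n_random_sample_sets` random
#' sample subsets (`sample_set_fraction` of the samples, without
#' replacement). A gene set passes a subset when the fuzzy bipartition of
#' its per-sample mean heating score separates survival at log-rank
#' P < `modulated_p`; it is retained when it passes on strictly more than
#' `pass_fraction` of the subsets. For retained sets the full per-subset
#' P value matrix is kept so that [calibrate_retention()] can re-apply
#' tighter cutoffs without re-screening.
#'
#' @param nm normalized netMatrix.
#' @param clinical clinical table covering the netMatrix samples.
#' @param pool character vector of candidate genes (the hallmark pool).
#' @param config parameters from [mss_config()].
#' @param seed RNG seed for set and subset draws.
#' @return object of class `mss_screen` (or `NULL` with a warning when the
#'   pool is smaller than `gene_set_size`).
#' @export
screen_random_gene_sets <- function(nm, clinical, pool,
                                    config = mss_config(), seed = 1L) {
  if (length(pool) < config$gene_set_size) {
    warn_fmt("pool (%d genes) smaller than gene_set_size (%d); hallmark skipped",
             length(pool), config$gene_set_size)
    return(NULL)
  }
  cl <- align_clinical(nm, clinical)
  n_samp <- ncol(nm)
  k_sub <- max(2L, round(config$sample_set_fraction * n_samp))
  with_seed(seed, {
    sets <- replicate(config$n_random_gene_sets,
                      sample(pool, config$gene_set_size), simplify = FALSE)
    subsets <- replicate(config$n_random_sample_sets,
                         sort(sample.int(n_samp, k_sub)), simplify = FALSE)
  })
  pool_scores <- nm[pool, , drop = FALSE]
  idx_mat <- matrix(match(unlist(sets), pool), nrow = config$gene_set_size)
  set_scores <- t(apply_sets_mean(pool_scores, idx_mat))

  ## single pass: the subset loop fails fast for hopeless sets, so retained
  ## sets always carry complete p-value rows for later cutoff tightening
  res <- .screen_sets_cpp(set_scores, subsets, cl$dfs_time, cl$dfs_event,
                          config$fuzzifier, config$modulated_p,
                          config$pass_fraction, TRUE, TRUE)
  retained_idx <- which(res$retained)
  pvals <- if (length(retained_idx)) {
    res$pvals[retained_idx, , drop = FALSE]
  }
  structure(list(sets = sets, retained_idx = retained_idx, pvals = pvals,
                 n_subsets = length(subsets), alpha = config$modulated_p,
                 need = res$need, config = config),
            class = "mss_screen")
}

## Column means of pool_scores rows indexed by each column of idx_mat:
## returns samples x sets.
apply_sets_mean <- function(pool_scores, idx_mat) {
  n_pool <- nrow(pool_scores)
  n_sets <- ncol(idx_mat)
  ind <- Matrix::sparseMatrix(i = as.vector(idx_mat),
                              j = rep(seq_len(n_sets), each = nrow(idx_mat)),
                              x = 1 / nrow(idx_mat),
                              dims = c(n_pool, n_sets))
  as.matrix(Matrix::crossprod(pool_scores, ind))
}

#' Calibrate the number of retained gene sets
#'
#' Applies the published retention band, scaled to the configured number of
#' random gene sets: below the scaled minimum the hallmark is discarded;
#' above the scaled maximum the per-subset P cutoff is halved (re-applied
#' from the stored P values) until the retained count is inside the band or
#' the cutoff falls below 1e-10.
#'
#' @param screen `mss_screen` object from [screen_random_gene_sets()].
#' @param config parameters from [mss_config()].
#' @return list with `sets` (retained gene sets), `alpha` (effective
#'   cutoff), `n_retained`, and `discarded` (logical with a `reason`
#'   attribute when `TRUE`).
#' @export
calibrate_retention <- function(screen, config = mss_config()) {
  scale <- config$n_random_gene_sets / 5e6
  min_eff <- max(1L, as.integer(round(config$retained_min * scale)))
  max_eff <- max(1L, as.integer(round(config$retained_max * scale)))
  count_at <- function(a) {
    which(rowSums(screen$pvals < a) >= screen$need)
  }
  alpha <- screen$alpha
  keep <- seq_along(screen$retained_idx)
  alpha_hi <- alpha  # last cutoff with too many sets
  while (length(keep) > max_eff && alpha / 2 >= 1e-10) {
    alpha_hi <- alpha
    alpha <- alpha / 2
    keep <- count_at(alpha)
  }
  ## Halving can overshoot the whole retention band when per-subset P values
  ## are strongly correlated across sets; bisect between the last two
  ## cutoffs for one inside the band (each set drops out at its own critical
  ## cutoff, so intermediate counts exist unless sets tie exactly).
  if (length(keep) < min_eff && alpha_hi > alpha) {
    lo <- alpha; hi <- alpha_hi
    for (it in seq_len(60L)) {
      mid <- sqrt(lo * hi)
      k_mid <- count_at(mid)
      if (length(k_mid) > max_eff) {
        hi <- mid
      } else if (length(k_mid) < min_eff) {
        lo <- mid
      } else {
        alpha <- mid
        keep <- k_mid
        break
      }
    }
    if (length(keep) < min_eff) {  # band straddled by exact ties
      alpha <- hi
      keep <- count_at(hi)
    }
  }
  n_ret <- length(keep)
  if (n_ret < min_eff) {
    return(list(sets = list(), alpha = alpha, n_retained = n_ret,
                discarded = structure(TRUE, reason = sprintf(
                  "only %d retained set(s), below the scaled minimum %d",
                  n_ret, min_eff))))
  }
  list(sets = screen$sets[screen$retained_idx[keep]], alpha = alpha,
       n_retained = n_ret, discarded = FALSE)
}

#' Build a NOG signature from retained gene sets
#'
#' Ranks pool genes by their occurrence count across the retained sets
#' (ties broken lexicographically by gene symbol), takes the top
#' `signature_size` genes, and computes the two state centroids: the mean
#' heating profile of the signature genes over the recurred and the
#' non-recurred samples.
#'
#' @param retained_sets list of gene vectors (from [calibrate_retention()]).
#' @param nm normalized netMatrix.
#' @param labels logical or 0/1 vector over netMatrix samples, `TRUE`/1 =
#'   recurred.
#' @param hallmark hallmark name carried in the signature.
#' @param config parameters from [mss_config()].
#' @return object of class `nog_signature` with fields `hallmark`, `genes`,
#'   `gene_frequencies`, `state_recurred`, `state_nonrecurred`,
#'   `n_retained`.
#' @export
build_signature <- function(retained_sets, nm, labels, hallmark = "hallmark",
                            config = mss_config()) {
  if (!length(retained_sets)) return(NULL)
  labels <- as.logical(labels)
  freq <- table(unlist(retained_sets))
  ord <- order(-as.integer(freq), names(freq))
  top <- head(names(freq)[ord], config$signature_size)
  freqs <- as.integer(freq[top])
  names(freqs) <- top
  x <- nm[top, , drop = FALSE]
  structure(list(hallmark = hallmark, genes = top, gene_frequencies = freqs,
                 state_recurred = rowMeans(x[, labels, drop = FALSE]),
                 state_nonrecurred = rowMeans(x[, !labels, drop = FALSE]),
                 n_retained = length(retained_sets)),
            class = "nog_signature")
}

#' @export
print.nog_signature <- function(x, ...) {
  cat(sprintf("NOG signature '%s': %d genes from %d retained sets\n",
              x$hallmark, length(x$genes), x$n_retained))
  cat("  top genes:", paste(head(x$genes, 8L), collapse = ", "), "...\n")
  invisible(x)
}

#' Discover NOG signatures for every hallmark
#'
#' End-to-end MSS: modulated-gene screen, hallmark pools, random-gene-set
#' screening, retention calibration, and frequency-ranked signatures with
#' their state centroids. Deterministic for a given seed.
#'
#' @param nm normalized netMatrix (genes x samples).
#' @param clinical clinical table covering the netMatrix samples.
#' @param hallmarks named list of hallmark gene sets.
#' @param config parameters from [mss_config()].
#' @param seed RNG seed.
#' @return list with `signatures` (named list of `nog_signature`),
#'   `modulated`, `pools`, and a per-hallmark `details` data frame.
#' @export
discover_signatures <- function(nm, clinical, hallmarks,
                                config = mss_config(), seed = 1L) {
  cl <- align_clinical(nm, clinical)
  modulated <- find_modulated_genes(nm, cl, config)
  pools <- collect_hallmark_pools(modulated, hallmarks, config)
  signatures <- list()
  details <- list()
  for (i in seq_along(pools)) {
    h <- names(pools)[i]
    screen <- screen_random_gene_sets(nm, cl, pools[[i]], config,
                                      seed = seed + i)
    if (is.null(screen)) {
      details[[h]] <- data.frame(hallmark = h, pool = length(pools[[i]]),
                                 retained = 0L, alpha = NA_real_,
                                 emitted = FALSE)
      next
    }
    cal <- calibrate_retention(screen, config)
    sig <- NULL
    if (!isTRUE(cal$discarded)) {
      sig <- build_signature(cal$sets, nm, cl$dfs_event == 1L, h, config)
    }
    if (!is.null(sig)) signatures[[h]] <- sig
    details[[h]] <- data.frame(hallmark = h, pool = length(pools[[i]]),
                               retained = cal$n_retained, alpha = cal$alpha,
                               emitted = !is.null(sig))
  }
  list(signatures = signatures, modulated = modulated, pools = pools,
       details = do.call(rbind, details))
}
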