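## Construction of the cancer-type-specific recurrence network: three
## evidence-derived gene sets (cell-line modulation, tumor survival
## association, copy-number-driven regulators) intersected and induced on a
## curated signaling network.

#' Resampling parameters for the Set 1 / Set 2 screens
#'
#' @param n_resamples number of re-samplings (default 10).
#' @param sample_fraction fraction of samples drawn per re-sampling
#'   (default 0.60).
#' @param p_threshold per-test significance cutoff (default 0.05).
#' @param retention_min_fraction fraction of re-samplings a gene must pass
#'   to be retained; the default 1.0 (all re-samplings) is the strictest
#'   reading and fully reproducible.
#' @return parameter list.
#' @export
resampling_config <- function(n_resamples = 10L, sample_fraction = 0.60,
                              p_threshold = 0.05,
                              retention_min_fraction = 1.0) {
  check_fraction(sample_fraction, "sample_fraction", lo_open = TRUE)
  check_fraction(p_threshold, "p_threshold", lo_open = TRUE, hi_open = TRUE)
  check_fraction(retention_min_fraction, "retention_min_fraction")
  list(n_resamples = as.integer(n_resamples),
       sample_fraction = sample_fraction, p_threshold = p_threshold,
       retention_min_fraction = retention_min_fraction)
}

#' Split cell lines into epithelial and mesenchymal
#'
#' Epithelial iff CDH1/VIM expression ratio exceeds `ratio_threshold`
#' (default 1.2); the boundary itself is mesenchymal.
#'
#' @param expr genes-by-samples expression matrix containing `CDH1` and
#'   `VIM` rows; `VIM` must be positive in every sample.
#' @param ratio_threshold epithelial/mesenchymal boundary (default 1.2).
#' @return factor (`epithelial`/`mesenchymal`) named by sample.
#' @export
classify_cell_lines <- function(expr, ratio_threshold = 1.2) {
  for (g in c("CDH1", "VIM")) {
    if (!g %in% rownames(expr)) stop_fmt("cell-line expression: missing gene %s", g)
  }
  vim <- expr["VIM", ]
  if (any(vim <= 0)) {
    stop_fmt("VIM expression must be positive (sample '%s')",
             colnames(expr)[which(vim <= 0)[1L]])
  }
  ratio <- expr["CDH1", ] / vim
  factor(ifelse(ratio > ratio_threshold, "epithelial", "mesenchymal"),
         levels = c("epithelial", "mesenchymal"))
}

## Stratified resample of sample indices: `fraction` per class, >= 2 each.
stratified_resample <- function(classes, fraction) {
  unlist(lapply(levels(classes), function(lv) {
    idx <- which(classes == lv)
    k <- max(2L, round(fraction * length(idx)))
    sample(idx, min(k, length(idx)))
  }), use.names = FALSE)
}

#' Set 1: genes modulated between epithelial and mesenchymal cell lines
#'
#' Per re-sampling (stratified 60% of each class), keeps genes whose
#' two-sample Welch t-test P value falls below `p_threshold`; a gene is
#' retained when it passes in at least `retention_min_fraction` of the
#' re-samplings.
#'
#' @param cellline_expr genes-by-samples cell-line expression matrix.
#' @param classes factor from [classify_cell_lines()] (computed from
#'   `cellline_expr` when `NULL`).
#' @param config parameters from [resampling_config()].
#' @param seed RNG seed for the re-samplings.
#' @return character vector of retained genes.
#' @export
identify_set1 <- function(cellline_expr, classes = NULL,
                          config = resampling_config(), seed = 1L) {
  classes <- classes %||% classify_cell_lines(cellline_expr)
  stopifnot(length(classes) == ncol(cellline_expr))
  if (any(table(classes) < 2L)) stop_fmt("both cell-line classes need >= 2 samples")
  with_seed(seed, {
    pass <- matrix(FALSE, nrow(cellline_expr), config$n_resamples)
    for (b in seq_len(config$n_resamples)) {
      idx <- stratified_resample(classes, config$sample_fraction)
      p <- row_welch_p(cellline_expr[, idx, drop = FALSE],
                       classes[idx] == "epithelial")
      pass[, b] <- !is.na(p) & p < config$p_threshold
    }
    need <- config$retention_min_fraction * config$n_resamples
    rownames(cellline_expr)[rowSums(pass) >= need]
  })
}

#' Set 2: survival-associated genes in tumor expression
#'
#' A full-cohort Welch t-test between recurred and non-recurred samples
#' screens for modulated genes; those are then subjected to a per-gene
#' median-split Kaplan--Meier log-rank test in each re-sampling, and a gene
#' is retained when its log-rank P value falls below `p_threshold` in at
#' least `retention_min_fraction` of the re-samplings (stratified by
#' outcome so both groups stay populated). Zero-variance genes cannot be
#' split and are excluded.
#'
#' @param tumor_expr genes-by-samples expression matrix.
#' @param clinical clinical table covering the expression samples.
#' @param config parameters from [resampling_config()].
#' @param seed RNG seed.
#' @return character vector of retained genes.
#' @export
identify_set2 <- function(tumor_expr, clinical, config = resampling_config(),
                          seed = 1L) {
  cl <- clinical[match(colnames(tumor_expr), clinical$sample_id), ]
  if (anyNA(cl$sample_id)) stop_fmt("clinical table does not cover all expression samples")
  if (!any(cl$dfs_event == 1L)) stop_fmt("no events")
  if (!any(cl$dfs_event == 0L)) stop_fmt("all samples recurred; no comparison group")
  classes <- factor(ifelse(cl$dfs_event == 1L, "recurred", "non_recurred"))

  p_t <- row_welch_p(tumor_expr, cl$dfs_event == 1L)
  t_pass <- !is.na(p_t) & p_t < config$p_threshold

  with_seed(seed, {
    pass <- matrix(FALSE, nrow(tumor_expr), config$n_resamples)
    for (b in seq_len(config$n_resamples)) {
      idx <- stratified_resample(classes, config$sample_fraction)
      sub <- tumor_expr[, idx, drop = FALSE]
      med <- apply(sub, 1L, median)
      tt <- cl$dfs_time[idx]
      ev <- cl$dfs_event[idx]
      pk <- vapply(seq_len(nrow(sub)), function(g) {
        grp <- as.integer(sub[g, ] > med[g])
        if (all(grp == 0L) || all(grp == 1L)) return(NA_real_)
        .logrank_p_cpp(tt, ev, grp)
      }, numeric(1L))
      pass[, b] <- !is.na(pk) & pk < config$p_threshold
    }
    need <- config$retention_min_fraction * config$n_resamples
    rownames(tumor_expr)[t_pass & rowSums(pass) >= need]
  })
}

#' Set 3: cancer regulator genes from copy-number evidence
#'
#' A gene is a cancer regulator when its GISTIC score exceeds 0.3 (strict)
#' and, in at least one sample, its expression ranks in the top 50% of that
#' sample's genome.
#'
#' @param gistic_scores named numeric vector of per-gene GISTIC scores.
#' @param tumor_expr genes-by-samples expression matrix sharing the gene
#'   universe.
#' @param gistic_threshold score cutoff (default 0.3, exclusive).
#' @param rank_fraction within-sample expression percentile cutoff
#'   (default 0.5 = top 50%, boundary inclusive).
#' @return character vector of regulator genes.
#' @export
identify_set3 <- function(gistic_scores, tumor_expr, gistic_threshold = 0.3,
                          rank_fraction = 0.5) {
  genes <- intersect(names(gistic_scores), rownames(tumor_expr))
  expr <- tumor_expr[genes, , drop = FALSE]
  ## within-sample percentile from the bottom; top 50% = percentile >= 0.5
  pct <- apply(tumor_expr, 2L, function(x) rank(x, ties.method = "average")) /
    nrow(tumor_expr)
  rownames(pct) <- rownames(tumor_expr)
  high_rank <- rowSums(pct[genes, , drop = FALSE] >= rank_fraction) > 0
  genes[gistic_scores[genes] > gistic_threshold & high_rank]
}

#' Intersect the three gene sets on the signaling network
#'
#' The recurrence network's vertex set is `set1` \eqn{\cap} `set2`
#' \eqn{\cap} `set3` \eqn{\cap} signaling-network genes, with the induced
#' edges. Vertices isolated by the restriction are retained (their count is
#' messaged). No edge is invented: every retained edge exists in the input.
#'
#' @param signaling edge `data.frame` (see [read_edge_list()]).
#' @param set1,set2,set3 character gene vectors.
#' @return object of class `recurrence_network`: list with `genes`, `edges`,
#'   `provenance` (per-gene set-membership flags) and `graph` (igraph).
#' @export
build_recurrence_network <- function(signaling, set1, set2, set3) {
  signaling <- canonicalize_edges(signaling)
  net_genes <- unique(c(signaling$gene1, signaling$gene2))
  common <- Reduce(intersect, list(set1, set2, set3, net_genes))
  if (!length(common)) stop_fmt("empty recurrence network")
  keep <- signaling$gene1 %in% common & signaling$gene2 %in% common
  edges <- signaling[keep, , drop = FALSE]
  graph <- igraph::graph_from_data_frame(
    edges[, c("gene1", "gene2")], directed = FALSE,
    vertices = data.frame(name = sort(common)))
  iso <- sum(igraph::degree(graph) == 0)
  if (iso) message(sprintf("recurrence network: %d isolated gene(s) retained", iso))
  structure(list(
    genes = sort(common),
    edges = edges,
    provenance = data.frame(gene = sort(common),
                            set1 = sort(common) %in% set1,
                            set2 = sort(common) %in% set2,
                            set3 = sort(common) %in% set3),
    graph = graph), class = "recurrence_network")
}

#' @export
print.recurrence_network <- function(x, ...) {
  cat(sprintf("Recurrence network: %d genes, %d interactions\n",
              length(x$genes), nrow(x$edges)))
  invisible(x)
}
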