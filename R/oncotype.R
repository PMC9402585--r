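## The 21-gene recurrence-score (RS) comparator. Sixteen informative genes
## in weighted groups plus five reference genes for normalization; the
## unscaled score is a linear combination of (floored) group scores,
## rescaled onto 0-100 and cut into low/intermediate/high risk. All gene
## lists, weights, floors and thresholds live in a YAML config so a variant
## formula can be dropped in.

#' Load the recurrence-score coefficient configuration
#'
#' @param path YAML file; defaults to the bundled published coefficients.
#' @return configuration list.
#' @export
oncotype_config <- function(path = NULL) {
  path <- path %||% system.file("extdata", "oncotype_coefficients.yaml",
                                package = "netmet")
  cfg <- yaml::read_yaml(path)
  cfg$informative_genes <- unique(unlist(lapply(cfg$groups, function(g) {
    names(g$weights)
  })))
  cfg
}

#' Compute the 21-gene recurrence score
#'
#' Expression values (linear scale, positive) are log2-transformed and
#' reference-normalized: the mean log2 expression of the five reference
#' genes is subtracted and a fixed offset places values on the 0--15
#' convention; multiplying every gene's expression by a common factor
#' therefore leaves the score unchanged. Group scores are weighted sums of
#' normalized expression, floored where the published algorithm floors them
#' (GRB7 group at 8, proliferation group at 6.5); the unscaled score
#' combines the groups linearly and `RS = 20 (RSu - 6.7)` clamped to
#' \[0, 100\].
#'
#' @param expr genes-by-samples matrix of positive, linear-scale expression
#'   containing all informative and reference genes.
#' @param config from [oncotype_config()].
#' @return `data.frame` with `sample_id`, `rs_unscaled`, `rs`, `category`.
#' @export
compute_rs <- function(expr, config = oncotype_config()) {
  need <- c(config$informative_genes, config$reference_genes)
  miss <- setdiff(need, rownames(expr))
  if (length(miss)) {
    stop_fmt("expression matrix missing gene(s): %s", paste(miss, collapse = ", "))
  }
  x <- expr[need, , drop = FALSE]
  if (any(x <= 0)) stop_fmt("non-positive expression value for a required gene")
  lg <- log2(x)
  ref <- colMeans(lg[config$reference_genes, , drop = FALSE])
  norm <- sweep(lg, 2L, ref) + config$offset

  group_score <- function(g) {
    w <- unlist(g$weights)
    sc <- colSums(norm[names(w), , drop = FALSE] * w)
    if (!is.null(g$floor)) sc <- pmax(sc, g$floor)
    sc
  }
  groups <- vapply(config$groups, group_score, numeric(ncol(expr)))
  groups <- matrix(groups, nrow = ncol(expr),
                   dimnames = list(colnames(expr), names(config$groups)))
  coef <- unlist(config$coefficients)
  rsu <- as.numeric(groups[, names(coef), drop = FALSE] %*% coef)
  rsc <- config$rescale
  rs <- pmin(pmax(rsc$scale * (rsu - rsc$shift), rsc$min), rsc$max)
  data.frame(sample_id = colnames(expr), rs_unscaled = rsu, rs = rs,
             category = assign_risk(rs, config))
}

#' Recurrence-score risk category
#'
#' `RS < 18` is low risk, `18 <= RS < 31` intermediate, `RS >= 31` high
#' (boundaries land in the higher category).
#'
#' @param rs numeric recurrence score(s) on the 0--100 scale.
#' @param config from [oncotype_config()].
#' @return character vector of `"low"`/`"intermediate"`/`"high"`.
#' @export
assign_risk <- function(rs, config = oncotype_config()) {
  cat <- config$categories
  ifelse(rs >= cat$high_from, "high",
         ifelse(rs >= cat$low_below, "intermediate", "low"))
}
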