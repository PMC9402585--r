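## Purity adjustment of tumor VAFs and the germline / founding-clone variant
## rules. Only variants in diploid (2n) regions are interpretable: a clonal
## heterozygous variant in a sample of purity p has expected raw VAF p * 0.5,
## so dividing the observed tumor VAF by p (clamped at 1) restores the
## cancer-cell-fraction scale on which the VAF windows are defined.

MUTATION_CLASSES <- c("germline_homozygous", "germline_heterozygous",
                      "founding_homozygous", "founding_heterozygous",
                      "excluded")

#' Variant classification cutoffs
#'
#' @param hom_min minimum VAF for a homozygous call (default 0.90).
#' @param het_min,het_max heterozygous VAF window (default 0.45--0.55).
#' @param normal_absent_max a variant counts as absent from the matched
#'   normal when its normal VAF is below this bound (default 0.05, a
#'   conventional sequencing-noise level).
#' @return list of cutoffs used by [classify_variants()].
#' @export
variant_filter_config <- function(hom_min = 0.90, het_min = 0.45,
                                  het_max = 0.55, normal_absent_max = 0.05) {
  check_fraction(hom_min, "hom_min")
  check_fraction(het_min, "het_min")
  check_fraction(het_max, "het_max")
  check_fraction(normal_absent_max, "normal_absent_max")
  if (het_min > het_max) stop_fmt("het_min must be <= het_max")
  list(hom_min = hom_min, het_min = het_min, het_max = het_max,
       normal_absent_max = normal_absent_max)
}

#' Adjust an observed tumor VAF for tumor purity
#'
#' Divides the observed VAF by the tumor purity and clamps at 1, the diploid
#' mixture model in which a fraction `purity` of sequenced cells are cancer
#' cells. Normal-sample VAFs are never adjusted.
#'
#' @param vaf observed VAF(s) in \[0, 1\].
#' @param purity tumor purity in (0, 1\]; recycled against `vaf`.
#' @return adjusted VAF(s) in \[0, 1\].
#' @export
adjust_tumor_vaf <- function(vaf, purity) {
  check_fraction(vaf, "vaf")
  if (any(purity <= 0 | purity > 1)) stop_fmt("purity must lie in (0, 1]")
  pmin(vaf / purity, 1)
}

#' Classify variants as germline, founding-clone somatic, or excluded
#'
#' Applies the VAF window rules on purity-adjusted tumor VAFs:
#' variants outside diploid (2n) regions are excluded; homozygous germline
#' calls need VAF >= `hom_min` in both normal and tumor; heterozygous
#' germline calls need the normal VAF inside \[`het_min`, `het_max`\];
#' founding-clone somatic calls need the variant absent from the normal
#' (below `normal_absent_max`) and the tumor VAF in the homozygous or
#' heterozygous window. Everything else (subclonal VAFs in particular) is
#' excluded. All boundaries are inclusive as written.
#'
#' @param normal_vaf,tumor_vaf numeric vectors in \[0, 1\]; `tumor_vaf` is the
#'   purity-adjusted tumor VAF.
#' @param copy_number_state integer vector; only state 2 is interpretable.
#' @param config cutoffs from [variant_filter_config()].
#' @return factor with levels
#'   `germline_homozygous`, `germline_heterozygous`, `founding_homozygous`,
#'   `founding_heterozygous`, `excluded`.
#' @export
classify_variants <- function(normal_vaf, tumor_vaf, copy_number_state = 2L,
                              config = variant_filter_config()) {
  check_fraction(normal_vaf, "normal_vaf")
  check_fraction(tumor_vaf, "tumor_vaf")
  n <- max(length(normal_vaf), length(tumor_vaf), length(copy_number_state))
  normal_vaf <- rep_len(normal_vaf, n)
  tumor_vaf <- rep_len(tumor_vaf, n)
  copy_number_state <- rep_len(copy_number_state, n)

  cls <- rep("excluded", n)
  diploid <- copy_number_state == 2L
  absent <- normal_vaf < config$normal_absent_max
  het <- function(v) v >= config$het_min & v <= config$het_max
  hom <- function(v) v >= config$hom_min

  cls[diploid & hom(normal_vaf) & hom(tumor_vaf)] <- "germline_homozygous"
  cls[diploid & cls == "excluded" & het(normal_vaf)] <- "germline_heterozygous"
  cls[diploid & cls == "excluded" & absent & hom(tumor_vaf)] <- "founding_homozygous"
  cls[diploid & cls == "excluded" & absent & het(tumor_vaf)] <- "founding_heterozygous"
  factor(cls, levels = MUTATION_CLASSES)
}

#' Founding-clone gene set of a single sample
#'
#' Adjusts the sample's tumor VAFs for purity, classifies every variant, and
#' returns the genes that carry at least one germline or founding-clone
#' variant *and* are functionally mutated. Variants are collapsed to gene
#' level: one qualifying variant suffices, duplicates count once.
#'
#' @param mutations mutation table rows of a single sample (see
#'   [read_mutation_table()] for the schema).
#' @param functional_genes character vector of functionally mutated genes for
#'   this sample.
#' @param config cutoffs from [variant_filter_config()].
#' @return list with `sample_id` and `genes` (sorted character vector; empty
#'   with a warning when no variant qualifies).
#' @export
build_founding_clone <- function(mutations, functional_genes,
                                 config = variant_filter_config()) {
  sid <- unique(mutations$sample_id)
  if (length(sid) > 1L) {
    stop_fmt("build_founding_clone expects a single sample, got %d", length(sid))
  }
  genes <- character()
  if (nrow(mutations)) {
    adj <- adjust_tumor_vaf(mutations$tumor_vaf, mutations$purity %||% 1)
    cls <- classify_variants(mutations$normal_vaf, adj,
                             mutations$copy_number_state %||% 2L, config)
    keep <- cls != "excluded"
    genes <- sort(intersect(unique(mutations$gene[keep]), functional_genes))
  }
  if (!length(genes)) {
    warn_fmt("sample '%s': empty founding clone (all-zero profile downstream)",
             if (length(sid)) sid else "<no sample>")
  }
  list(sample_id = if (length(sid)) sid else NA_character_, genes = genes)
}

#' Founding-clone gene sets for a cohort
#'
#' Applies [build_founding_clone()] to every sample of a mutation table.
#'
#' @param mutations multi-sample mutation table.
#' @param functional_genes named list (sample -> character vector of
#'   functionally mutated genes, as from [merge_functional_genes()]) or a
#'   single character vector applied to all samples.
#' @param config cutoffs from [variant_filter_config()].
#' @return named list (sample -> sorted gene vector), one founding clone per
#'   sample appearing in `mutations`.
#' @export
build_founding_clones <- function(mutations, functional_genes,
                                  config = variant_filter_config()) {
  samples <- unique(mutations$sample_id)
  out <- lapply(samples, function(s) {
    fg <- if (is.list(functional_genes)) {
      functional_genes[[s]] %||% character()
    } else functional_genes
    build_founding_clone(mutations[mutations$sample_id == s, , drop = FALSE],
                         fg, config)$genes
  })
  setNames(out, samples)
}
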