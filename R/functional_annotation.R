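## Merge of the three functional annotators. A variant is functional when any
## tool calls it so; missing annotator fields fail their branch rather than
## erroring, because the tools cover different variant classes.

#' Functional-annotation cutoffs
#'
#' @param cravat_min minimum CRAVAT score for a functional call (default 0.5).
#' @param cadd_min minimum CADD C-score (default 10); the CADD branch
#'   additionally requires a damaging PolyPhen-2 or deleterious SIFT call.
#' @param cadd_missense_only restrict the CADD branch to rows whose
#'   `variant_class` column equals `"missense"` (the stricter reading);
#'   default `FALSE` applies it to any variant carrying PolyPhen/SIFT calls.
#' @return list of cutoffs used by [is_functional()].
#' @export
annotation_config <- function(cravat_min = 0.5, cadd_min = 10,
                              cadd_missense_only = FALSE) {
  list(cravat_min = cravat_min, cadd_min = cadd_min,
       cadd_missense_only = isTRUE(cadd_missense_only))
}

#' Is a variant functionally mutated?
#'
#' Merge rule over the three annotators: functional iff
#' CRAVAT score >= 0.5, *or* MutationTaster calls `disease`, *or*
#' CADD C-score >= 10 together with a damaging PolyPhen-2 or deleterious
#' SIFT call. Absent fields fail their branch; a record with no annotator
#' field at all is an error.
#'
#' @param records annotation `data.frame` (see [read_annotation_table()]).
#' @param config cutoffs from [annotation_config()].
#' @return logical vector, one element per record row.
#' @export
is_functional <- function(records, config = annotation_config()) {
  n <- nrow(records)
  get <- function(col) {
    if (col %in% names(records)) records[[col]] else rep(NA, n)
  }
  cravat <- get("cravat_score")
  mt <- get("mutationtaster_call")
  cadd <- get("cadd_cscore")
  pph <- get("polyphen_call")
  sift <- get("sift_call")

  none <- is.na(cravat) & is.na(mt) & is.na(cadd) & is.na(pph) & is.na(sift)
  if (any(none)) {
    stop_fmt("unannotated variant at row(s) %s",
             paste(head(which(none), 5L), collapse = ", "))
  }
  branch <- function(x) !is.na(x) & x
  cadd_ok <- branch(cadd >= config$cadd_min) &
    (branch(pph == "damaging") | branch(sift == "deleterious"))
  if (config$cadd_missense_only) {
    cadd_ok <- cadd_ok & branch(get("variant_class") == "missense")
  }
  branch(cravat >= config$cravat_min) | branch(mt == "disease") | cadd_ok
}

#' Per-sample functionally mutated gene sets
#'
#' Union semantics: a gene is functionally mutated in a sample if any of its
#' variants is functional by any annotator.
#'
#' @param records annotation `data.frame` covering one or more samples.
#' @param config cutoffs from [annotation_config()].
#' @return named list (sample -> sorted unique gene vector; possibly empty).
#' @export
merge_functional_genes <- function(records, config = annotation_config()) {
  fun <- is_functional(records, config)
  samples <- unique(records$sample_id)
  out <- lapply(samples, function(s) {
    sort(unique(records$gene[fun & records$sample_id == s]))
  })
  setNames(out, samples)
}
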