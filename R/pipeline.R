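## End-to-end orchestration: variant filtering -> functional annotation ->
## recurrence network (built or provided) -> propagation -> signature
## discovery -> combinatory set selection -> leave-one-out prediction.
## Every stage persists its output and the run manifest records seeds,
## parameters and per-stage row counts.

#' Run the full pipeline
#'
#' `config` is a list (or path to a YAML file) with input paths and
#' optional parameter overrides:
#' \describe{
#'   \item{inputs}{`mutations`, `annotations`, `clinical`, `hallmarks`, and
#'     either `network` (edge list used directly as the recurrence network)
#'     or `celline_expr` + `tumor_expr` + `gistic` + `signaling` to build
#'     one.}
#'   \item{out_dir}{output directory.}
#'   \item{seed}{RNG seed for all stochastic stages.}
#'   \item{params}{optional overrides: `variant_filter`, `annotation`,
#'     `propagation`, `mss`, `css`, `resampling` (argument lists for the
#'     respective `*_config()` constructors) and `delta`.}
#' }
#' Input files are loaded lazily: a missing file aborts at the stage that
#' needs it, naming both.
#'
#' @param config list or YAML path.
#' @return run manifest (also written to `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  inputs <- config$inputs %||% stop_fmt("config$inputs is required")
  out_dir <- config$out_dir %||% stop_fmt("config$out_dir is required")
  seed <- as.integer(config$seed %||% 1L)
  par <- config$params %||% list()
  cfg_of <- function(ctor, args) do.call(ctor, as.list(args %||% list()))
  vf_cfg <- cfg_of(variant_filter_config, par$variant_filter)
  an_cfg <- cfg_of(annotation_config, par$annotation)
  pr_cfg <- cfg_of(propagation_config, par$propagation)
  mss_cfg <- cfg_of(mss_config, par$mss)
  css_cfg <- cfg_of(css_config, par$css)
  rs_cfg <- cfg_of(resampling_config, par$resampling)
  delta <- par$delta %||% 0

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  note <- function(name, rows, outputs = character()) {
    stages[[name]] <<- list(name = name, rows = rows, outputs = outputs)
    message(sprintf("[%s] done (%s rows)", name, paste(rows, collapse = "/")))
  }
  need_file <- function(key, stage) {
    path <- inputs[[key]]
    if (is.null(path) || !file.exists(path %||% "")) {
      stop_fmt("stage '%s': missing input file '%s' (%s)", stage, key,
               path %||% "<unset>")
    }
    path
  }

  ## 1. variant filtering + 2. functional annotation
  mutations <- read_mutation_table(need_file("mutations", "filter-variants"))
  annotations <- read_annotation_table(need_file("annotations", "annotate-merge"))
  functional <- merge_functional_genes(annotations, an_cfg)
  fun_df <- data.frame(
    sample_id = rep(names(functional), lengths(functional)),
    gene = unlist(functional, use.names = FALSE))
  write_tsv(fun_df, file.path(out_dir, "functional_genes.tsv"))
  note("annotate-merge", nrow(fun_df), "functional_genes.tsv")

  clones <- suppressWarnings(build_founding_clones(mutations, functional, vf_cfg))
  clone_df <- data.frame(sample_id = rep(names(clones), lengths(clones)),
                         gene = unlist(clones, use.names = FALSE))
  write_tsv(clone_df, file.path(out_dir, "founding_clones.tsv"))
  note("filter-variants", nrow(clone_df), "founding_clones.tsv")

  ## 3. recurrence network: provided or built from evidence
  if (!is.null(inputs$network)) {
    edges <- read_edge_list(need_file("network", "build-network"))
    network <- igraph::graph_from_data_frame(edges[, c("gene1", "gene2")],
                                             directed = FALSE)
    note("build-network", nrow(edges), "(provided)")
  } else {
    celline <- read_expression(need_file("celline_expr", "build-network"))
    tumor <- read_expression(need_file("tumor_expr", "build-network"))
    clin_net <- read_clinical(need_file("clinical", "build-network"))
    gistic_df <- read_tsv(need_file("gistic", "build-network"))
    gistic <- setNames(gistic_df$score, gistic_df$gene)
    signaling <- read_edge_list(need_file("signaling", "build-network"))
    set1 <- identify_set1(celline, config = rs_cfg, seed = seed + 11L)
    set2 <- identify_set2(tumor, clin_net, config = rs_cfg, seed = seed + 12L)
    set3 <- identify_set3(gistic, tumor)
    network <- build_recurrence_network(signaling, set1, set2, set3)
    write_edge_list(network$edges, file.path(out_dir, "recurrence_network.tsv"))
    write_tsv(network$provenance,
              file.path(out_dir, "recurrence_network_genes.tsv"))
    note("build-network", nrow(network$edges),
         c("recurrence_network.tsv", "recurrence_network_genes.tsv"))
  }

  ## 4. propagation
  profiles <- suppressWarnings(propagate_cohort(network, clones, pr_cfg))
  nm <- build_netmatrix(profiles)
  write_netmatrix(nm, file.path(out_dir, "netmatrix.tsv"))
  note("propagate", paste(dim(nm), collapse = "x"), "netmatrix.tsv")

  ## 5. signature discovery
  clinical <- read_clinical(need_file("clinical", "discover-signatures"))
  hallmarks <- read_gmt(need_file("hallmarks", "discover-signatures"))
  nm <- nm[, colnames(nm) %in% clinical$sample_id, drop = FALSE]
  disc <- discover_signatures(nm, clinical, hallmarks, mss_cfg,
                              seed = seed + 20L)
  sig_dir <- file.path(out_dir, "signatures")
  dir.create(sig_dir, showWarnings = FALSE)
  for (sig in disc$signatures) {
    write_tsv(data.frame(rank = seq_along(sig$genes), gene = sig$genes,
                         frequency = sig$gene_frequencies,
                         state_recurred = fmt_num(sig$state_recurred),
                         state_nonrecurred = fmt_num(sig$state_nonrecurred)),
              file.path(sig_dir, paste0(sig$hallmark, ".tsv")))
  }
  note("discover-signatures", length(disc$signatures), "signatures/")
  if (!length(disc$signatures)) {
    stop_fmt("stage 'discover-signatures': no signature emitted")
  }

  ## 6. combinatory set selection
  css <- select_n_signatures(unname(disc$signatures), nm, clinical, css_cfg,
                             delta)
  jsonlite::write_json(
    list(N = css$N, LN = css$LN, HN = css$HN,
         signatures = lapply(css$signatures, function(s) {
           list(hallmark = s$hallmark, genes = s$genes)
         }),
         trace = css$trace),
    file.path(out_dir, "css.json"), auto_unbox = TRUE, digits = NA)
  note("build-css", css$N, "css.json")

  ## 7. prediction (leave-one-out)
  pred <- suppressWarnings(loocv(css, nm, clinical, delta))
  write_tsv(pred$calls, file.path(out_dir, "calls.tsv"))
  note("predict", nrow(pred$calls), "calls.tsv")

  manifest <- list(package = "netmet",
                   version = as.character(utils::packageVersion("netmet")),
                   seed = seed, timestamp = format(Sys.time(), tz = "UTC"),
                   stages = unname(stages),
                   evaluation = pred$evaluation)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}
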