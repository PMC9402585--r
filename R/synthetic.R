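## Fully synthetic fixtures with the statistical structure the pipeline
## assumes: a preferential-attachment gene network with two densely wired
## planted modules, sparse per-sample mutation profiles concentrated in the
## module matching each sample's outcome state, VAFs landing in the
## germline/founding/subclonal windows, annotator calls, two-group survival,
## and expression/copy-number evidence feeding the network construction.
## Every generator is deterministic per seed and emits a truth manifest.

#' Simulation parameters
#'
#' Defaults describe the desk-scale study cohort: 200 samples, a 2000-gene
#' network with two 30-gene planted modules, a sparse mutation load of
#' 5--10 functionally mutated genes per sample (about two thirds from the
#' module matching the sample's observed outcome, so samples share network
#' regions rather than genes), and two-state survival with baseline hazard
#' 0.001/month, hazard ratio 5 and uniform(24, 120)-month censoring,
#' giving roughly 30% observed events in the recurrence-prone state and 7%
#' in the other (about 19% of the cohort recurs).
#'
#' @param n_samples cohort size.
#' @param recurred_fraction fraction of samples in the recurrence-prone
#'   state.
#' @param n_genes network size.
#' @param pa_edges_per_gene preferential-attachment edges per added gene.
#' @param module_size genes per planted module.
#' @param module_edge_enrichment within-module wiring probability as a
#'   multiple of the background edge density.
#' @param mutations_range min/max mutated genes per sample.
#' @param off_module_rate fraction of a sample's mutated genes drawn outside
#'   its state module.
#' @param class_mix named proportions of variant classes
#'   (founding/germline het/hom and subclonal).
#' @param non_diploid_rate fraction of variants placed in non-2n regions.
#' @param purity_range tumor purity range (uniform).
#' @param functional_rate probability that a variant receives a functional
#'   annotation (the branch is drawn uniformly among the three tools).
#' @param baseline_hazard exponential event hazard per month of the
#'   non-recurrence state.
#' @param hazard_ratio hazard multiplier of the recurrence-prone state.
#' @param censoring_range uniform censoring window (months).
#' @param expression_effect between-state mean shift (in within-group sd
#'   units) planted on module genes in expression data.
#' @param n_celllines,n_celllines_epithelial cell-line panel composition.
#' @param hallmark_background non-module filler genes per hallmark set.
#' @param regulator_fraction fraction of background genes with elevated
#'   copy-number scores in addition to the module genes.
#' @return parameter list.
#' @export
sim_config <- function(n_samples = 200L, recurred_fraction = 0.5,
                       n_genes = 2000L, pa_edges_per_gene = 2L,
                       module_size = 30L, module_edge_enrichment = 200,
                       mutations_range = c(5L, 10L), off_module_rate = 0.35,
                       class_mix = c(founding_heterozygous = 0.60,
                                     founding_homozygous = 0.10,
                                     germline_heterozygous = 0.10,
                                     germline_homozygous = 0.05,
                                     subclonal = 0.15),
                       non_diploid_rate = 0.05, purity_range = c(0.5, 0.9),
                       functional_rate = 0.9, baseline_hazard = 0.001,
                       hazard_ratio = 5, censoring_range = c(24, 120),
                       expression_effect = 3, n_celllines = 22L,
                       n_celllines_epithelial = 13L,
                       hallmark_background = 30L,
                       regulator_fraction = 0.10) {
  check_fraction(recurred_fraction, "recurred_fraction", lo_open = TRUE,
                 hi_open = TRUE)
  check_fraction(off_module_rate, "off_module_rate")
  if (hazard_ratio <= 0) stop_fmt("hazard_ratio must be positive")
  if (n_genes < 3L * 2L * module_size) {
    stop_fmt("n_genes must be at least 3x the total planted module size")
  }
  list(n_samples = as.integer(n_samples),
       recurred_fraction = recurred_fraction, n_genes = as.integer(n_genes),
       pa_edges_per_gene = as.integer(pa_edges_per_gene),
       module_size = as.integer(module_size),
       module_edge_enrichment = module_edge_enrichment,
       mutations_range = as.integer(mutations_range),
       off_module_rate = off_module_rate, class_mix = class_mix,
       non_diploid_rate = non_diploid_rate, purity_range = purity_range,
       functional_rate = functional_rate, baseline_hazard = baseline_hazard,
       hazard_ratio = hazard_ratio, censoring_range = censoring_range,
       expression_effect = expression_effect,
       n_celllines = as.integer(n_celllines),
       n_celllines_epithelial = as.integer(n_celllines_epithelial),
       hallmark_background = as.integer(hallmark_background),
       regulator_fraction = regulator_fraction)
}

hallmark_names <- function() {
  c("apoptosis", "cell_cycle", "cell_adhesion",
    "cytoskeleton", "immune_response", "cell_proliferation")
}

#' Simulate the signaling network with planted modules
#'
#' Preferential-attachment backbone plus two planted modules whose members
#' are additionally wired with probability
#' `module_edge_enrichment x background density`.
#'
#' @param config from [sim_config()].
#' @param seed RNG seed.
#' `module_edge_enrichment = 1` therefore leaves the modules statistically
#' indistinguishable from the background.
#'
#' @return list with `edges` (canonical edge `data.frame`), `modules`
#'   (list of two gene vectors), `genes`.
#' @export
simulate_network <- function(config = sim_config(), seed = 1L) {
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(config$n_genes))
    g <- igraph::sample_pa(config$n_genes, power = 1,
                           m = config$pa_edges_per_gene, directed = FALSE)
    igraph::V(g)$name <- genes
    el <- igraph::as_edgelist(g)
    edges <- data.frame(gene1 = el[, 1L], gene2 = el[, 2L])
    ## extra within-module wiring beyond the backbone, bringing the total
    ## within-module density to ~enrichment x background (enrichment 1 adds
    ## nothing)
    density <- nrow(edges) / choose(config$n_genes, 2L)
    p_within <- min(1, max(0, (config$module_edge_enrichment - 1) * density))
    picked <- sample(genes, 2L * config$module_size)
    modules <- list(module1 = sort(picked[seq_len(config$module_size)]),
                    module2 = sort(picked[-seq_len(config$module_size)]))
    for (mod in modules) {
      pairs <- t(combn(mod, 2L))
      add <- runif(nrow(pairs)) < p_within
      if (any(add)) {
        edges <- rbind(edges, data.frame(gene1 = pairs[add, 1L],
                                         gene2 = pairs[add, 2L]))
      }
    }
    edges <- suppressWarnings(canonicalize_edges(edges))
    list(edges = edges, modules = modules, genes = genes)
  })
}

## VAF windows per variant class; observed tumor VAF is the cancer-cell
## fraction VAF diluted by purity.
sim_variant_vafs <- function(cls, purity) {
  n <- length(cls)
  normal <- numeric(n)
  tumor_ccf <- numeric(n)
  draw <- function(k, lo, hi) runif(k, lo, hi)
  for (cl in unique(cls)) {
    i <- which(cls == cl)
    k <- length(i)
    switch(cl,
      germline_homozygous = {
        normal[i] <- draw(k, 0.92, 1)
        tumor_ccf[i] <- draw(k, 0.92, 1)
      },
      germline_heterozygous = {
        normal[i] <- draw(k, 0.46, 0.54)
        tumor_ccf[i] <- draw(k, 0.46, 0.54)
      },
      founding_homozygous = {
        normal[i] <- draw(k, 0, 0.02)
        tumor_ccf[i] <- draw(k, 0.92, 1)
      },
      founding_heterozygous = {
        normal[i] <- draw(k, 0, 0.02)
        tumor_ccf[i] <- draw(k, 0.46, 0.54)
      },
      subclonal = {
        normal[i] <- draw(k, 0, 0.02)
        tumor_ccf[i] <- draw(k, 0.08, 0.35)
      })
  }
  list(normal = normal, tumor_obs = tumor_ccf * purity)
}

#' Simulate the mutation cohort
#'
#' Survival comes first: each sample is assigned a hazard state
#' (recurrence-prone or not), draws an exponential event time against
#' independent uniform censoring, and its *observed* recurrence status is
#' the event indicator. Recurred samples then draw most of their mutated
#' genes from the recurrence module, non-recurred samples from the other
#' module, the rest uniformly from the background — founding-clone
#' genotypes converge on the network region matching the outcome, while
#' mutated genes are rarely shared between samples. Variant VAFs land in
#' the configured class windows (diluted by a per-sample purity) and
#' annotator calls pass the functional merge at the configured rate.
#'
#' @param config from [sim_config()].
#' @param network from [simulate_network()].
#' @param seed RNG seed.
#' @return list with `mutations`, `annotations`, `clinical` (data frames)
#'   and `truth` (per-sample state, planted modules, per-variant class).
#' @export
simulate_cohort <- function(config = sim_config(),
                            network = simulate_network(config), seed = 1L) {
  with_seed(seed, {
    n <- config$n_samples
    ids <- sprintf("s%03d", seq_len(n))
    state <- rbinom(n, 1L, config$recurred_fraction)  # 1 = recurrence-prone

    ## survival: exponential event time vs uniform censoring
    rate <- config$baseline_hazard * ifelse(state == 1L, config$hazard_ratio, 1)
    t_event <- rexp(n, rate)
    t_cens <- runif(n, config$censoring_range[1L], config$censoring_range[2L])
    dfs_event <- as.integer(t_event <= t_cens)
    dfs_time <- pmin(t_event, t_cens)
    clinical <- data.frame(sample_id = ids, dfs_time = dfs_time,
                           dfs_event = dfs_event, er_status = "positive")

    purity <- runif(n, config$purity_range[1L], config$purity_range[2L])
    background <- setdiff(network$genes, unlist(network$modules))

    mut_rows <- vector("list", n)
    ann_rows <- vector("list", n)
    variant_truth <- vector("list", n)
    pos_counter <- 0L
    for (i in seq_len(n)) {
      n_mut <- sample(config$mutations_range[1L]:config$mutations_range[2L], 1L)
      n_off <- rbinom(1L, n_mut, config$off_module_rate)
      n_on <- n_mut - n_off
      mod <- network$modules[[if (dfs_event[i] == 1L) "module1" else "module2"]]
      genes_i <- c(sample(mod, min(n_on, length(mod))),
                   sample(background, n_off))
      k <- length(genes_i)
      cls <- sample(names(config$class_mix), k, replace = TRUE,
                    prob = config$class_mix)
      vafs <- sim_variant_vafs(cls, purity[i])
      cn <- ifelse(runif(k) < config$non_diploid_rate, 3L, 2L)
      pos <- pos_counter + seq_len(k)
      pos_counter <- pos_counter + k
      mut_rows[[i]] <- data.frame(
        sample_id = ids[i], gene = genes_i, chrom = "1", pos = pos,
        ref = "A", alt = "T", tumor_vaf = vafs$tumor_obs,
        normal_vaf = vafs$normal, copy_number_state = cn, purity = purity[i])
      variant_truth[[i]] <- data.frame(sample_id = ids[i], gene = genes_i,
                                       class = cls, copy_number_state = cn)

      ## annotator calls: one functional branch per functional variant
      functional <- runif(k) < config$functional_rate
      branch <- sample(c("cravat", "mt", "cadd"), k, replace = TRUE)
      cravat <- runif(k, 0, 0.49)
      mt <- rep("benign", k)
      cadd <- runif(k, 0, 9)
      pph <- rep("benign", k)
      sift <- rep("tolerated", k)
      sel <- functional & branch == "cravat"
      cravat[sel] <- runif(sum(sel), 0.5, 1)
      sel <- functional & branch == "mt"
      mt[sel] <- "disease"
      sel <- functional & branch == "cadd"
      cadd[sel] <- runif(sum(sel), 10, 40)
      pph[sel] <- "damaging"
      ann_rows[[i]] <- data.frame(
        sample_id = ids[i], gene = genes_i, chrom = "1", pos = pos,
        ref = "A", alt = "T", cravat_score = cravat,
        mutationtaster_call = mt, cadd_cscore = cadd, polyphen_call = pph,
        sift_call = sift, functional_truth = functional)
    }
    annotations <- do.call(rbind, ann_rows)
    truth_functional <- annotations$functional_truth
    annotations$functional_truth <- NULL
    list(mutations = do.call(rbind, mut_rows), annotations = annotations,
         clinical = clinical,
         truth = list(state = setNames(state, ids),
                      recurred = setNames(dfs_event, ids),
                      modules = network$modules,
                      variant_class = do.call(rbind, variant_truth),
                      functional = truth_functional,
                      purity = setNames(purity, ids)))
  })
}

#' Simulate expression, copy-number and hallmark evidence
#'
#' Tumor expression is Gaussian around gene-level baselines with the
#' planted modules shifted between the observed recurrence groups;
#' cell-line expression
#' separates an epithelial and a mesenchymal group (CDH1/VIM markers
#' included) with the same module shifts; GISTIC-like scores are elevated
#' for module genes and a random regulator subset; hallmark gene sets each
#' contain one planted module plus disjoint background fillers.
#'
#' @param config from [sim_config()].
#' @param network from [simulate_network()].
#' @param truth truth list from [simulate_cohort()].
#' @param seed RNG seed.
#' @return list with `tumor_expr`, `celline_expr`, `gistic`, `hallmarks`
#'   (+`hallmark_modules` truth map).
#' @export
simulate_expression <- function(config = sim_config(), network, truth,
                                seed = 1L) {
  with_seed(seed, {
    genes <- network$genes
    ids <- names(truth$state)
    base <- rnorm(length(genes), 8, 1)
    names(base) <- genes
    eff <- config$expression_effect

    tumor <- matrix(rnorm(length(genes) * length(ids), base, 1),
                    nrow = length(genes), dimnames = list(genes, ids))
    rec <- truth$recurred == 1L
    tumor[network$modules$module1, rec] <-
      tumor[network$modules$module1, rec] + eff
    tumor[network$modules$module2, !rec] <-
      tumor[network$modules$module2, !rec] + eff

    ## cell lines: epithelial vs mesenchymal with CDH1/VIM markers
    n_cl <- config$n_celllines
    n_epi <- config$n_celllines_epithelial
    cl_ids <- sprintf("cl%02d", seq_len(n_cl))
    epi <- seq_len(n_cl) <= n_epi
    cl_genes <- c(genes, "CDH1", "VIM")
    celline <- matrix(rnorm(length(cl_genes) * n_cl, c(base, 8, 8), 1),
                      nrow = length(cl_genes),
                      dimnames = list(cl_genes, cl_ids))
    celline[network$modules$module1, epi] <-
      celline[network$modules$module1, epi] + eff
    celline[network$modules$module2, !epi] <-
      celline[network$modules$module2, !epi] + eff
    celline["CDH1", ] <- ifelse(epi, runif(n_cl, 1.8, 2.2), runif(n_cl, 0.8, 1.1))
    celline["VIM", ] <- ifelse(epi, runif(n_cl, 0.8, 1.1), runif(n_cl, 1.8, 2.2))

    ## GISTIC-like scores: module genes + a random background subset elevated
    background <- setdiff(genes, unlist(network$modules))
    regulators <- c(unlist(network$modules),
                    sample(background,
                           round(config$regulator_fraction * length(background))))
    gistic <- setNames(runif(length(genes), 0, 0.3), genes)
    gistic[regulators] <- runif(length(regulators), 0.4, 1)

    ## hallmarks: module1 in the first three sets, module2 in the last three
    hm <- hallmark_names()
    fillers <- sample(background, 6L * config$hallmark_background)
    filler_sets <- split(fillers, rep(seq_len(6L), each = config$hallmark_background))
    hallmarks <- lapply(seq_len(6L), function(i) {
      mod <- if (i <= 3L) network$modules$module1 else network$modules$module2
      sort(c(mod, filler_sets[[i]]))
    })
    names(hallmarks) <- hm
    attr(hallmarks, "descriptions") <- setNames(rep("synthetic hallmark", 6L), hm)
    hallmark_modules <- setNames(rep(c("module1", "module2"), each = 3L), hm)

    list(tumor_expr = tumor, celline_expr = celline, gistic = gistic,
         hallmarks = hallmarks, hallmark_modules = hallmark_modules)
  })
}

#' One-call synthetic dataset
#'
#' Runs [simulate_network()], [simulate_cohort()] and
#' [simulate_expression()] under sub-seeds derived from `seed` and bundles
#' everything, including the truth manifest.
#'
#' @param config from [sim_config()].
#' @param seed RNG seed.
#' @return list with `network`, `cohort`, `evidence`, `config`, `seed`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1L) {
  network <- simulate_network(config, seed = seed)
  cohort <- simulate_cohort(config, network, seed = seed + 1L)
  evidence <- simulate_expression(config, network, cohort$truth,
                                  seed = seed + 2L)
  list(network = network, cohort = cohort, evidence = evidence,
       config = config, seed = seed)
}

#' Write a synthetic dataset to pipeline input files
#'
#' Emits the TSV/GMT files the pipeline reads plus a JSON truth manifest.
#'
#' @param dataset from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  num_cols <- c("tumor_vaf", "normal_vaf", "purity")
  mut <- dataset$cohort$mutations
  mut[num_cols] <- lapply(mut[num_cols], fmt_num)
  write_tsv(mut, p("mutations.tsv"))
  ann <- dataset$cohort$annotations
  ann[c("cravat_score", "cadd_cscore")] <-
    lapply(ann[c("cravat_score", "cadd_cscore")], fmt_num)
  write_tsv(ann, p("annotations.tsv"))
  cl <- dataset$cohort$clinical
  cl$dfs_time <- fmt_num(cl$dfs_time)
  write_tsv(cl, p("clinical.tsv"))
  write_edge_list(dataset$network$edges, p("network.tsv"))
  write_expression(dataset$evidence$tumor_expr, p("tumor_expression.tsv"))
  write_expression(dataset$evidence$celline_expr, p("celline_expression.tsv"))
  write_tsv(data.frame(gene = names(dataset$evidence$gistic),
                       score = fmt_num(dataset$evidence$gistic)),
            p("gistic.tsv"))
  write_gmt(dataset$evidence$hallmarks, p("hallmarks.gmt"))
  jsonlite::write_json(
    list(seed = dataset$seed,
         state = as.list(dataset$cohort$truth$state),
         modules = dataset$cohort$truth$modules,
         hallmark_modules = as.list(dataset$evidence$hallmark_modules)),
    p("truth.json"), auto_unbox = TRUE)
  c(mutations = p("mutations.tsv"), annotations = p("annotations.tsv"),
    clinical = p("clinical.tsv"), network = p("network.tsv"),
    tumor_expr = p("tumor_expression.tsv"),
    celline_expr = p("celline_expression.tsv"), gistic = p("gistic.tsv"),
    hallmarks = p("hallmarks.gmt"), truth = p("truth.json"))
}
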