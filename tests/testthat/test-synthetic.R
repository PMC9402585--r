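small_cfg <- function(n_samples = 60L, ...) {
  sim_config(n_samples = n_samples, n_genes = 400L,
             mutations_range = c(15L, 25L), hallmark_background = 20L, ...)
}

test_that("generators are deterministic per seed", {
  n1 <- simulate_network(small_cfg(), seed = 5)
  n2 <- simulate_network(small_cfg(), seed = 5)
  expect_identical(n1, n2)
  expect_false(identical(n1$edges, simulate_network(small_cfg(), seed = 6)$edges))

  d1 <- simulate_dataset(small_cfg(), seed = 5)
  d2 <- simulate_dataset(small_cfg(), seed = 5)
  expect_identical(d1$cohort$mutations, d2$cohort$mutations)
  expect_identical(d1$evidence$tumor_expr, d2$evidence$tumor_expr)
})

test_that("planted modules are wired above background density", {
  cfg <- small_cfg()
  net <- simulate_network(cfg, seed = 7)
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$genes)
  deg <- igraph::degree(g)
  in_module <- names(deg) %in% unlist(net$modules)
  expect_gt(mean(deg[in_module]), mean(deg))

  # within-module edge probability far exceeds background
  mod <- net$modules$module1
  sub <- igraph::induced_subgraph(g, mod)
  p_within <- igraph::ecount(sub) / choose(length(mod), 2)
  p_global <- igraph::ecount(g) / choose(length(net$genes), 2)
  expect_gt(p_within, 10 * p_global)

  # enrichment 1: modules indistinguishable from background (chi-square
  # over pooled counts across seeds)
  within <- 0; within_exp <- 0
  for (s in 1:20) {
    n0 <- simulate_network(small_cfg(module_edge_enrichment = 1), seed = s)
    g0 <- igraph::graph_from_data_frame(n0$edges, directed = FALSE,
                                        vertices = n0$genes)
    m0 <- n0$modules$module1
    within <- within + igraph::ecount(igraph::induced_subgraph(g0, m0))
    within_exp <- within_exp + igraph::ecount(g0) / choose(400, 2) * choose(30, 2)
  }
  expect_gt(poisson.test(within, T = within_exp)$p.value, 0.01)
})

test_that("the cohort has sparse mutation overlap and planted VAF structure", {
  cfg <- sim_config()
  net <- simulate_network(cfg, seed = 11)
  co <- simulate_cohort(cfg, net, seed = 12)

  genes_by_sample <- split(co$mutations$gene, co$mutations$sample_id)
  pairs <- combn(100, 2)
  jac <- apply(pairs, 2, function(ij) {
    a <- genes_by_sample[[ij[1]]]; b <- genes_by_sample[[ij[2]]]
    length(intersect(a, b)) / length(union(a, b))
  })
  expect_lt(median(jac), 0.1)

  # classification recovers the planted classes on diploid variants
  adj <- adjust_tumor_vaf(co$mutations$tumor_vaf, co$mutations$purity)
  got <- as.character(classify_variants(co$mutations$normal_vaf, adj,
                                        co$mutations$copy_number_state))
  want <- co$truth$variant_class$class
  diploid <- co$mutations$copy_number_state == 2L
  want[!diploid] <- "excluded"
  want[diploid & want == "subclonal"] <- "excluded"
  expect_identical(got, want)

  # all-founding configuration: variant filtering recovers every planted gene
  cfg1 <- small_cfg(class_mix = c(founding_heterozygous = 1),
                    non_diploid_rate = 0, functional_rate = 1)
  net1 <- simulate_network(cfg1, seed = 13)
  co1 <- simulate_cohort(cfg1, net1, seed = 14)
  clones <- suppressWarnings(build_founding_clones(
    co1$mutations, merge_functional_genes(co1$annotations)))
  planted <- split(co1$mutations$gene, co1$mutations$sample_id)
  for (s in names(planted)) {
    expect_setequal(clones[[s]], planted[[s]])
  }

  # annotations pass the functional merge exactly at the planted truth
  fun <- is_functional(co$annotations)
  expect_equal(mean(fun), cfg$functional_rate, tolerance = 0.02)
})

test_that("a null hazard ratio removes the survival contrast between states", {
  hits <- 0
  for (s in 1:20) {
    cfg0 <- small_cfg(hazard_ratio = 1, baseline_hazard = 0.01)
    net <- simulate_network(cfg0, seed = 100 + s)
    co <- simulate_cohort(cfg0, net, seed = 200 + s)
    st <- co$truth$state
    p <- logrank_p(names(st)[st == 1], names(st)[st == 0], co$clinical)
    if (p < 0.05) hits <- hits + 1
  }
  expect_lte(hits, 2)  # non-significant in at least 18/20 seeds
})

test_that("expression evidence reconstructs the planted network sets", {
  # survival strong enough that the resampled Kaplan-Meier stage keeps
  # genuinely associated genes in every re-sampling
  cfg <- small_cfg(n_samples = 200L, baseline_hazard = 0.01)
  ds <- simulate_dataset(cfg, seed = 21)
  m1 <- ds$network$modules$module1
  m2 <- ds$network$modules$module2
  planted <- c(m1, m2)

  set1 <- identify_set1(ds$evidence$celline_expr, seed = 1)
  set2 <- identify_set2(ds$evidence$tumor_expr, ds$cohort$clinical, seed = 2)
  set3 <- identify_set3(ds$evidence$gistic, ds$evidence$tumor_expr)
  common <- Reduce(intersect, list(set1, set2, set3))
  expect_gte(mean(planted %in% common), 0.8)

  # type-I calibration: a single unresampled t-screen keeps ~5% of null genes
  null_genes <- setdiff(ds$network$genes, planted)
  cls <- classify_cell_lines(ds$evidence$celline_expr)
  p <- netmet:::row_welch_p(ds$evidence$celline_expr[null_genes, ],
                            cls == "epithelial")
  expect_gt(mean(p < 0.05, na.rm = TRUE), 0.02)
  expect_lt(mean(p < 0.05, na.rm = TRUE), 0.09)
})

test_that("written datasets pass the package's own readers unchanged", {
  dir <- tempfile()
  ds <- simulate_dataset(small_cfg(), seed = 31)
  paths <- write_dataset(ds, dir)
  mut <- read_mutation_table(paths[["mutations"]])
  expect_equal(nrow(mut), nrow(ds$cohort$mutations))
  cl <- read_clinical(paths[["clinical"]])
  expect_equal(nrow(cl), 60)
  edges <- read_edge_list(paths[["network"]])
  expect_equal(nrow(edges), nrow(ds$network$edges))
  gmt <- read_gmt(paths[["hallmarks"]])
  expect_equal(lengths(gmt), lengths(ds$evidence$hallmarks))
  ann <- read_annotation_table(paths[["annotations"]])
  expect_equal(nrow(ann), nrow(ds$cohort$annotations))
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(length(truth$state), 60)
})
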