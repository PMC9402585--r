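# Permutation-based log-rank oracle for tiny cohorts: the chi-square
# statistic's null distribution is generated by permuting group labels.
permutation_logrank_p <- function(time, event, group, n_perm = 2000) {
  stat <- function(g) {
    fit <- survival::survdiff(survival::Surv(time, event) ~ g)
    fit$chisq
  }
  obs <- stat(group)
  perms <- replicate(n_perm, stat(sample(group)))
  mean(perms >= obs)
}

test_that("fuzzy bipartition separates clean groups and is symmetric", {
  fb <- fuzzy_bipartition(c(0, 0, 0, 10, 10, 10))
  expect_equal(fb$cluster, c(1, 1, 1, 2, 2, 2))
  expect_error(fuzzy_bipartition(rep(3, 8)), "degenerate")

  # symmetric values split into equal-sized groups
  v <- c(-4, -3, -2, -1, 1, 2, 3, 4)
  fb2 <- fuzzy_bipartition(v)
  expect_equal(sum(fb2$cluster == 1), 4)
  expect_equal(fb2$centers[1], -fb2$centers[2], tolerance = 1e-6)

  # bimodal mixture with 4-sd separation: >95% agreement with the truth
  withr_seed(41)
  lab <- rep(c(1, 2), each = 100)
  x <- rnorm(200, mean = c(0, 4)[lab])
  fb3 <- fuzzy_bipartition(x)
  expect_gt(mean(fb3$cluster == lab), 0.95)
})

test_that("fuzzy bipartition agrees with the reference fuzzy c-means", {
  skip_if_not_installed("e1071")
  withr_seed(42)
  for (rep in 1:10) {
    x <- c(rnorm(60, 0), rnorm(40, 5))
    fb <- fuzzy_bipartition(x)
    init <- matrix(quantile(x, c(0.25, 0.75)), ncol = 1)
    ref <- e1071::cmeans(matrix(x, ncol = 1), centers = init, m = 2)
    ref_cl <- ref$cluster
    if (ref$centers[1] > ref$centers[2]) ref_cl <- 3 - ref_cl
    expect_gt(mean(fb$cluster == ref_cl), 0.99)
    expect_equal(sort(as.numeric(ref$centers)), fb$centers, tolerance = 1e-3)
  }
})

test_that("log-rank p matches survdiff, the C++ kernel, and a permutation oracle", {
  withr_seed(43)
  n <- 24
  cl <- data.frame(sample_id = sprintf("s%02d", 1:n),
                   dfs_time = rexp(n, 1 / 40), dfs_event = rbinom(n, 1, 0.7))
  ga <- cl$sample_id[1:12]
  gb <- cl$sample_id[13:24]
  p <- logrank_p(ga, gb, cl)
  p_cpp <- netmet:::.logrank_p_cpp(cl$dfs_time, cl$dfs_event,
                                   rep(0:1, each = 12))
  expect_equal(p, p_cpp, tolerance = 1e-12)
  p_perm <- permutation_logrank_p(cl$dfs_time, cl$dfs_event,
                                  rep(0:1, each = 12))
  expect_equal(p, p_perm, tolerance = 0.05)

  # strong hazard contrast is decisively significant
  time2 <- c(rexp(50, 1 / 10), rexp(50, 1 / 50))
  cl2 <- data.frame(sample_id = sprintf("t%03d", 1:100),
                    dfs_time = time2, dfs_event = 1L)
  expect_lt(logrank_p(cl2$sample_id[1:50], cl2$sample_id[51:100], cl2), 1e-6)

  # near-identical survival: p close to 1
  cl3 <- data.frame(sample_id = sprintf("u%02d", 1:20),
                    dfs_time = rep(1:10, 2) + rep(c(0, 1e-9), each = 10),
                    dfs_event = 1L)
  expect_gt(logrank_p(cl3$sample_id[1:10], cl3$sample_id[11:20], cl3), 0.9)

  expect_error(logrank_p(ga, gb, transform(cl, dfs_event = 0L)), "no events")
  expect_error(logrank_p(character(), gb, cl), "non-empty")
})

test_that("modulated-gene screen keeps outcome-tracking genes at the nominal rate", {
  pl <- planted_netmatrix()
  mod <- suppressMessages(find_modulated_genes(pl$nm, pl$clinical))
  expect_true(all(pl$signal_genes %in% mod))

  # direct oracle on one planted gene: its clusters separate survival
  fb <- fuzzy_bipartition(pl$nm[pl$signal_genes[1], ])
  ids <- pl$clinical$sample_id
  expect_lt(logrank_p(ids[fb$cluster == 1], ids[fb$cluster == 2],
                      pl$clinical), 1e-4)

  # null genes are retained at about the nominal 5% rate
  withr_seed(44)
  null_nm <- matrix(rnorm(800 * 80), 800, 80,
                    dimnames = list(sprintf("n%03d", 1:800),
                                    pl$clinical$sample_id))
  null_mod <- find_modulated_genes(null_nm, pl$clinical)
  expect_gt(length(null_mod) / 800, 0.01)
  expect_lt(length(null_mod) / 800, 0.09)

  # constant genes are skipped, not errors
  null_nm[1, ] <- 7
  expect_message(find_modulated_genes(null_nm, pl$clinical), "skipped 1")
})

test_that("hallmark pools intersect, warn out of range, and skip empties", {
  hallmarks <- list(a = sprintf("g%03d", 1:150), b = sprintf("g%03d", 200:205),
                    c = "absent")
  modulated <- sprintf("g%03d", 1:300)
  expect_warning(expect_warning(
    pools <- collect_hallmark_pools(modulated, hallmarks),
    "empty pool"), "outside")
  expect_equal(names(pools), c("a", "b"))
  expect_equal(length(pools$a), 150)

  quiet <- collect_hallmark_pools(modulated, list(a = sprintf("g%03d", 1:150)))
  expect_equal(lengths(quiet), c(a = 150L))
})

test_that("random-set screening retains signal sets and rejects null sets", {
  pl <- planted_netmatrix(n_genes = 80, k_signal = 30, n_samples = 100)
  cfg <- mss_config(n_random_gene_sets = 300, n_random_sample_sets = 60)
  pool_signal <- pl$signal_genes                 # pure signal: one possible set
  scr <- screen_random_gene_sets(pl$nm, pl$clinical, pool_signal, cfg, seed = 3)
  expect_equal(length(scr$retained_idx), 300)    # every draw passes

  # Null sets survive only rarely. The sample subsets are resamples of one
  # cohort, so per-subset passes are strongly correlated: a null set that is
  # lucky on the cohort passes most subsets, which keeps the retention rate
  # small but not exactly zero.
  pool_null <- rownames(pl$nm)[31:80]            # 50 noise genes
  scr0 <- screen_random_gene_sets(pl$nm, pl$clinical, pool_null,
                                  mss_config(n_random_gene_sets = 500,
                                             n_random_sample_sets = 60),
                                  seed = 4)
  expect_lt(length(scr0$retained_idx) / 500, 0.01)

  expect_warning(
    expect_null(screen_random_gene_sets(pl$nm, pl$clinical,
                                        rownames(pl$nm)[1:10], cfg)),
    "smaller than")

  # the pass criterion is strictly more than pass_fraction of the subsets
  expect_equal(scr$need, floor(0.8 * 60) + 1)
})

test_that("retention calibration applies the scaled band and tightens cutoffs", {
  # synthetic screen object: 40 sets whose pass counts at halved cutoffs
  # differ, so tightening must order them
  withr_seed(45)
  pv <- matrix(runif(40 * 100, 0, 0.04), 40, 100)
  pv[1:5, ] <- runif(5 * 100, 0, 1e-4)  # the truly robust sets
  scr <- structure(list(sets = lapply(1:40, function(i) letters[1:3]),
                        retained_idx = 1:40, pvals = pv, n_subsets = 100,
                        alpha = 0.05, need = 81),
                   class = "mss_screen")
  # scaled band: 10000/5e6 * (1000, 5000) = (2, 10)
  cfg <- mss_config(n_random_gene_sets = 10000)
  cal <- calibrate_retention(scr, cfg)
  expect_false(isTRUE(cal$discarded))
  expect_lte(cal$n_retained, 10)
  expect_gte(cal$n_retained, 2)
  expect_lt(cal$alpha, 0.05)
  expect_true(all(1:5 %in% scr$retained_idx[
    which(rowSums(pv < cal$alpha) >= 81)]))

  # below the scaled minimum: hallmark discarded
  scr_small <- scr
  scr_small$retained_idx <- 1L
  scr_small$sets <- scr$sets[1]
  scr_small$pvals <- pv[1, , drop = FALSE]
  cal2 <- calibrate_retention(scr_small, cfg)
  expect_true(isTRUE(cal2$discarded))

  # inside the band: untouched
  scr_ok <- scr
  scr_ok$retained_idx <- 1:5
  scr_ok$sets <- scr$sets[1:5]
  scr_ok$pvals <- pv[1:5, , drop = FALSE]
  cal3 <- calibrate_retention(scr_ok, cfg)
  expect_equal(cal3$n_retained, 5)
  expect_equal(cal3$alpha, 0.05)
})

test_that("signatures rank genes by frequency with lexicographic ties", {
  pl <- planted_netmatrix()
  sets <- list(c("b", "a", "c"), c("a", "c", "d"), c("a", "b", "e"))
  rownames(pl$nm)[1:5] <- c("a", "b", "c", "d", "e")
  sig <- build_signature(sets, pl$nm, pl$clinical$dfs_event == 1,
                         hallmark = "h", mss_config(signature_size = 4))
  expect_equal(sig$genes, c("a", "b", "c", "d"))  # 3,2,2,1; b<c breaks the tie
  expect_equal(unname(sig$gene_frequencies), c(3L, 2L, 2L, 1L))
  expect_true(all(diff(sig$gene_frequencies) <= 0))
  expect_null(build_signature(list(), pl$nm, pl$clinical$dfs_event == 1))

  # the two state centroids differ on signal genes (the state switch)
  pl2 <- planted_netmatrix()
  sig2 <- build_signature(list(pl2$signal_genes), pl2$nm,
                          pl2$clinical$dfs_event == 1, "h2",
                          mss_config(signature_size = 10))
  expect_gt(mean(sig2$state_recurred - sig2$state_nonrecurred), 1)
})

test_that("discovery is deterministic given the seed", {
  pl <- planted_netmatrix(n_genes = 80, k_signal = 30, n_samples = 100)
  hallmarks <- list(h1 = rownames(pl$nm)[1:40])
  cfg <- mss_config(n_random_gene_sets = 200, n_random_sample_sets = 40)
  d1 <- suppressWarnings(discover_signatures(pl$nm, pl$clinical, hallmarks,
                                             cfg, seed = 9))
  d2 <- suppressWarnings(discover_signatures(pl$nm, pl$clinical, hallmarks,
                                             cfg, seed = 9))
  expect_identical(lapply(d1$signatures, `[[`, "genes"),
                   lapply(d2$signatures, `[[`, "genes"))
  expect_identical(d1$details, d2$details)
})
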