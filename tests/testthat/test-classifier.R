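toy_sig <- function(genes) structure(list(hallmark = "toy", genes = genes),
                                     class = "nog_signature")

test_that("centroid training reduces to class means at zero shrinkage", {
  # hand fixture: 3 genes x 4 samples, 2 per class
  nm <- matrix(c(1, 4, 0,
                 3, 6, 2,
                 10, 0, 5,
                 12, 2, 7), nrow = 3,
               dimnames = list(c("gA", "gB", "gC"), paste0("s", 1:4)))
  labels <- c(FALSE, FALSE, TRUE, TRUE)
  mod <- train_centroids(toy_sig(c("gA", "gB", "gC")), nm, labels, delta = 0)
  # manual arithmetic: class means
  expect_equal(unname(mod$centroid_low), c((1 + 3) / 2, (4 + 6) / 2, (0 + 2) / 2))
  expect_equal(unname(mod$centroid_high), c(11, 1, 6))

  # full shrinkage collapses both centroids onto the overall mean
  mod2 <- train_centroids(toy_sig(c("gA", "gB", "gC")), nm, labels, delta = 1e6)
  overall <- rowMeans(nm)
  expect_equal(mod2$centroid_low, overall)
  expect_equal(mod2$centroid_high, overall)

  # intermediate shrinkage moves centroids toward the overall mean
  mod3 <- train_centroids(toy_sig(c("gA", "gB", "gC")), nm, labels, delta = 0.5)
  expect_true(all(abs(mod3$centroid_high - overall) <=
                  abs(mod$centroid_high - overall) + 1e-12))

  expect_error(train_centroids(toy_sig("gA"), nm, c(TRUE, FALSE, FALSE, FALSE)),
               ">= 2")
})

test_that("votes follow the closer state centroid and are affine invariant", {
  genes <- sprintf("g%02d", 1:20)
  withr_seed(51)
  model <- structure(list(genes = genes,
                          centroid_high = rnorm(20, 2),
                          centroid_low = rnorm(20, -2)),
                     class = "centroid_model")
  names(model$centroid_high) <- names(model$centroid_low) <- genes

  expect_equal(vote(model$centroid_low, model), "low")
  expect_equal(vote(model$centroid_high, model), "high")
  expect_equal(vote(setNames(rep(1, 20), genes), model), "abstain")

  # scaling and shifting a profile never changes the vote
  for (rep in 1:20) {
    x <- setNames(rnorm(20), genes)
    v <- vote(x, model)
    expect_equal(vote(3.7 * x + 11, model), v)
    expect_equal(vote(0.01 * x - 5, model), v)
  }

  # recurred centroid plus small noise votes high nearly always
  hits <- sum(vapply(1:100, function(i) {
    vote(model$centroid_high + rnorm(20, sd = 0.01), model) == "high"
  }, logical(1)))
  expect_gte(hits, 99)
})

test_that("vote aggregation reproduces the published cutoff behavior", {
  mk <- function(low, high, m = 18) {
    c(rep("low", low), rep("high", high), rep("abstain", m - low - high))
  }
  expect_equal(aggregate_votes(mk(18, 0), 9, 15)$call, "low")
  expect_equal(aggregate_votes(mk(2, 16), 9, 15)$call, "high")
  expect_equal(aggregate_votes(mk(8, 10), 9, 15)$call, "unclassified")

  # enumerated sweep against an independent statement of the rule
  for (low in 0:18) {
    for (high in 0:(18 - low)) {
      agg <- aggregate_votes(mk(low, high), 9, 15)
      want <- if (high >= 15) "high" else if (low >= 9) "low" else "unclassified"
      expect_equal(agg$call, want)
      expect_equal(agg$low_votes + agg$high_votes + agg$abstentions, 18)
    }
  }

  # permutation invariance over signature order
  withr_seed(52)
  v <- sample(mk(7, 6))
  expect_equal(aggregate_votes(v, 9, 15), aggregate_votes(rev(v), 9, 15))
})

test_that("LOOCV separates well-separated classes and never leaks the fold", {
  withr_seed(53)
  n <- 40
  genes <- sprintf("g%02d", 1:15)
  state <- rep(c(0L, 1L), each = n / 2)
  nm <- matrix(rnorm(15 * n), 15, n,
               dimnames = list(genes, sprintf("s%02d", 1:n)))
  # 4-sd centroid gap with per-gene structure on both states (correlation
  # voting compares profile shapes, so each class needs its own shape)
  nm[, state == 1L] <- nm[, state == 1L] + rnorm(15, 0, 4)
  nm[, state == 0L] <- nm[, state == 0L] + rnorm(15, 0, 4)
  clinical <- data.frame(sample_id = colnames(nm),
                         dfs_time = ifelse(state == 1, 10, 100),
                         dfs_event = state)
  css <- list(signatures = list(toy_sig(genes)), LN = 1L, HN = 1L)
  res <- loocv(css, nm, clinical)
  acc <- mean((res$calls$call == "high") == (state == 1L))
  expect_gte(acc, 0.9)
  expect_gte(res$evaluation$low$precision, 0.9)

  # shuffled labels: chance-level accuracy pooled over repeats
  correct <- 0; total <- 0
  for (k in 1:20) {
    sh <- clinical
    sh$dfs_event <- sample(sh$dfs_event)
    r <- loocv(css, nm, sh)
    ok <- (r$calls$call == "high") == (sh$dfs_event[match(r$calls$sample_id,
                                                          sh$sample_id)] == 1L)
    correct <- correct + sum(ok[r$calls$call != "unclassified"])
    total <- total + sum(r$calls$call != "unclassified")
  }
  expect_gt(correct / total, 0.35)
  expect_lt(correct / total, 0.65)

  # leakage check: every fold's call equals classification with centroids
  # trained on all other samples -- the held-out sample never sees itself
  for (i in c(1, 15, 33)) {
    mod_i <- train_centroids(css$signatures[[1]], nm[, -i],
                             clinical$dfs_event[-i] == 1L)
    v <- vote(nm[, i], mod_i)
    want <- if (v == "high") "high" else if (v == "low") "low" else "unclassified"
    expect_equal(res$calls$call[res$calls$sample_id == colnames(nm)[i]], want)
  }

  # one sample per class: every fold skipped
  tiny_nm <- nm[, 1:2]
  tiny_cl <- clinical[1:2, ]
  tiny_cl$dfs_event <- c(0L, 1L)
  expect_warning(res3 <- loocv(css, tiny_nm, tiny_cl), "skipped")
  expect_equal(nrow(res3$calls), 0L)
})
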