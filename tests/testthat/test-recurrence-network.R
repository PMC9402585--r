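test_that("cell-line classification uses the CDH1/VIM ratio with its boundary", {
  expr <- matrix(c(1.3, 1.0, 1.2, 1.0, 0, 5), nrow = 2,
                 dimnames = list(c("CDH1", "VIM"), c("c1", "c2", "c3")))
  cls <- classify_cell_lines(expr)
  expect_equal(as.character(cls), c("epithelial", "mesenchymal", "mesenchymal"))
  expr["VIM", 1] <- 0
  expect_error(classify_cell_lines(expr), "VIM")
})

test_that("Set 1 keeps planted genes and drops flat ones across resamples", {
  withr_seed(31)
  n <- 20
  expr <- matrix(rnorm(50 * 2 * n), 50, 2 * n,
                 dimnames = list(sprintf("g%02d", 1:50),
                                 sprintf("c%02d", seq_len(2 * n))))
  classes <- factor(rep(c("epithelial", "mesenchymal"), each = n),
                    levels = c("epithelial", "mesenchymal"))
  expr[1:5, classes == "epithelial"] <- expr[1:5, classes == "epithelial"] + 5
  expr["g10", ] <- 1  # identical in both groups

  # direct-oracle check: a 5-sd shift is overwhelming for a plain t-test
  expect_lt(t.test(expr[1, classes == "epithelial"],
                   expr[1, classes == "mesenchymal"])$p.value, 1e-10)

  set1 <- identify_set1(expr, classes, seed = 1)
  expect_true(all(sprintf("g%02d", 1:5) %in% set1))
  expect_false("g10" %in% set1)

  # degenerate config reduces to a single plain t-test screen
  single <- identify_set1(expr, classes,
                          resampling_config(n_resamples = 1, sample_fraction = 1),
                          seed = 1)
  p <- netmet:::row_welch_p(expr, classes == "epithelial")
  expect_setequal(single, rownames(expr)[!is.na(p) & p < 0.05])

  # shrinking the threshold never grows the screen
  tight <- identify_set1(expr, classes, resampling_config(p_threshold = 0.001),
                         seed = 1)
  expect_true(all(tight %in% set1))
})

test_that("Set 2 requires both the t-screen and resampled survival association", {
  withr_seed(32)
  n <- 120
  expr <- matrix(rnorm(40 * n), 40, n,
                 dimnames = list(sprintf("g%02d", 1:40), sprintf("s%03d", 1:n)))
  risk <- expr["g01", ] > median(expr["g01", ])  # gene 1 drives hazard
  time <- ifelse(risk, rexp(n, 1 / 20), rexp(n, 1 / 100))
  cens <- runif(n, 50, 150)
  clinical <- data.frame(sample_id = colnames(expr),
                         dfs_time = pmin(time, cens),
                         dfs_event = as.integer(time <= cens))
  expr["g01", ] <- expr["g01", ] + 3 * clinical$dfs_event  # also modulated
  expr["g02", ] <- 0  # zero variance

  # full-cohort oracle: the planted gene separates survival decisively
  expect_lt(logrank_p(clinical$sample_id[risk], clinical$sample_id[!risk],
                      clinical), 1e-6)

  set2 <- identify_set2(expr, clinical, seed = 2)
  expect_true("g01" %in% set2)
  expect_false("g02" %in% set2)

  flat <- clinical
  flat$dfs_event <- 0L
  expect_error(identify_set2(expr, flat), "no events")
})

test_that("Set 3 combines the GISTIC cutoff with within-sample expression rank", {
  expr <- matrix(seq_len(10), nrow = 10, ncol = 1,
                 dimnames = list(letters[1:10], "s1"))
  gistic <- setNames(rep(0.4, 10), letters[1:10])
  gistic["a"] <- 0.3   # boundary: strict greater-than
  gistic["j"] <- 0.8
  set3 <- identify_set3(gistic, expr)
  # rows e..j reach the top 50% by rank (boundary inclusive); 'a' fails the
  # strict GISTIC cutoff
  expect_setequal(set3, c("e", "f", "g", "h", "i", "j"))
  # high GISTIC but bottom-decile expression does not qualify
  gistic2 <- setNames(c(0.8, rep(0, 9)), letters[1:10])
  expect_equal(identify_set3(gistic2, expr), character())
})

test_that("network construction is an induced subgraph of the intersection", {
  edges <- data.frame(gene1 = c("A", "B", "C", "D"),
                      gene2 = c("B", "D", "A", "E"))
  net <- build_recurrence_network(edges, set1 = c("A", "B", "C"),
                                  set2 = c("A", "B", "C", "E"),
                                  set3 = c("C", "B", "A"))
  expect_equal(net$genes, c("A", "B", "C"))
  got <- apply(net$edges[, c("gene1", "gene2")], 1, paste, collapse = "-")
  expect_setequal(got, c("A-B", "A-C"))
  expect_error(build_recurrence_network(edges, "A", "B", "C"), "empty")

  # order of the three sets and edge direction do not matter
  rev_edges <- edges[, c("gene2", "gene1")]
  names(rev_edges) <- c("gene1", "gene2")
  net2 <- build_recurrence_network(rev_edges, set1 = c("C", "B", "A"),
                                   set2 = c("A", "B", "C", "E"),
                                   set3 = c("A", "B", "C"))
  expect_equal(net2$genes, net$genes)
  expect_setequal(unname(apply(net2$edges[, c("gene1", "gene2")], 1, paste,
                               collapse = "-")), unname(got))

  # every retained edge existed in the input
  withr_seed(33)
  big <- data.frame(gene1 = sample(LETTERS[1:15], 40, TRUE),
                    gene2 = sample(LETTERS[1:15], 40, TRUE))
  big <- big[big$gene1 != big$gene2, ]
  keep <- sample(LETTERS[1:15], 10)
  net3 <- build_recurrence_network(big, keep, keep, keep)
  in_edges <- paste(pmin(big$gene1, big$gene2), pmax(big$gene1, big$gene2))
  out_edges <- paste(net3$edges$gene1, net3$edges$gene2)
  expect_true(all(out_edges %in% in_edges))
})
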