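test_that("differential gene selection applies the Welch test and cutoff", {
  set.seed(51)
  M <- matrix(rnorm(50 * 20), 50, 20,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:20)))
  labels <- rep(1:2, each = 10)
  # plant a strong shift and a degenerate gene
  M[1, labels == 2] <- M[1, labels == 2] + 5
  M[2, ] <- 3
  expect_message(sig <- differential_genes(M, labels, alpha = 0.01),
                 "zero variance")
  expect_true("g1" %in% sig$gene_ids)
  expect_false("g2" %in% sig$gene_ids)
  expect_equal(sig$n_excluded, 1)
  expect_equal(sig$n_tested, 49)
  expect_true(all(sig$p_values < 0.01))
  # statistics agree with the closed-form Welch expressions
  i <- match("g1", rownames(M))
  o <- oracle_welch(M[i, labels == 1], M[i, labels == 2])
  j <- match("g1", sig$gene_ids)
  expect_equal(sig$t_stats[j], o$t, tolerance = 1e-10)
  expect_equal(sig$p_values[j], o$p, tolerance = 1e-10)
  expect_lt(sig$p_values[j], 1e-6)
  expect_error(differential_genes(M, c(rep(1, 19), 2)), "at least two")
})

test_that("gene selection is invariant to swapping the group labels", {
  set.seed(52)
  M <- matrix(rnorm(30 * 12), 30, 12)
  labels <- rep(1:2, each = 6)
  s1 <- differential_genes(M, labels, alpha = 0.1)
  s2 <- differential_genes(M, 3 - labels, alpha = 0.1)
  expect_identical(s1$gene_ids, s2$gene_ids)
  expect_equal(s1$p_values, s2$p_values, tolerance = 1e-12)
})

test_that("signature intersection and filtering behave as set operations", {
  a <- c("g1", "g2", "g3", "g7")
  b <- c("g9", "g3", "g1")
  expect_identical(intersect_signatures(list(a, b)), c("g1", "g3"))
  expect_identical(intersect_signatures(list(a, a)), a)
  expect_length(intersect_signatures(list(a, c("x", "y"))), 0)
  # planted overlap among noise ids
  set.seed(53)
  common <- paste0("core", 1:7)
  s1 <- sample(c(common, paste0("a", 1:40)))
  s2 <- sample(c(common, paste0("b", 1:40)))
  expect_setequal(intersect_signatures(list(s1, s2)), common)
  expect_identical(filter_signature(a, c("g2", "g7", "zz")), c("g2", "g7"))
})

test_that("least-squares classification assigns the nearest centroid", {
  train <- cbind(c(0, 0), c(0, 0), c(10, 10), c(10, 10))
  rownames(train) <- c("gA", "gB")
  labels <- c(1, 1, 2, 2)
  test <- cbind(c(0, 0), c(10, 10), c(5, 5), c(9, 9))
  rownames(test) <- c("gA", "gB")
  pred <- least_squares_classify(train, labels, test)
  expect_equal(as.vector(pred), c(1, 2, 1, 2))   # equidistant -> class 1
  expect_error(least_squares_classify(train, labels, test[2:1, ]),
               "reordered")
  # planted separation recovered perfectly
  inst <- generate_planted(40, 60, 2, 2, matrix(c(8, 0, 0, 0), 2, 2),
                           noise_sd = 0.5, seed = 12)
  tr <- inst$M[, 1:30]; te <- inst$M[, 31:60]
  pred2 <- least_squares_classify(tr, inst$col_truth[1:30], te)
  expect_equal(ari(pred2, inst$col_truth[31:60]), 1)
})

test_that("Kaplan-Meier estimate matches the product-limit formula", {
  # no events: survival stays at 1
  tab <- survival_table(paste0("s", 1:4), c(1, 2, 3, 4), rep(0, 4))
  S <- km_estimate(tab)
  expect_equal(S(c(0, 2.5, 10)), rep(1, 3))
  # two subjects with events at t = 1, 2
  tab2 <- survival_table(c("a", "b"), c(1, 2), c(1, 1))
  S2 <- km_estimate(tab2)
  expect_equal(S2(c(0.5, 1, 1.9, 2, 5)), c(1, 0.5, 0.5, 0, 0))
  # random table against the direct computation at every event time
  set.seed(54)
  tab3 <- survival_table(paste0("p", 1:40), rexp(40, 0.1),
                         rbinom(40, 1, 0.7))
  S3 <- km_estimate(tab3)
  ref <- oracle_km(tab3$time, tab3$event)
  expect_equal(S3(ref$time), ref$surv, tolerance = 1e-12)
  expect_error(survival_table("x", -1, 1), "nonnegative")
})

test_that("log-rank test matches hand accumulation and handles edge cases", {
  # identical survival experience in both groups: O = E exactly
  base <- data.frame(sample_id = paste0("s", 1:6),
                     time = c(2, 4, 6, 8, 10, 12),
                     event = c(1, 0, 1, 1, 0, 1))
  dup <- rbind(base, transform(base, sample_id = paste0("t", 1:6)))
  lr0 <- logrank_test(dup, rep(1:2, each = 6))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-12)
  # tiny hand-computable table
  tab <- survival_table(letters[1:4], c(1, 2, 3, 4), c(1, 1, 1, 1))
  g <- c(1, 1, 2, 2)
  lr <- logrank_test(tab, g)
  o <- oracle_logrank(tab$time, tab$event, g)
  expect_equal(lr$statistic, o$statistic, tolerance = 1e-10)
  expect_equal(lr$p_value, o$p, tolerance = 1e-10)
  # no events at all -> warning, p = 1
  none <- survival_table(letters[1:4], 1:4, rep(0, 4))
  expect_warning(lrn <- logrank_test(none, g), "no events")
  expect_equal(lrn$p_value, 1)
  # truncation horizon censors late events
  late <- survival_table(letters[1:4], c(10, 20, 70, 80), c(1, 1, 1, 1))
  S <- km_estimate(late, horizon = 60)
  expect_equal(S(65), 0.5)
})

test_that("log-rank p-values are close to uniform under the null", {
  set.seed(55)
  p <- replicate(400, {
    tab <- survival_table(paste0("s", 1:30), rexp(30, 0.05),
                          rbinom(30, 1, 0.8))
    logrank_test(tab, rep(1:2, each = 15))$p_value
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})
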