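test_that("one-way ANOVA matches aov and is label-permutation invariant", {
  set.seed(2)
  m <- toy_matrix(20, 12)
  labels <- rep(c("A", "B", "C"), each = 4)
  res <- test_multigroup(m, labels)
  # oracle: stats::aov on a handful of targets
  for (i in c(1, 7, 20)) {
    fit <- summary(stats::aov(m[i, ] ~ factor(labels)))[[1]]
    expect_equal(res$statistic[i], fit[["F value"]][1], tolerance = 1e-10)
    expect_equal(res$p[i], fit[["Pr(>F)"]][1], tolerance = 1e-10)
  }
  relabel <- c(A = "z9", B = "z1", C = "z5")[labels]
  res2 <- test_multigroup(m, relabel)
  expect_equal(res$statistic, res2$statistic)
  expect_equal(res$p, res2$p)
})

test_that("degenerate equal-value targets give F = 0, p = 1", {
  m <- rbind(t1 = rep(3, 8), t2 = rnorm(8))
  colnames(m) <- paste0("s", 1:8)
  res <- test_multigroup(m, rep(c("A", "B"), each = 4))
  expect_equal(res$statistic[1], 0)
  expect_equal(res$p[1], 1)
})

test_that("Welch t matches the textbook formula and t.test", {
  m <- rbind(t1 = c(1, 2, 3, 4, 5, 6))
  colnames(m) <- paste0("s", 1:6)
  labels <- rep(c("g1", "g2"), each = 3)
  res <- test_twogroup(m, labels)
  # hand Welch on (1,2,3) vs (4,5,6): t = 3/sqrt(2/3), df = 4
  expect_equal(res$statistic[1], 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$p[1], 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)
  tt <- t.test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(res$p[1], tt$p.value, tolerance = 1e-12)

  # swapping the two labels flips the sign, not the p-value
  swapped <- test_twogroup(m, rep(c("g2", "g1"), each = 3))
  expect_equal(swapped$statistic[1], -res$statistic[1])
  expect_equal(swapped$p[1], res$p[1])

  ident <- rbind(t1 = rep(c(1, 2), 4))
  colnames(ident) <- paste0("s", 1:8)
  r0 <- test_twogroup(ident, rep(c("a", "b"), each = 4))
  expect_equal(r0$statistic[1], 0)
  expect_equal(r0$p[1], 1)
})

test_that("two-group ANOVA F equals pooled t squared", {
  set.seed(5)
  m <- toy_matrix(15, 10)
  labels <- rep(c("A", "B"), each = 5)
  fa <- test_multigroup(m, labels)
  # pooled two-sample t via lm (equal-variance), squared
  for (i in c(2, 9)) {
    tp <- summary(stats::lm(m[i, ] ~ factor(labels)))$coefficients[2, 3]
    expect_equal(fa$statistic[i], tp^2, tolerance = 1e-10)
  }
})

test_that("Storey q-values reproduce the hand-executed recursion", {
  # lambda = 0.5; p = (.001, .5, .9, .95): #{p > .5} = 2 -> pi0 = 1
  # q4 = .95; q3 = min(.95, .9*4/3) = .95; q2 = min(.95, .5*2) = .95;
  # q1 = min(.95, .001*4) = .004
  out <- estimate_qvalues(c(0.001, 0.5, 0.9, 0.95))
  expect_equal(out$pi0, 1)
  expect_equal(out$q, c(0.004, 0.95, 0.95, 0.95))

  expect_equal(estimate_qvalues(0.05)$q, 0.05)  # single p, pi0 forced to 1

  q <- estimate_qvalues(c(0.01, 0.02, 0.03))$q
  expect_true(all(diff(q) >= 0))

  expect_error(estimate_qvalues(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("q-values are invariant to input order", {
  set.seed(6)
  p <- runif(200)^2
  perm <- sample(200)
  q1 <- estimate_qvalues(p)$q
  q2 <- estimate_qvalues(p[perm])$q
  expect_equal(q1[perm], q2)
})

test_that("null p-values are uniform: type-I rate and pi0 behave", {
  set.seed(77)
  m <- matrix(rnorm(10000 * 12), 10000, 12,
              dimnames = list(sprintf("t%05d", 1:10000), paste0("s", 1:12)))
  res <- test_twogroup(m, rep(c("A", "B"), each = 6))
  rate <- mean(res$p < 0.05)
  expect_gt(rate, 0.04)
  expect_lt(rate, 0.06)
  expect_gte(estimate_qvalues(res$p)$pi0, 0.85)
})

test_that("fold change is the max pairwise ratio of class means", {
  m <- rbind(t1 = c(0, 0, 0.3, 0.3, 1.585, 1.585),
             t2 = rep(1, 6),
             t3 = c(0, 0, 0, 1, 1, 1))
  colnames(m) <- paste0("s", 1:6)
  fc3 <- fold_change(m, rep(c("A", "B", "C"), each = 2))
  expect_equal(fc3$fc[1], 2^1.585, tolerance = 1e-12)  # = 3.0
  expect_equal(fc3$fc[1], 3.0, tolerance = 1e-3)
  expect_equal(fc3$fc[2], 1)

  fc2 <- fold_change(m, rep(c("A", "B"), each = 3))
  expect_equal(fc2$fc[3], 2)  # means 0 vs 1 glog2 unit apart
  expect_identical(fc2$direction[1], "up")
})

test_that("signature selection applies both thresholds and sorts by q", {
  res <- data.frame(target = c("b", "a", "c", "d"),
                    q = c(0.001, 0.001, 0.5, 0.004),
                    fc = c(2.0, 3.0, 4.0, 1.2))
  sel <- select_signature(res, fdr_threshold = 0.02, fc_threshold = 1.5)
  expect_equal(sel$target, c("a", "b"))  # d fails FC, c fails q; ties by id
  expect_equal(nrow(select_signature(res, 1e-6, 1.5)), 0)
})

test_that("planted two-group DE targets are recovered at FDR 2% / FC 1.5", {
  sens <- fdr <- numeric(0)
  for (s in 1:10) {
    pc <- processed_cohort(
      seed = s, class_sizes = c(BL = 14, LN = 11), n_targets = 200,
      n_planted_de = 20, de_offset = 1.25, de_classes = list("BL"),
      beta = 0)
    labels <- pc$sim$metadata$class[
      match(colnames(pc$targets$values), pc$sim$metadata$sample_id)]
    de <- differential_expression(pc$targets, labels)
    sel <- select_signature(de, 0.02, 1.5)
    truth <- pc$sim$truth$planted_de$target
    sens <- c(sens, mean(truth %in% sel$target))
    fdr <- c(fdr, if (nrow(sel)) mean(!sel$target %in% truth) else 0)
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fdr), 0.1)
})

test_that("selection is invariant to sample column order", {
  pc <- processed_cohort(seed = 2, class_sizes = c(BL = 14, LN = 11),
                         n_targets = 100, n_planted_de = 10,
                         de_classes = list("BL"), beta = 0)
  labels <- pc$sim$metadata$class[
    match(colnames(pc$targets$values), pc$sim$metadata$sample_id)]
  de1 <- differential_expression(pc$targets$values, labels)
  perm <- sample(ncol(pc$targets$values))
  de2 <- differential_expression(pc$targets$values[, perm], labels[perm])
  s1 <- select_signature(de1, 0.02, 1.5)
  s2 <- select_signature(de2, 0.02, 1.5)
  expect_equal(s1$target, s2$target)
})

test_that("1 - Pearson clustering: distances and planted blocks", {
  # perfectly correlated pair merges at height 0; anticorrelated at 2
  m <- rbind(s1 = c(1, 2, 3, 4), s2 = c(2, 4, 6, 8), s3 = c(4, 3, 2, 1))
  cl <- hierarchical_cluster(t(m), axis = "samples")
  d <- as.matrix(cl$dist)
  expect_equal(d["s1", "s2"], 0, tolerance = 1e-12)
  expect_equal(d["s1", "s3"], 2, tolerance = 1e-12)
  expect_equal(min(cl$tree$height), 0, tolerance = 1e-12)

  # two planted correlation blocks recovered exactly at k = 2
  set.seed(13)
  shared_a <- rnorm(40); shared_b <- rnorm(40)
  m2 <- cbind(sapply(1:6, function(i) shared_a + rnorm(40, sd = 0.45)),
              sapply(1:6, function(i) shared_b + rnorm(40, sd = 0.45)))
  dimnames(m2) <- list(paste0("f", 1:40), sprintf("s%02d", 1:12))
  cl2 <- hierarchical_cluster(m2, axis = "samples")
  grp <- stats::cutree(cl2$tree, k = 2)
  truth <- rep(1:2, each = 6)
  expect_equal(adjusted_rand(grp, truth), 1)

  expect_error(hierarchical_cluster(rbind(a = c(1, 1, 1), b = c(1, 2, 3)),
                                    "features"), "a")
})
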