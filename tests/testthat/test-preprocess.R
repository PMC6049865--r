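test_that("glog normalization calibrates scale differences away", {
  set.seed(1)
  base <- rexp(60, 1 / 400) + 30
  m <- cbind(s1 = base, s2 = base)
  rownames(m) <- paste0("p", 1:60)
  out <- glog_normalize(expr_matrix(m, "probe", "raw"))
  expect_equal(out$normalized$values[, "s1"], out$normalized$values[, "s2"])

  # pure rescaling (no offset): identical normalized columns
  m2 <- cbind(s1 = base, s2 = 2 * base)
  rownames(m2) <- paste0("p", 1:60)
  out2 <- glog_normalize(expr_matrix(m2, "probe", "raw"), bg_quantile = 0)
  expect_equal(out2$normalized$values[, "s1"],
               out2$normalized$values[, "s2"], tolerance = 1e-6)
})

test_that("glog tends to log2 for large intensities, bounded by c^2/(2 x^2 ln 2)", {
  x <- 1e6; cc <- 1
  y <- log2(x + sqrt(x^2 + cc^2)) - 1
  expect_lt(abs(y - log2(x)), cc^2 / (2 * x^2 * log(2)))
})

test_that("glog normalization preserves ranks within each array", {
  set.seed(4)
  m <- matrix(rexp(500, 1 / 300), 100, 5,
              dimnames = list(paste0("p", 1:100), paste0("s", 1:5)))
  out <- glog_normalize(expr_matrix(m, "probe", "raw"))
  for (j in 1:5)
    expect_identical(order(m[, j]), order(out$normalized$values[, j]))
})

test_that("constant arrays are rejected by name", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(5, 5, 5))
  rownames(m) <- paste0("p", 1:3)
  expect_error(glog_normalize(expr_matrix(m, "probe", "raw")), "s2")
})

test_that("median polish handles the degenerate and additive cases", {
  f1 <- median_polish(matrix(5))
  expect_equal(f1$overall, 5)
  expect_equal(unname(f1$residuals[1, 1]), 0)

  f2 <- median_polish(rbind(c(1, 2), c(3, 4)))
  expect_equal(f2$overall, 2.5)
  expect_true(all(abs(f2$residuals) < 1e-12))
  expect_true(f2$converged)
})

test_that("median polish matches the reference implementation on random matrices", {
  n_converged <- 0
  for (s in 1:25) {
    set.seed(s + 100)
    nr <- sample(2:6, 1); nc <- sample(2:6, 1)
    m <- matrix(rnorm(nr * nc, sd = 5), nr, nc)
    if (s %% 2 == 0) m[sample(length(m), 2)] <- NA
    if (any(rowSums(!is.na(m)) == 0) || any(colSums(!is.na(m)) == 0)) next
    mine <- median_polish(m, max_iter = 200, tol = 1e-12)
    ref <- suppressWarnings(
      stats::medpolish(m, eps = 1e-12, maxiter = 200,
                       trace.iter = FALSE, na.rm = TRUE))
    expect_equal(mine$overall, ref$overall, tolerance = 1e-8)
    expect_equal(unname(mine$row), unname(ref$row), tolerance = 1e-8)
    expect_equal(unname(mine$col), unname(ref$col), tolerance = 1e-8)
    # residual row/col medians vanish whenever a fixed point is reached
    # (even-by-even matrices may stall in a two-cycle and report
    # converged = FALSE)
    if (mine$converged) {
      n_converged <- n_converged + 1
      expect_lt(max(abs(apply(mine$residuals, 1, median, na.rm = TRUE))),
                1e-9)
      expect_lt(max(abs(apply(mine$residuals, 2, median, na.rm = TRUE))),
                1e-9)
    }
  }
  expect_gt(n_converged, 15)
})

test_that("median polish reconstruction identity holds entrywise", {
  for (s in 1:10) {
    set.seed(s)
    m <- matrix(rnorm(30), 5, 6)
    fit <- median_polish(m, max_iter = 100, tol = 1e-10)
    recon <- fit$overall + outer(fit$row, fit$col, "+") + fit$residuals
    expect_lt(max(abs(recon - m)), 1e-9)
  }
})

test_that("median polish rejects all-missing slices", {
  m <- rbind(c(NA, NA), c(1, 2))
  expect_error(median_polish(m), "all-missing")
})

test_that("probe collapse recovers a common profile despite probe offsets", {
  profile <- c(a = 1, b = 5, c = 3, d = 8)
  block <- rbind(p1 = profile - 1, p2 = profile, p3 = profile + 1)
  m <- expr_matrix(block, "probe", "glog2")
  ann <- data.frame(probe_id = c("p1", "p2", "p3"),
                    target_id = rep("t1", 3))
  out <- collapse_probes(m, ann)
  expect_equal(unname(out$values["t1", ]), unname(profile), tolerance = 1e-9)

  # single-probe and identical-probe targets pass through
  m2 <- expr_matrix(rbind(p1 = profile, p2 = profile, p3 = profile * 2),
                    "probe", "glog2")
  ann2 <- data.frame(probe_id = c("p1", "p2", "p3"),
                     target_id = c("t1", "t1", "t2"))
  out2 <- collapse_probes(m2, ann2)
  expect_equal(unname(out2$values["t1", ]), unname(profile))
  expect_equal(unname(out2$values["t2", ]), unname(profile * 2))
})

test_that("probe collapse is invariant to probe order and per-probe shifts", {
  set.seed(8)
  m <- matrix(rnorm(24, 8), 4, 6,
              dimnames = list(paste0("p", 1:4), paste0("s", 1:6)))
  ann <- data.frame(probe_id = paste0("p", 1:4),
                    target_id = c("t1", "t1", "t1", "t2"))
  a <- collapse_probes(expr_matrix(m, "probe", "glog2"), ann)
  perm <- c(3, 1, 4, 2)
  b <- collapse_probes(expr_matrix(m[perm, ], "probe", "glog2"),
                       ann[perm, ])
  expect_equal(a$values, b$values)

  # adding a constant to one probe's whole row can only shift that
  # target's profile by a per-target constant (the median row effect);
  # the profile shape across samples is untouched
  m2 <- m; m2["p2", ] <- m2["p2", ] + 3
  c2 <- collapse_probes(expr_matrix(m2, "probe", "glog2"), ann)
  shift <- c2$values - a$values
  expect_lt(diff(range(shift["t1", ])), 1e-9)
  expect_equal(unname(shift["t2", ]), rep(0, 6))
})

test_that("unannotated probes abort the collapse with their ids", {
  m <- expr_matrix(toy_matrix(3, 4, prefix = "p"), "probe", "glog2")
  ann <- data.frame(probe_id = c("p1", "p2"), target_id = c("t1", "t1"))
  expect_error(collapse_probes(m, ann), "p3")
})

test_that("ddCt relative quantification follows the comparative method", {
  ct <- rbind(
    data.frame(sample_id = "cal", assay_id = c("mir", "RNU44", "U47"),
               ct = c(25, 20, 22)),
    data.frame(sample_id = "s1", assay_id = c("mir", "RNU44", "U47"),
               ct = c(25, 20, 22)),
    data.frame(sample_id = "s2", assay_id = c("mir", "RNU44", "U47"),
               ct = c(24, 20, 22)))
  rq <- qpcr_relative_expression(ct, "mir", calibrator = "cal")
  expect_equal(rq$rq[rq$sample_id == "cal"], 1)
  expect_equal(rq$rq[rq$sample_id == "s1"], 1)   # same dCt as calibrator
  expect_equal(rq$rq[rq$sample_id == "s2"], 2)   # one cycle lower

  # references (20, 22), target 25 vs calibrator dCt 3 -> RQ 2^(-1) = 0.5
  ct2 <- rbind(
    data.frame(sample_id = "cal", assay_id = c("mir", "RNU44", "U47"),
               ct = c(24, 20, 22)),
    data.frame(sample_id = "s", assay_id = c("mir", "RNU44", "U47"),
               ct = c(25, 20, 22)))
  rq2 <- qpcr_relative_expression(ct2, "mir", calibrator = "cal")
  expect_equal(rq2$rq[rq2$sample_id == "s"], 0.5)

  expect_error(
    qpcr_relative_expression(ct[-2, ], "mir", calibrator = "cal"),
    "missing Ct")
})
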