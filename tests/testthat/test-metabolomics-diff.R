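test_that("technical replicate averaging is the arithmetic mean", {
  m <- matrix(c(10, 20, 30, 5, 5, 5), nrow = 1,
              dimnames = list("f1", c("a_t1", "a_t2", "a_t3", "b_t1", "b_t2", "b_t3")))
  map <- c(a_t1 = "a", a_t2 = "a", a_t3 = "a", b_t1 = "b", b_t2 = "b", b_t3 = "b")
  avg <- average_technical_replicates(m, map)
  expect_equal(avg["f1", "a"], 20)
  expect_equal(avg["f1", "b"], 5)
  # singleton passes through; zeros average to zero
  s <- matrix(c(5, 0, 0), nrow = 1, dimnames = list(NULL, c("x_t1", "y_t1", "y_t2")))
  avg2 <- average_technical_replicates(s, c(x_t1 = "x", y_t1 = "y", y_t2 = "y"))
  expect_equal(as.numeric(avg2), c(5, 0))
  expect_error(average_technical_replicates(m, map[-1]), "absent")
})

test_that("feature test is a Welch t-test on log2 intensities", {
  r <- test_feature(c(100, 100, 100), c(100, 100, 100))
  expect_equal(r$p_value, 1)
  expect_equal(r$log2fc, 0)

  # constant but different groups; and undersized groups
  expect_equal(test_feature(c(10, 10, 10), c(80, 80, 80))$p_value, 0)
  expect_true(is.na(test_feature(c(10), c(80, 90, 85))$p_value))
  expect_equal(test_feature(c(10), c(80), pseudo = 1e-12)$log2fc, 3,
               tolerance = 1e-9)

  # exact 8-fold with vanishing pseudo-intensity
  ctrl <- c(120, 80, 100)
  r8 <- test_feature(ctrl, 8 * ctrl, pseudo = 1e-12)
  expect_equal(r8$log2fc, 3, tolerance = 1e-9)

  # matches stats::t.test directly
  set.seed(5)
  a <- rlnorm(4, log(1e5), 0.4); b <- rlnorm(5, log(4e5), 0.4)
  expect_equal(test_feature(a, b)$p_value,
               t.test(log2(b + 1), log2(a + 1))$p.value)
})

test_that("Welch p agrees with permutation oracles", {
  # n = 3 per group: the permutation null has only 20 relabelings, so its
  # two-sided p cannot fall below 0.1 even for complete separation; the
  # exact enumeration value is frozen at 0.1 while Welch goes below 0.01
  ctrl <- c(10, 12, 11); trt <- c(80, 96, 88)
  r <- test_feature(ctrl, trt)
  expect_lt(r$p_value, 0.01)
  expect_equal(perm_test_exact(ctrl, trt), 2 / 20)

  # n = 10 per group: permutation null is rich; Welch and a 10,000-draw
  # permutation p agree closely
  set.seed(11)
  a <- rlnorm(10, log(1e5), 0.3)
  b <- rlnorm(10, log(1.9e5), 0.3)
  r2 <- test_feature(a, b)
  p_perm <- perm_test_oracle(a, b, n_draw = 10000, seed = 2)
  expect_lt(abs(r2$p_value - p_perm), 0.02)
})

test_that("BH adjustment equals brute-force step-up on random vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, brute_bh(p))
    expect_true(all(q >= p - 1e-12))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
})

test_that("signed fold-change maps decreases to negative reciprocals", {
  expect_equal(signed_fold_change(1), 2)
  expect_equal(signed_fold_change(-log2(5)), -5)
  expect_equal(signed_fold_change(0), 1)
  set.seed(3)
  x <- rnorm(100, 0, 3)
  expect_true(all(abs(signed_fold_change(x)) >= 1))
  expect_error(signed_fold_change(Inf), "finite")
})

test_that("retention alignment recovers planted shifts and warps", {
  set.seed(21)
  base <- data.frame(id = sprintf("f%02d", 1:30),
                     mz = sort(runif(30, 100, 900)),
                     rt = runif(30, 0.5, 13),
                     intensity = rlnorm(30, 11, 1))

  # identical runs: identity maps
  al <- align_retention(list(a = base, b = base, c = base))
  for (r in names(al$runs)) expect_equal(al$runs[[r]]$rt, base$rt)

  # constant offset against two reference runs: exact inverse at anchors
  shifted <- base; shifted$rt <- base$rt + 0.2
  al2 <- align_retention(list(a = base, b = base, c = shifted))
  expect_equal(al2$runs$c$rt, base$rt, tolerance = 1e-6)

  # multiplicative warp: anchor spread shrinks
  warped <- base; warped$rt <- base$rt * 1.02
  pre_sd <- mean(abs(warped$rt - base$rt))
  al3 <- align_retention(list(a = base, b = base, c = warped))
  anchors <- al3$anchors
  spread <- tapply(anchors$rt_corrected, anchors$anchor, sd)
  spread_pre <- tapply(anchors$rt, anchors$anchor, sd)
  expect_lt(mean(spread), mean(spread_pre))

  expect_error(align_retention(list(a = base)), "at least 2")
  far <- base; far$mz <- base$mz * 1.5
  expect_error(align_retention(list(a = base, b = far)), "tolerance")
})

test_that("merged runs keep per-run intensities and median coordinates", {
  r1 <- data.frame(id = c("f1", "f2"), mz = c(100, 200), rt = c(1, 2),
                   intensity = c(10, 20))
  r2 <- data.frame(id = c("f1", "f2"), mz = c(100.0002, 200), rt = c(1.1, 2),
                   intensity = c(11, 21))
  m <- merge_runs(list(a = r1, b = r2))
  expect_equal(m$rt[m$id == "f1"], 1.05)
  expect_equal(m$a, c(10, 20))
  expect_equal(m$b, c(11, 21))
})

test_that("differential table has the fixed column order and q >= p", {
  ds <- small_sim(seed = 2)
  av <- averaged_features(ds)
  dt <- diff_features(av$features, av$groups)
  expect_identical(names(dt), c("id", "mz", "rt", "signed_fold_change",
                                "log2fc", "p_value", "q_value", "direction"))
  ok <- !is.na(dt$p_value)
  expect_true(all(dt$q_value[ok] >= dt$p_value[ok] - 1e-12))
  expect_true(all(dt$direction == ifelse(dt$log2fc >= 0, "up", "down")))
  expect_true(all(abs(dt$signed_fold_change) >= 1))
})

test_that("zero-noise simulations return planted fold-changes exactly", {
  cfg <- sim_config(n_compounds = 15, n_genes = 40, intensity_log_sd = 0,
                    mass_error_ppm = 0, seed = 6)
  ds <- simulate_dataset(cfg, synthetic_registry(20, seed = 7))
  av <- averaged_features(ds)
  dt <- diff_features(av$features, av$groups, pseudo = 1e-9)
  tr <- ds$feature_truth
  got <- dt$signed_fold_change[match(tr$id, dt$id)]
  expect_equal(got, signed_fold_change(log2(tr$ratio)), tolerance = 1e-9)
})
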