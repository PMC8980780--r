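test_that("pixel metrics match hand-computable cases", {
  t1 <- matrix(c(1, 1, 0, 0), 2)
  s1 <- matrix(c(0.9, 0.4, 0.6, 0.2), 2)
  pm <- pixel_metrics(s1, t1)
  expect_equal(pm$auc, 0.75)          # 3 of 4 concordant pairs

  perfect <- pixel_metrics(t1, t1) |> suppressWarnings()
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$accuracy, 1)

  const <- pixel_metrics(matrix(0.5, 2, 2), t1)
  expect_equal(const$auc, 0.5)

  allpos <- matrix(1L, 2, 2)
  expect_warning(und <- pixel_metrics(s1, allpos),
                 class = "vesselmetrics_undefined_measure")
  expect_true(is.na(und$auc))
  expect_error(pixel_metrics(s1, matrix(0L, 3, 3)),
               class = "vesselmetrics_shape_error")
})

test_that("rank AUC equals brute-force pair enumeration and F1 its identity", {
  withr::with_seed(7, {
    for (i in 1:20) {
      n <- sample(8:32, 1)
      truth <- matrix(rbinom(n * n, 1, 0.3), n)
      if (sum(truth) == 0 || sum(truth) == n * n) next
      scores <- matrix(pmin(1, pmax(0, truth * 0.4 + runif(n * n))), n)
      pm <- pixel_metrics(scores, truth)
      expect_equal(pm$auc, oracle_auc(scores, truth), tolerance = 1e-12)
      prec <- pm$tp / (pm$tp + pm$fp)
      rec <- pm$tp / (pm$tp + pm$fn)
      expect_equal(pm$f1, 2 * prec * rec / (prec + rec), tolerance = 1e-12)
      expect_equal(pm$accuracy, (pm$tp + pm$tn) / (n * n), tolerance = 1e-12)
    }
  })
})

test_that("metrics are restricted to the field of view", {
  truth <- matrix(0L, 10, 10); truth[5, 3:8] <- 1L
  scores <- matrix(0, 10, 10); scores[5, 3:8] <- 0.9
  fov <- matrix(0L, 10, 10); fov[3:8, 1:10] <- 1L
  inside <- pixel_metrics(scores, truth, fov) |> suppressWarnings()
  everywhere <- pixel_metrics(scores, truth) |> suppressWarnings()
  expect_identical(inside$tn + inside$tp + inside$fp + inside$fn, sum(fov))
  expect_gt(everywhere$tn, inside$tn)
})

test_that("ICC(A,1) reproduces an independent reference and its bands", {
  # fixture frozen against an external two-way random-effects implementation
  x1 <- c(20.9802, 18.0073, 22.7189, 21.9624, 14.5156, 15.1346, 21.2620,
          19.0013, 19.7647, 16.7599, 23.8607, 22.1788)
  x2 <- c(20.9858, 17.0279, 23.2837, 23.6871, 15.0596, 17.0243, 23.0252,
          19.1449, 19.9374, 17.1271, 23.7542, 23.9623)
  r <- icc_agreement(cbind(x1, x2))
  expect_equal(r$icc, 0.938993, tolerance = 1e-6)
  expect_equal(round(r$ci_low, 2), 0.73)
  expect_equal(round(r$ci_high, 2), 0.98)
  expect_identical(r$band, "excellent")

  ident <- icc_agreement(cbind(1:10, 1:10))
  expect_equal(ident$icc, 1)
  expect_identical(ident$band, "excellent")

  withr::with_seed(3, {
    noise <- cbind(rnorm(40), rnorm(40))
  })
  rn <- icc_agreement(noise)
  expect_lt(abs(rn$icc), 0.35)
  expect_true(rn$ci_low < 0 && rn$ci_high > rn$icc)
  expect_identical(rn$band, "poor")

  expect_identical(icc_band(c(0.3, 0.6, 0.8, 0.95)),
                   c("poor", "moderate", "good", "excellent"))
  expect_error(icc_agreement(cbind(1:2, 2:3)),
               class = "vesselmetrics_contract_error")
})

test_that("ICC recovers a known variance ratio in simulation", {
  withr::with_seed(11, {
    n <- 200
    s2_subj <- 4; s2_rater <- 0.5; s2_err <- 1
    subj <- rnorm(n, 0, sqrt(s2_subj))
    rater <- rnorm(2, 0, sqrt(s2_rater))
    x <- cbind(subj + rater[1] + rnorm(n, 0, sqrt(s2_err)),
               subj + rater[2] + rnorm(n, 0, sqrt(s2_err)))
  })
  r <- icc_agreement(x)
  target <- s2_subj / (s2_subj + s2_rater + s2_err)
  expect_gt(target, r$ci_low)
  expect_lt(target, r$ci_high)
})

test_that("Bland-Altman limits are mean +/- 1.96 sample SD", {
  ident <- bland_altman(cbind(1:5, 1:5))
  expect_equal(ident$mean_diff, 0)
  expect_equal(ident$loa_lower, 0)
  expect_equal(ident$loa_upper, 0)

  ba <- bland_altman(cbind(c(10, 20), c(12, 18)))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$loa_upper, 1.96 * sd(c(-2, 2)), tolerance = 1e-12)
  expect_equal(ba$loa_upper, 5.5437, tolerance = 1e-4)

  off <- bland_altman(cbind(c(4, 7, 9) + 3, c(4, 7, 9)))
  expect_equal(off$mean_diff, 3)
  expect_equal(off$loa_upper - off$loa_lower, 0)

  expect_error(bland_altman(cbind(1:4, 1:4, 1:4)),
               class = "vesselmetrics_contract_error")
  p <- autoplot(bland_altman(cbind(rnorm(10), rnorm(10))))
  expect_s3_class(p, "ggplot")
})
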