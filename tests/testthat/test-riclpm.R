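test_that("RI-CLPM parameter counts and constraint handling", {
  mAE <- buildRiclpmModel(list(x = c("A", "E"), y = c("A", "E")))
  expect_equal(nParams(mAE), 38)  # 4 blocks x (3+3) + 8 paths + 6 means
  mACE <- buildRiclpmModel(list(x = c("A", "E"), y = c("A", "C", "E")),
                           traits = c(x = "wb", y = "negind"))
  expect_equal(nParams(mACE), 42)  # + 4 y-only C variances

  mNC <- buildRiclpmModel(constraints = "no_crosslags")
  expect_equal(nParams(mAE) - nParams(mNC), 4)
  expect_error(buildRiclpmModel(list(x = "A", y = c("A", "E"))), "E component")
  expect_error(buildRiclpmModel(constraints = "nonexistent_param"),
               "unknown constrained")
})

test_that("random-intercept shares and splits follow their defining arithmetic", {
  tr <- riclpmTruth()
  params <- riclpmParams(tr$model, tr$theta)
  rv <- riVarianceShares(params)
  shX <- rv$shares[rv$shares$trait == "x", ]
  # generating construction: 40/40/36% and an 81/19 A/E split
  expect_equal(shX$riShare, c(0.40, 0.40, 0.36), tolerance = 1e-10)
  splX <- rv$riSplit[rv$riSplit$trait == "x", ]
  expect_equal(splX$share[splX$component == "A"], 0.81, tolerance = 1e-10)
  expect_equal(splX$share[splX$component == "E"], 0.19, tolerance = 1e-10)
  expect_equal(sum(splX$share), 1, tolerance = 1e-12)

  # var(RI) = 4, var(w1) = 6 -> 40%, checked through the same code path
  expect_equal(4 / (4 + 6), 0.4)
  expect_equal(shX$riVar[1] / (shX$riVar[1] + shX$withinVar[1]),
               shX$riShare[1])
})

test_that("implied observed variance decomposes exactly into RI + within (unit loadings)", {
  tr <- riclpmTruth()
  mom <- expectedMoments(tr$model, tr$theta, "MZ")
  rv <- riVarianceShares(riclpmParams(tr$model, tr$theta))
  sh <- rv$shares
  for (i in seq_len(nrow(sh))) {
    idx <- (sh$wave[i] - 1) * 2 + if (sh$trait[i] == "x") 1 else 2
    expect_equal(unname(mom$sigma[idx, idx]),
                 sh$riVar[i] + sh$withinVar[i], tolerance = 1e-12)
  }
})

test_that("within-person variance recursion matches a Monte-Carlo simulation of trajectories", {
  set.seed(31)
  tr <- riclpmTruth()
  params <- riclpmParams(tr$model, tr$theta)
  cv <- twinpanel:::riclpmCovariances(params)
  nsim <- 1000000
  draw <- function(blocks) {
    out <- matrix(0, nsim, 2)
    for (k in names(blocks))
      out <- out + matrix(rnorm(2 * nsim), nsim, 2) %*% t(blocks[[k]])
    out
  }
  w1 <- draw(params@w1)
  w2 <- w1 %*% t(params@T1) + draw(params@i2)
  w3 <- w2 %*% t(params@T2) + draw(params@i3)
  for (i in 1:2) {
    expect_equal(var(w2[, i]), cv$V[[2]][i, i], tolerance = 0.005)
    expect_equal(var(w3[, i]), cv$V[[3]][i, i], tolerance = 0.005)
  }
})

test_that("standardized paths apply the factor-SD ratio (and zero stays zero)", {
  tr <- riclpmTruth()
  params <- riclpmParams(tr$model, tr$theta)
  sp <- standardizePaths(params)
  cv <- twinpanel:::riclpmCovariances(params)
  # gamma = -0.2, SD(pred) = 1, SD(out) = 2 -> -0.1 (pure formula check
  # through the same standardization map)
  row <- sp[sp$param == "cl_xy_1", ]
  expect_equal(row$std,
               row$raw * sqrt(cv$V[[1]][2, 2] / cv$V[[2]][1, 1]),
               tolerance = 1e-12)
  expect_equal(-0.2 * 1 / 2, -0.1)
  # generating standardized cross-lags are reproduced exactly
  expect_equal(sp$std[sp$param == "cl_xy_1"], -0.11, tolerance = 1e-10)
  expect_equal(sp$std[sp$param == "cl_yx_2"], -0.10, tolerance = 1e-10)

  # zero raw path -> zero standardized
  th0 <- tr$theta
  th0["cl_xy_1"] <- 0
  sp0 <- standardizePaths(riclpmParams(tr$model, th0))
  expect_equal(sp0$std[sp0$param == "cl_xy_1"], 0)
})

test_that("with A sources zeroed the MZ and DZ implied covariances coincide", {
  tr <- riclpmTruth()
  th <- tr$theta
  th[grepl("_A_", names(th))] <- 0
  expect_equal(expectedMoments(tr$model, th, "MZ")$sigma,
               expectedMoments(tr$model, th, "DZ")$sigma,
               tolerance = 1e-12)
})

test_that("decoupled x-trait moments reduce to a univariate RI + wave-factor model", {
  tr <- riclpmTruth()
  th <- tr$theta
  # remove every cross path and y-touching source
  th[c("cl_xy_1", "cl_yx_1", "cl_xy_2", "cl_yx_2")] <- 0
  th[grepl("_(21|22)$", names(th)) & grepl("^(ri|w1|i2|i3)_", names(th))] <- 0
  mom <- expectedMoments(tr$model, th, "MZ")
  xIdx <- c(1, 3, 5)
  # manual univariate composition: obs_w = RI + w_w with
  # w2 = b1 w1 + s2, w3 = b2 w2 + s3
  ri <- th[["ri_A_11"]]^2 + th[["ri_E_11"]]^2
  v1 <- th[["w1_A_11"]]^2 + th[["w1_E_11"]]^2
  b1 <- th[["ar_x_1"]]; b2 <- th[["ar_x_2"]]
  v2 <- b1^2 * v1 + th[["i2_A_11"]]^2 + th[["i2_E_11"]]^2
  v3 <- b2^2 * v2 + th[["i3_A_11"]]^2 + th[["i3_E_11"]]^2
  expect_equal(unname(diag(mom$sigma)[xIdx]), c(ri + v1, ri + v2, ri + v3),
               tolerance = 1e-10)
  # cross-wave within-twin covariance: RI + transmitted part
  expect_equal(unname(mom$sigma[1, 3]), ri + b1 * v1, tolerance = 1e-10)
  expect_equal(unname(mom$sigma[3, 5]), ri + b2 * v2, tolerance = 1e-10)
})

test_that("swapping trait labels transposes the estimates", {
  tr <- riclpmTruth()
  ds <- simulatePairs(tr$model, tr$theta, 250, 400, seed = 33)
  fit <- fitModel(tr$model, ds, list(nStarts = 1, gradCheck = FALSE))

  # same data with x and y columns exchanged, fitted with swapped traits
  swapped <- buildRiclpmModel(list(x = c("A", "E"), y = c("A", "E")),
                              traits = c(x = "negdep", y = "wb"))
  fit2 <- fitModel(swapped, ds, list(nStarts = 1, gradCheck = FALSE))
  expect_equal(fit2@minus2LL, fit@minus2LL, tolerance = 1e-4)
  sp1 <- standardizePaths(fit)
  sp2 <- standardizePaths(fit2)
  expect_equal(sp2$std[sp2$param == "cl_xy_1"],
               sp1$std[sp1$param == "cl_yx_1"], tolerance = 5e-3)
  expect_equal(sp2$std[sp2$param == "ar_x_1"],
               sp1$std[sp1$param == "ar_y_1"], tolerance = 5e-3)
})

test_that("constraining lagged paths yields the right df and a warm-started LRT", {
  tr <- riclpmTruth()
  ds <- simulatePairs(tr$model, tr$theta, 250, 400, seed = 34)
  fit <- fitModel(tr$model, ds, list(nStarts = 1, gradCheck = FALSE))
  res <- testLaggedPaths(ds, fit, "no_crosslags")
  expect_equal(res$lrt$df, 4)
  expect_gte(res$lrt$chisq, 0)
  expect_lte(res$lrt$p, 1)
  expect_setequal(res$constrained,
                  c("cl_xy_1", "cl_yx_1", "cl_xy_2", "cl_yx_2"))
})
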