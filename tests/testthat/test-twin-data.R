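test_that("CSV reader validates, maps schema, and round-trips the writer", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("fam,zyg,wb1_t1,wb1_t2",
               "f1,mono,7,8",
               "f2,di,5,6"), f)
  ds <- readTwinTable(f, schema = c(family_id = "fam", zygosity = "zyg"),
                      zygosityCodes = c(MZ = "mono", DZ = "di"))
  expect_equal(nPairs(ds), 2)
  expect_equal(zygosity(ds), c("MZ", "DZ"))
  expect_false(anyNA(pairData(ds)[, c("wb1_t1", "wb1_t2")]))

  writeLines(c("family_id,zygosity,wb1_t1,wb1_t2", "f1,MZ,11,5"), f)
  expect_error(readTwinTable(f), "wb1_t1.*row 1")

  writeLines(c("family_id,zygosity,wb1_t1,wb1_t2", "f1,XX,5,5"), f)
  expect_error(readTwinTable(f), "unknown zygosity")

  # simulator output -> write -> read equals the simulated dataset
  tr <- choleskyTruth()
  sim <- simulatePairs(tr$model, tr$theta, 20, 30, seed = 5)
  out <- tempfile(fileext = ".csv")
  writeTwinTable(sim, out)
  back <- readTwinTable(out, checkRanges = FALSE)
  expect_equal(back@pairs[, names(sim@pairs)], sim@pairs,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("phenotypic correlations match the Pearson formula and are a symmetric unit-diagonal set", {
  set.seed(1)
  n <- 10
  x <- matrix(rnorm(2 * n), n, 2)
  y <- 0.5 * x + matrix(rnorm(2 * n, sd = 0.8), n, 2)
  ds <- pairsDataset(rep(c("MZ", "DZ"), each = n / 2), wb1 = x, negdep1 = y)
  rep <- phenotypicCorrelations(ds, c("wb1", "negdep1"))

  # direct Pearson formula on the 20 stacked individuals
  xs <- c(x); ys <- c(y)
  rOracle <- (sum(xs * ys) - length(xs) * mean(xs) * mean(ys)) /
    ((length(xs) - 1) * sd(xs) * sd(ys))
  got <- rep$r[rep$var1 == "wb1" & rep$var2 == "negdep1"]
  expect_equal(got, rOracle, tolerance = 1e-12)
  expect_equal(rep$n[rep$var1 == "wb1" & rep$var2 == "negdep1"], 20L)

  # identity and exact negation
  expect_equal(rep$r[rep$var1 == "wb1" & rep$var2 == "wb1"], 1)
  ds2 <- pairsDataset(rep("MZ", n), wb1 = x, negdep1 = -x)
  rep2 <- phenotypicCorrelations(ds2, c("wb1", "negdep1"))
  expect_equal(rep2$r[rep2$var1 == "wb1" & rep2$var2 == "negdep1"], -1)

  # symmetry of the full set
  M <- matrix(rep$r, 2, 2)
  expect_equal(M, t(M))

  # fewer than 3 complete pairs -> undefined
  x3 <- x; x3[3:n, 2] <- NA
  ds3 <- pairsDataset(rep("MZ", n), wb1 = cbind(x3[, 1], rep(NA, n)),
                      negdep1 = cbind(x3[, 2], rep(NA, n)))
  rep3 <- phenotypicCorrelations(ds3, c("wb1", "negdep1"))
  expect_true(is.na(rep3$r[rep3$var1 == "wb1" & rep3$var2 == "negdep1"]))
})

test_that("twin correlations: estimates, Fisher-z CI closed form, and double-entry swap invariance", {
  # identical co-twins -> r = 1
  v <- rnorm(20)
  ds <- pairsDataset(rep(c("MZ", "DZ"), each = 10), wb1 = cbind(v, v))
  tc <- twinCorrelations(ds, "wb1")
  expect_equal(tc$r, c(1, 1))

  # exact r = 0 at n = 100 pairs: CI half-width tanh(1.96 / sqrt(97))
  set.seed(2)
  x <- rnorm(100)
  y <- residuals(lm(rnorm(100) ~ x))
  y <- y / sd(y) * sd(x)
  ds0 <- pairsDataset(rep("MZ", 100), wb1 = cbind(x, y))
  tc0 <- twinCorrelations(ds0, "wb1")
  expect_equal(tc0$r[1], 0, tolerance = 1e-12)
  hw <- tanh(qnorm(0.975) / sqrt(97))
  expect_equal(tc0$lower[1], -hw, tolerance = 1e-10)
  expect_equal(tc0$upper[1], hw, tolerance = 1e-10)
  expect_equal(hw, 0.196, tolerance = 0.005)

  # profile CI brackets the estimate and is close to Fisher at this n
  tcp <- twinCorrelations(ds0, "wb1", ciMethod = "profile")
  expect_lt(tcp$lower[1], tc0$r[1])
  expect_gt(tcp$upper[1], tc0$r[1])
  expect_equal(tcp$lower[1], tc0$lower[1], tolerance = 0.03)

  # swapping twin labels: exactly invariant under double entry
  set.seed(3)
  a <- matrix(rnorm(60), 30, 2)
  swap <- a[, 2:1]
  swap[1:15, ] <- a[1:15, ]
  d1 <- pairsDataset(rep("MZ", 30), wb1 = a)
  d2 <- pairsDataset(rep("MZ", 30), wb1 = swap)
  expect_equal(twinCorrelations(d1, "wb1", doubleEntry = TRUE)$r[1],
               twinCorrelations(d2, "wb1", doubleEntry = TRUE)$r[1],
               tolerance = 1e-12)
})

test_that("twin correlation of simulated AE data matches the model-implied cross-twin correlation", {
  tr <- choleskyTruth()
  ds <- simulatePairs(tr$model, tr$theta, 20000, 0, seed = 11)
  mom <- expectedMoments(tr$model, tr$theta, "MZ")
  implied <- mom$sigma["wb1_t1", "wb1_t2"] /
    sqrt(mom$sigma["wb1_t1", "wb1_t1"] * mom$sigma["wb1_t2", "wb1_t2"])
  tc <- twinCorrelations(ds, "wb1")
  expect_equal(tc$r[1], implied, tolerance = 0.02)
})

test_that("age residualization matches OLS, is idempotent, and propagates missing age", {
  set.seed(4)
  n <- 15
  age <- matrix(15 + rnorm(2 * n, sd = 1.5), n, 2)
  y <- 0.3 * age + matrix(rnorm(2 * n), n, 2)
  d <- data.frame(family_id = paste0("f", 1:n), zygosity = "MZ",
                  wb1_t1 = y[, 1], wb1_t2 = y[, 2],
                  age1_t1 = age[, 1], age1_t2 = age[, 2])
  ds <- TwinDataset(d)
  out <- residualizeOnAge(ds, "wb")

  # explicit normal-equations solve on the 30 stacked individuals
  ys <- c(y); as <- c(age)
  X <- cbind(1, as)
  beta <- solve(t(X) %*% X, t(X) %*% ys)
  expect_equal(c(pairData(out)$wb1_t1, pairData(out)$wb1_t2),
               as.vector(ys - X %*% beta), tolerance = 1e-10)

  # idempotent
  out2 <- residualizeOnAge(out, "wb")
  expect_equal(pairData(out2)$wb1_t1, pairData(out)$wb1_t1,
               tolerance = 1e-10)

  # y exactly linear in age -> all residuals zero
  d2 <- d
  d2$wb1_t1 <- 2 * d$age1_t1; d2$wb1_t2 <- 2 * d$age1_t2
  out3 <- residualizeOnAge(TwinDataset(d2), "wb")
  expect_equal(max(abs(c(pairData(out3)$wb1_t1, pairData(out3)$wb1_t2))), 0,
               tolerance = 1e-10)

  # missing age -> missing residual; other cells untouched
  d4 <- d; d4$age1_t1[1] <- NA
  out4 <- residualizeOnAge(TwinDataset(d4), "wb")
  expect_true(is.na(pairData(out4)$wb1_t1[1]))
  expect_false(anyNA(pairData(out4)$wb1_t2))

  # constant age -> mean-centering with a warning
  d5 <- d; d5$age1_t1 <- 16; d5$age1_t2 <- 16
  expect_warning(out5 <- residualizeOnAge(TwinDataset(d5), "wb"),
                 "constant")
  expect_equal(mean(c(pairData(out5)$wb1_t1, pairData(out5)$wb1_t2)), 0,
               tolerance = 1e-10)
})

test_that("event-category screening applies the negligible-and-nonsignificant rule", {
  mk <- function(r, p) {
    do.call(rbind, lapply(1:3, function(w)
      data.frame(var1 = paste0("posdep", w), var2 = paste0("wb", w),
                 r = r[w], n = 500, p = p[w], significant = p[w] < 0.05)))
  }
  dec <- screenEventCategory(mk(c(0, 0, 0), c(1, 1, 1)), "posdep")
  expect_false(dec$include)
  dec2 <- screenEventCategory(mk(c(-0.30, 0.02, 0.01), c(1e-4, 0.9, 0.9)),
                              "posdep")
  expect_true(dec2$include)
  expect_error(screenEventCategory(mk(c(0, 0, 0), c(1, 1, 1)), "negdep"),
               "not found")
})

test_that("screening under a true-null cross-trait correlation excludes in at least 90% of replicates", {
  set.seed(20)
  n <- 1000  # pairs -> 2000 individuals
  excl <- vapply(1:60, function(i) {
    ds <- pairsDataset(rep(c("MZ", "DZ"), each = n / 2),
                       wb1 = matrix(rnorm(2 * n), n, 2),
                       wb2 = matrix(rnorm(2 * n), n, 2),
                       wb3 = matrix(rnorm(2 * n), n, 2),
                       posdep1 = matrix(rnorm(2 * n), n, 2),
                       posdep2 = matrix(rnorm(2 * n), n, 2),
                       posdep3 = matrix(rnorm(2 * n), n, 2))
    rep <- phenotypicCorrelations(ds)
    !screenEventCategory(rep, "posdep")$include
  }, TRUE)
  expect_gte(mean(excl), 0.9)
})
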