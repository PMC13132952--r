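# small inline models and fixtures used across test files

# univariate twin model: one phenotype, paths (a, e) and a mean
makeUnivariateAEModel <- function() {
  new("SourceLoadingModel", name = "uni_AE", variables = "wb1",
      paramNames = c("a", "e", "mu"), lower = c(0, 0, -Inf),
      upper = rep(Inf, 3),
      loadings = function(theta)
        list(A = matrix(theta[1]), E = matrix(theta[2])),
      means = function(theta) theta[3],
      startFun = function(ds) {
        v <- var(c(ds@pairs$wb1_t1, ds@pairs$wb1_t2), na.rm = TRUE)
        c(sqrt(v / 2), sqrt(v / 2),
          mean(c(ds@pairs$wb1_t1, ds@pairs$wb1_t2), na.rm = TRUE))
      },
      meta = list(kind = "test"))
}

# univariate model with unit E loading fixed: only the mean is free,
# so the observed variance is known (=1) and SE(mu) has a closed form
makeKnownVarMeanModel <- function() {
  new("SourceLoadingModel", name = "uni_mean", variables = "wb1",
      paramNames = "mu", lower = -Inf, upper = Inf,
      loadings = function(theta) list(E = matrix(1)),
      means = function(theta) theta[1],
      startFun = function(ds)
        mean(c(ds@pairs$wb1_t1, ds@pairs$wb1_t2), na.rm = TRUE),
      meta = list(kind = "test"))
}

# bivariate AE model with an optional zero constraint on the genetic
# cross path a21; the free a21 is sign-unconstrained, so the LRT of
# a21 = 0 has a regular chi-square(1) reference
makeBivariateAEModel <- function(fixA21 = FALSE) {
  pn <- c("a11", if (!fixA21) "a21", "a22",
          "e11", "e21", "e22", "mu1", "mu2")
  lower <- setNames(rep(-Inf, length(pn)), pn)
  lower[c("a11", "a22", "e11", "e22")] <- 0
  tri <- function(v11, v21, v22) rbind(c(v11, 0), c(v21, v22))
  new("SourceLoadingModel", name = "biv_AE",
      variables = c("wb1", "wb2"), paramNames = pn,
      lower = unname(lower), upper = rep(Inf, length(pn)),
      loadings = function(theta) {
        th <- setNames(theta, pn)
        list(A = tri(th[["a11"]], if (fixA21) 0 else th[["a21"]],
                     th[["a22"]]),
             E = tri(th[["e11"]], th[["e21"]], th[["e22"]]))
      },
      means = function(theta) setNames(theta, pn)[c("mu1", "mu2")],
      startFun = function(ds) {
        st <- setNames(numeric(length(pn)), pn)
        for (v in c("wb1", "wb2")) {
          x <- c(ds@pairs[[paste0(v, "_t1")]], ds@pairs[[paste0(v, "_t2")]])
          i <- if (v == "wb1") "11" else "22"
          st[paste0(c("a", "e"), i)] <- sqrt(var(x, na.rm = TRUE) / 2)
          st[paste0("mu", substr(i, 1, 1))] <- mean(x, na.rm = TRUE)
        }
        unname(st)
      },
      meta = list(kind = "test"))
}

# naive row-by-row FIML -2lnL, the reference for the pattern-grouped path
naiveMinus2LL <- function(model, theta, ds) {
  total <- 0
  for (g in c("MZ", "DZ")) {
    mom <- expectedMoments(model, theta, g)
    cols <- c(paste0(model@variables, "_t1"), paste0(model@variables, "_t2"))
    X <- as.matrix(ds@pairs[ds@pairs$zygosity == g, cols, drop = FALSE])
    for (i in seq_len(nrow(X))) {
      o <- which(!is.na(X[i, ]))
      if (!length(o)) next
      S <- mom$sigma[o, o, drop = FALSE]
      d <- X[i, o] - mom$mu[o]
      total <- total + length(o) * log(2 * pi) +
        as.numeric(determinant(S)$modulus) + drop(d %*% solve(S, d))
    }
  }
  total
}

# quick twin dataset from explicit per-variable pair matrices
pairsDataset <- function(zyg, ...) {
  vars <- list(...)
  d <- data.frame(family_id = paste0("f", seq_along(zyg)), zygosity = zyg)
  for (v in names(vars)) {
    d[[paste0(v, "_t1")]] <- vars[[v]][, 1]
    d[[paste0(v, "_t2")]] <- vars[[v]][, 2]
  }
  TwinDataset(d)
}
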