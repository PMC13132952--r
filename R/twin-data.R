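## Reading/writing wide twin tables, descriptive correlations,
## age residualization, and event-category screening.

#' Read a wide twin-pair table from CSV
#'
#' Expects one row per twin pair. Column names can be remapped through
#' \code{schema}; zygosity codes through \code{zygosityCodes}. Values are
#' range-checked against the instrument bounds (wellbeing 1-10, event
#' counts 0-14 / 0-19 / 0-5) unless \code{checkRanges = FALSE}, which is
#' appropriate for continuous simulated scores.
#'
#' @param file path to a CSV file (UTF-8, header row required).
#' @param schema optional named character vector mapping canonical column
#'   names (names) to file column names (values).
#' @param zygosityCodes named character vector mapping \code{MZ}/\code{DZ}
#'   to the codes used in the file.
#' @param naCodes strings treated as missing.
#' @param checkRanges logical; validate measure ranges (error listing the
#'   offending cells).
#' @return A \linkS4class{TwinDataset}.
#' @export
readTwinTable <- function(file, schema = NULL,
                          zygosityCodes = c(MZ = "MZ", DZ = "DZ"),
                          naCodes = c("", "NA"), checkRanges = TRUE) {
  raw <- read.csv(file, stringsAsFactors = FALSE, na.strings = naCodes,
                  check.names = FALSE)
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      src <- schema[[canonical]]
      if (!src %in% names(raw))
        stop(sprintf("schema column '%s' (for '%s') not found", src,
                     canonical))
      names(raw)[names(raw) == src] <- canonical
    }
  }
  if (!all(c("family_id", "zygosity") %in% names(raw)))
    stop("input must provide 'family_id' and 'zygosity' columns (via schema if needed)")
  zy <- as.character(raw$zygosity)
  known <- zy %in% zygosityCodes
  if (any(!known & !is.na(zy)))
    stop(sprintf("unknown zygosity code(s): %s",
                 paste(unique(zy[!known & !is.na(zy)]), collapse = ", ")))
  if (anyNA(zy)) stop("zygosity missing for some rows")
  raw$zygosity <- names(zygosityCodes)[match(zy, zygosityCodes)]
  if (checkRanges) {
    bad <- character()
    for (m in TWIN_MEASURES) for (w in TWIN_WAVES) for (t in 1:2) {
      col <- twinCol(paste0(m, w), t)
      if (!col %in% names(raw)) next
      v <- raw[[col]]
      b <- MEASURE_BOUNDS[[m]]
      out <- which(!is.na(v) & (v < b[1] | v > b[2]))
      if (length(out))
        bad <- c(bad, sprintf("%s row %d (value %s, allowed [%g, %g])",
                              col, out, v[out], b[1], b[2]))
    }
    if (length(bad))
      stop("out-of-range values:\n  ", paste(bad, collapse = "\n  "))
  }
  TwinDataset(raw)
}

#' Write a TwinDataset to CSV
#'
#' Emits the same wide dialect \code{\link{readTwinTable}} reads, so a
#' write/read round trip reproduces the dataset field by field.
#'
#' @param ds a TwinDataset.
#' @param file output path.
#' @export
writeTwinTable <- function(ds, file) {
  stopifnot(is(ds, "TwinDataset"))
  write.csv(ds@pairs, file, row.names = FALSE, na = "")
  invisible(file)
}

## stack twins as individuals: one row per twin, columns = measure-wave
## variables (+ per-wave age if present)
individualTable <- function(ds, variables = NULL) {
  p <- ds@pairs
  variables <- variables %||% ds@variables
  out <- lapply(1:2, function(t) {
    d <- data.frame(family_id = p$family_id, zygosity = p$zygosity,
                    twin = t)
    for (v in variables) d[[v]] <- p[[twinCol(v, t)]]
    for (w in TWIN_WAVES) {
      ac <- twinCol(paste0("age", w), t)
      if (ac %in% names(p)) d[[paste0("age", w)]] <- p[[ac]]
    }
    d
  })
  rbind(out[[1]], out[[2]])
}

#' Pairwise Pearson correlations between study variables
#'
#' Twins enter as individual observations; correlations use
#' pairwise-complete deletion, with two-sided p-values from the t
#' transform. Family clustering is not corrected for, so p-values are
#' anti-conservative for cross-twin dependent data; the report is meant
#' for descriptive screening of correlation magnitudes.
#'
#' @param ds a TwinDataset.
#' @param variables measure-wave variable names (default: all present).
#' @param alpha significance level used for the \code{significant} flag.
#' @return data.frame with columns \code{var1}, \code{var2}, \code{r},
#'   \code{n}, \code{p}, \code{significant} (a full symmetric set,
#'   including the unit diagonal).
#' @export
phenotypicCorrelations <- function(ds, variables = NULL, alpha = 0.05) {
  variables <- variables %||% ds@variables
  X <- as.matrix(individualTable(ds, variables)[, variables, drop = FALSE])
  k <- ncol(X)
  out <- expand.grid(var1 = variables, var2 = variables,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$r <- NA_real_; out$n <- NA_integer_; out$p <- NA_real_
  for (i in seq_len(k)) for (j in seq_len(k)) {
    x <- X[, i]; y <- X[, j]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    row <- (j - 1L) * k + i
    out$n[row] <- n
    if (n < 3) next
    r <- cor(x[ok], y[ok])
    out$r[row] <- r
    if (i == j || abs(r) >= 1) {
      out$p[row] <- if (i == j) NA_real_ else 0
    } else {
      tval <- r * sqrt((n - 2) / (1 - r^2))
      out$p[row] <- 2 * pt(-abs(tval), df = n - 2)
    }
  }
  out$significant <- !is.na(out$p) & out$p < alpha
  attr(out, "alpha") <- alpha
  out
}

## profile-likelihood CI for a bivariate-normal correlation:
## -2lnL profiled over means/SDs, boundary at qchisq(level, 1)
profileCorCI <- function(x, y, level) {
  n <- length(x)
  negLL <- function(r, mus) {
    m1 <- mus[1]; m2 <- mus[2]; s1 <- exp(mus[3]); s2 <- exp(mus[4])
    z1 <- (x - m1) / s1; z2 <- (y - m2) / s2
    q <- (z1^2 - 2 * r * z1 * z2 + z2^2) / (1 - r^2)
    n * log(2 * pi) + n * log(s1 * s2) + n * 0.5 * log(1 - r^2) + 0.5 * sum(q)
  }
  prof <- function(r) {
    st <- c(mean(x), mean(y), log(sd(x)), log(sd(y)))
    2 * optim(st, function(p) negLL(r, p), method = "BFGS")$value
  }
  rhat <- cor(x, y)
  m0 <- prof(rhat)
  crit <- stats::qchisq(level, 1)
  bound <- function(lo) {
    f <- function(r) prof(r) - m0 - crit
    ends <- if (lo) c(-0.9999, rhat) else c(rhat, 0.9999)
    if (f(ends[if (lo) 1 else 2]) < 0) return(if (lo) -1 else 1)
    stats::uniroot(f, ends, tol = 1e-6)$root
  }
  c(bound(TRUE), bound(FALSE))
}

#' Within-pair twin correlations by zygosity
#'
#' Pearson correlation between co-twins on one variable, separately for MZ
#' and DZ pairs, with confidence intervals via the Fisher z transform
#' (default) or a bivariate-normal profile likelihood.
#'
#' @param ds a TwinDataset.
#' @param variable measure-wave name, e.g. \code{"wb1"}.
#' @param ciLevel confidence level.
#' @param doubleEntry logical; if TRUE each pair enters twice with twins
#'   swapped (r then exactly invariant to twin labelling; the CI still uses
#'   the number of distinct pairs).
#' @param ciMethod \code{"fisher"} or \code{"profile"}.
#' @return data.frame with rows MZ and DZ: \code{r}, \code{n} (complete
#'   pairs), \code{lower}, \code{upper}.
#' @export
twinCorrelations <- function(ds, variable, ciLevel = 0.95,
                             doubleEntry = FALSE,
                             ciMethod = c("fisher", "profile")) {
  ciMethod <- match.arg(ciMethod)
  p <- ds@pairs
  res <- lapply(c("MZ", "DZ"), function(z) {
    sel <- p$zygosity == z
    x <- p[[twinCol(variable, 1)]][sel]
    y <- p[[twinCol(variable, 2)]][sel]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3)
      return(data.frame(zygosity = z, r = NA_real_, n = n,
                        lower = NA_real_, upper = NA_real_))
    if (doubleEntry) { xx <- c(x, y); yy <- c(y, x) } else { xx <- x; yy <- y }
    r <- cor(xx, yy)
    if (ciMethod == "fisher") {
      if (abs(r) >= 1 || n <= 3) { ci <- c(NA_real_, NA_real_) }
      else {
        zcrit <- qnorm(1 - (1 - ciLevel) / 2)
        ci <- tanh(atanh(r) + c(-1, 1) * zcrit / sqrt(n - 3))
      }
    } else {
      ci <- profileCorCI(if (doubleEntry) xx else x,
                         if (doubleEntry) yy else y, ciLevel)
    }
    data.frame(zygosity = z, r = r, n = n, lower = ci[1], upper = ci[2])
  })
  do.call(rbind, res)
}

#' Residualize a measure on within-wave age
#'
#' Per wave, regresses the measure on age across all twins as individuals
#' (ordinary least squares) and replaces the measure with the residuals.
#' Observations with missing age become missing in the output; the
#' missingness pattern is otherwise preserved. If age is constant within a
#' wave the slope is undefined and the measure is mean-centred instead,
#' with a warning.
#'
#' @param ds a TwinDataset with per-wave \code{age<w>_t<t>} columns.
#' @param variable measure name without wave suffix, e.g. \code{"wb"}.
#' @return A new TwinDataset with the residualized measure.
#' @export
residualizeOnAge <- function(ds, variable = "wb") {
  p <- ds@pairs
  for (w in TWIN_WAVES) {
    cols <- twinCol(paste0(variable, w), 1:2)
    acols <- twinCol(paste0("age", w), 1:2)
    if (!all(cols %in% names(p))) next
    if (!all(acols %in% names(p)))
      stop(sprintf("age columns for wave %d are required", w))
    y <- c(p[[cols[1]]], p[[cols[2]]])
    a <- c(p[[acols[1]]], p[[acols[2]]])
    ok <- !is.na(y) & !is.na(a)
    res <- rep(NA_real_, length(y))
    if (sum(ok) >= 2) {
      if (sd(a[ok]) == 0) {
        warning(sprintf("age constant in wave %d; mean-centering '%s%d'",
                        w, variable, w))
        res[ok] <- y[ok] - mean(y[ok])
      } else {
        fit <- lm(y[ok] ~ a[ok])
        res[ok] <- residuals(fit)
      }
    }
    n <- nrow(p)
    p[[cols[1]]] <- res[seq_len(n)]
    p[[cols[2]]] <- res[n + seq_len(n)]
  }
  TwinDataset(p)
}

#' Screen a life-event category against wellbeing correlations
#'
#' Applies the pre-modelling screening rule: a category is retained for
#' the twin analyses only when at least one same-wave correlation with
#' wellbeing is both non-negligible in magnitude (|r| above
#' \code{threshold}) and significant at \code{alpha}; otherwise it is
#' excluded. A significant but negligible correlation (easily produced by
#' a large sample) does not retain a category, and neither does a large
#' but non-significant one.
#'
#' @param reports a correlation report from
#'   \code{\link{phenotypicCorrelations}} covering the category and
#'   wellbeing at all waves.
#' @param category measure name, e.g. \code{"posdep"}.
#' @param wellbeing measure name of the wellbeing variable.
#' @param threshold negligibility threshold on |r|.
#' @param alpha significance level.
#' @return list with \code{include} (logical), \code{category}, the
#'   same-wave \code{correlations} that drove the decision, and a
#'   \code{rationale} string.
#' @export
screenEventCategory <- function(reports, category, wellbeing = "wb",
                                threshold = 0.10, alpha = 0.05) {
  rows <- do.call(rbind, lapply(TWIN_WAVES, function(w) {
    v1 <- paste0(category, w); v2 <- paste0(wellbeing, w)
    hit <- reports[(reports$var1 == v1 & reports$var2 == v2) |
                   (reports$var1 == v2 & reports$var2 == v1), , drop = FALSE]
    if (!nrow(hit)) return(NULL)
    cbind(wave = w, hit[1, c("r", "n", "p"), drop = FALSE])
  }))
  if (is.null(rows) || !nrow(rows))
    stop(sprintf("category '%s' not found in the correlation report", category))
  driving <- !is.na(rows$r) & abs(rows$r) > threshold &
    !is.na(rows$p) & rows$p < alpha
  include <- any(driving)
  rows$driving <- driving
  list(include = include, category = category, correlations = rows,
       rationale = if (include)
         sprintf("retained: same-wave correlation(s) with %s at wave(s) %s exceed |r| = %g and are significant at alpha = %g",
                 wellbeing, paste(rows$wave[driving], collapse = ","),
                 threshold, alpha)
       else
         sprintf("excluded: no same-wave correlation with %s is both above |r| = %g and significant at alpha = %g",
                 wellbeing, threshold, alpha))
}
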