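#' Assemble the pooled ACC time series from per-frame counts
#'
#' One point per timestep: droplet counts are summed over locations
#' (pooling, matching totals reported across monitored locations), the
#' representative time is the mean of the per-location acquisition times,
#' and the span records the earliest and latest acquisition.
#'
#' @param counts data.frame of per-frame counts (as produced by
#'   [countTimepoint()] or [generateTimelapse()]`$counts`), with columns
#'   `location_id`, `timestep_index`, `acquisition_time_min`, `N_d`,
#'   `N_d_ACC`.
#' @return data.frame sorted by timestep with columns `timestep_index`,
#'   `mean_time_min`, `time_min`, `time_max`, `N_d`, `N_d_ACC`,
#'   `n_locations`; rows with missing counts are excluded with a warning.
#' @export
assembleTimeseries <- function(counts) {
  if (is.list(counts) && !is.data.frame(counts)) counts <- do.call(rbind, counts)
  need <- c("timestep_index", "acquisition_time_min", "N_d", "N_d_ACC")
  if (!all(need %in% names(counts)))
    stop("counts must carry columns ", paste(need, collapse = ", "))
  bad <- !stats::complete.cases(counts[, need])
  if (any(bad)) {
    warning(sprintf("excluding %d count row(s) with missing values", sum(bad)))
    counts <- counts[!bad, , drop = FALSE]
  }
  if (nrow(counts) == 0) stop("no usable count rows")
  sp <- split(counts, counts$timestep_index)
  out <- do.call(rbind, lapply(sp, function(g) data.frame(
    timestep_index = g$timestep_index[1],
    mean_time_min = mean(g$acquisition_time_min),
    time_min = min(g$acquisition_time_min),
    time_max = max(g$acquisition_time_min),
    N_d = sum(g$N_d), N_d_ACC = sum(g$N_d_ACC),
    n_locations = nrow(g))))
  out <- out[order(out$timestep_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the exponential-plateau decay N(t) = A exp(-k t) + C
#'
#' Unweighted nonlinear least squares (Levenberg-Marquardt via
#' [minpack.lm::nlsLM()]) of the three-parameter first-order
#' transformation model. Initialisation: `C0 = min(y)`,
#' `A0 = max(y) - C0`, and `k0` from a log-linear regression of
#' `y - 0.99 * C0` on time; the rate is constrained nonnegative and the
#' parameter tolerance is 1e-10. A series with no measurable decay
#' returns `A = 0`, `k = 0`, `C = mean(y)` flagged `noDecay`.
#'
#' @param time numeric vector of nonnegative times (minutes).
#' @param y droplet counts (form `"count"`) or ACC fractions
#'   (form `"ratio"`; plateau constrained to [0, 1]).
#' @param form `"count"` or `"ratio"`.
#' @param weights optional least-squares weights (e.g. inverse binomial
#'   variances); unweighted by default.
#' @return A [DecayFit-class].
#' @examples
#' t <- seq(0, 360, length.out = 17)
#' y <- 65.63 * exp(-0.027 * t) + 596.0
#' kRate(fitDecay(t, y, form = "count"))
#' @export
fitDecay <- function(time, y, form = c("count", "ratio"), weights = NULL) {
  form <- match.arg(form)
  if (length(time) != length(y)) stop("time and y must have equal length")
  if (length(y) < 4) stop("at least 4 points are required to fit 3 parameters")
  if (any(!is.finite(time)) || any(!is.finite(y)))
    stop("times and values must be finite (zero-droplet timesteps give undefined ratios)")
  if (any(time < 0)) stop("times must be nonnegative")
  if (form == "ratio" && (min(y) < -1e-9 || max(y) > 1 + 1e-9))
    stop("ratio-form values must lie in [0, 1]")
  C0 <- min(y)
  A0 <- max(y) - C0
  if (A0 <= 1e-12 * max(1, abs(C0)) || sd(y) < 1e-14)
    return(DecayFit(form = form, A = 0, k = 0, C = mean(y),
                    rss = sum((y - mean(y))^2), nPoints = length(y),
                    noDecay = TRUE))
  resid0 <- y - 0.99 * C0
  pos <- resid0 > 0
  k0 <- if (sum(pos) >= 2) {
    sl <- coef(lm(log(resid0[pos]) ~ time[pos]))[2]
    max(-sl, 1e-6)
  } else 1e-3
  lower <- if (form == "ratio") c(A = 0, k = 0, C = 0) else c(A = 0, k = 0, C = -Inf)
  upper <- if (form == "ratio") c(A = 1, k = Inf, C = 1) else c(A = Inf, k = Inf, C = Inf)
  df <- data.frame(t = time, y = y)
  args <- list(y ~ A * exp(-k * t) + C, data = df,
               start = list(A = A0, k = k0, C = C0),
               lower = lower, upper = upper,
               control = minpack.lm::nls.lm.control(
                 ftol = 1e-10, ptol = 1e-10, maxiter = 1000))
  if (!is.null(weights)) args$weights <- weights
  fit <- tryCatch(
    do.call(minpack.lm::nlsLM, args),
    error = function(e)
      stop(sprintf("decay fit failed to converge (start A=%.4g k=%.4g C=%.4g): %s",
                   A0, k0, C0, conditionMessage(e)), call. = FALSE))
  cf <- coef(fit)
  rss <- sum(stats::resid(fit)^2)
  noDecay <- unname(cf["A"]) < 1e-8 * max(1, abs(cf["C"])) || unname(cf["k"]) < 1e-12
  DecayFit(form = form, A = unname(cf["A"]), k = unname(cf["k"]),
           C = unname(min(max(cf["C"], lower["C"]), upper["C"])),
           rss = rss, nPoints = length(y), noDecay = noDecay)
}

#' Evaluate a decay fit at time t
#'
#' @param fit a [DecayFit-class].
#' @param t time(s), minutes, nonnegative.
#' @return `A * exp(-k * t) + C`.
#' @examples
#' evaluateFit(DecayFit("ratio", 0.099, 0.027, 0.898), c(0, 360))
#' @export
evaluateFit <- function(fit, t) {
  stopifnot(is(fit, "DecayFit"), all(t >= 0))
  fit@A * exp(-fit@k * t) + fit@C
}

#' Fraction of droplets still containing ACC
#'
#' @param nAcc droplets containing the amorphous phase.
#' @param nTotal total droplets (> 0).
#' @return The quotient, reported to three decimals.
#' @examples
#' accFraction(443, 653)
#' @export
accFraction <- function(nAcc, nTotal) {
  if (nTotal <= 0) stop("nTotal must be positive")
  if (nAcc < 0 || nAcc > nTotal) stop("nAcc must lie in [0, nTotal]")
  round(nAcc / nTotal, 3)
}

#' Bootstrap confidence interval for the transformation rate
#'
#' Nonparametric uncertainty for the ratio-form rate: droplet outcomes at
#' each timestep are resampled (binomial with the observed ACC fraction),
#' the ratio-form model is refit, and percentile intervals of the rate are
#' reported. The published analysis reports no uncertainty; this interval
#' is an additive feature of the package.
#'
#' @param timeseries data.frame from [assembleTimeseries()].
#' @param nBoot bootstrap resamples (default 200).
#' @param seed RNG seed.
#' @param level interval coverage (default 0.95).
#' @return list with `k`, `ciLower`, `ciUpper`, `nBoot`, `level`.
#' @export
bootstrapRateCI <- function(timeseries, nBoot = 200L, seed = 1L,
                            level = 0.95) {
  stopifnot(all(c("mean_time_min", "N_d", "N_d_ACC") %in% names(timeseries)))
  phat <- timeseries$N_d_ACC / timeseries$N_d
  fit0 <- fitDecay(timeseries$mean_time_min, phat, form = "ratio")
  set.seed(seed)
  ks <- vapply(seq_len(nBoot), function(b) {
    yb <- rbinom(nrow(timeseries), timeseries$N_d, phat) / timeseries$N_d
    f <- tryCatch(fitDecay(timeseries$mean_time_min, yb, form = "ratio"),
                  error = function(e) NULL)
    if (is.null(f)) NA_real_ else f@k
  }, numeric(1))
  qs <- stats::quantile(ks, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE)
  list(k = fit0@k, ciLower = unname(qs[1]), ciUpper = unname(qs[2]),
       nBoot = nBoot, level = level)
}

#' Half-life of the ACC droplet fraction
#'
#' From a ratio-form fit: exact `t1/2 = log(A / (0.5 - C)) / k` when the
#' plateau lies below 0.5 and the rate is positive; otherwise the fraction
#' never reaches 0.5 under the fitted model. From an empirical series:
#' a lower bound, the latest observation time at which the fraction still
#' exceeds 0.5.
#'
#' @param fit a ratio-form [DecayFit-class] (or `NULL`).
#' @param series data.frame with columns `time` and `fraction` (or `NULL`).
#' @return A [HalfLifeBound-class].
#' @examples
#' halfLifeBound(series = data.frame(time = 1440, fraction = 0.678))
#' halfLifeBound(fit = DecayFit("ratio", 0.099, 0.027, 0.898))
#' @export
halfLifeBound <- function(fit = NULL, series = NULL) {
  if (!is.null(fit)) {
    stopifnot(is(fit, "DecayFit"))
    if (fit@form != "ratio") stop("model-based half-life needs a ratio-form fit")
    if (fit@A + fit@C <= 0.5)
      return(new("HalfLifeBound", kind = "exact", valueMin = 0, basis = "model"))
    if (fit@C >= 0.5 || fit@k <= 0)
      return(new("HalfLifeBound", kind = "unreachable", valueMin = NA_real_,
                 basis = "model"))
    return(new("HalfLifeBound", kind = "exact",
               valueMin = log(fit@A / (0.5 - fit@C)) / fit@k, basis = "model"))
  }
  if (!is.null(series)) {
    stopifnot(all(c("time", "fraction") %in% names(series)))
    above <- series$time[series$fraction > 0.5]
    val <- if (length(above)) max(above) else 0
    return(new("HalfLifeBound", kind = "lower_bound", valueMin = val,
               basis = "empirical"))
  }
  stop("provide a fit or a series")
}
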