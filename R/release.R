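#' Release-intensity curve from evoked EPSC charge
#'
#' For each IV sweep the evoked EPSC charge is the magnitude of the integral
#' of the baseline-subtracted postsynaptic current from step onset to step
#' end plus a short tail (default 2 ms) that captures release triggered at
#' the end of the depolarization.
#'
#' @param sweeps list of IV sweeps (postsynaptic trace used; leak
#'   subtraction is irrelevant here).
#' @param tail_ms integration tail beyond the step end (ms).
#' @return data frame of class `"release_intensity"` with columns `v` (mV),
#'   `q_epsc` (fC, magnitude) and `q_norm` (normalized to the maximum;
#'   all-`NaN` with attribute `undefined = TRUE` if no step released
#'   anything).
#' @export
release_intensity <- function(sweeps, tail_ms = 2) {
  if (!length(sweeps)) stop("no IV sweeps supplied")
  rows <- lapply(sweeps, function(sw) {
    se <- stim_epochs(sw)
    if (is.null(se) || nrow(se) == 0)
      stop("sweep without a stimulation epoch")
    st <- se$start[1] - sw$t0
    en <- min(se$end[1] - sw$t0 + tail_ms,
              (length(sw$i_post) - 1) * sw$dt)
    dt <- sw$dt
    n0 <- max(1L, floor(st / dt) - round(5 / dt))
    base <- mean(sw$i_post[n0:max(n0, floor(st / dt))])
    q <- abs(trapz_window(sw$i_post - base, dt, st, en))
    data.frame(v = se$level[1], q_epsc = q)
  })
  out <- do.call(rbind, rows)
  out <- stats::aggregate(q_epsc ~ v, data = out, FUN = mean)
  out <- out[order(out$v), , drop = FALSE]
  qmax <- max(out$q_epsc)
  undefined <- !is.finite(qmax) || qmax <= 0
  out$q_norm <- if (undefined) NaN else out$q_epsc / qmax
  rownames(out) <- NULL
  structure(out, class = c("release_intensity", "data.frame"),
            undefined = undefined)
}

#' Fit the sigmoidal release-intensity curve
#'
#' Least-squares fit of \eqn{Q(V) = Q_{max}/(1+e^{(Q_{50}-V)/s})} to the
#' normalized release-intensity points. The voltages of 10% and 90% maximal
#' release and the dynamic range follow from the closed-form identities
#' \eqn{Q_{10} = Q_{50} - s\ln 9}, \eqn{Q_{90} = Q_{50} + s\ln 9},
#' \eqn{Q_{90}-Q_{10} = s\ln 81}. Pairs whose curve the sigmoid does not
#' describe (R-squared below `r2_min`, midpoint outside the sampled voltage
#' range, or non-convergence) are marked `fit_ok = FALSE` and excluded from
#' group statistics; this replaces by-eye exclusion with a reproducible
#' rule.
#'
#' @param points a [release_intensity()] data frame (or any data frame with
#'   `v` and `q_norm`/`q_epsc`).
#' @param r2_min exclusion threshold on R-squared (default 0.5).
#' @return object of class `"sigmoid_fit"` with `q_max`, `q50`, `slope`,
#'   `q10`, `q90`, `dynamic_range` (mV), `rmse`, `r2`, `fit_ok`.
#' @export
fit_release_sigmoid <- function(points, r2_min = 0.5) {
  if (nrow(points) < 5) stop("need at least 5 release-intensity points")
  q <- if (!is.null(points$q_norm) && all(is.finite(points$q_norm)))
    points$q_norm else points$q_epsc / max(points$q_epsc)
  dat <- data.frame(v = points$v, q = q)
  if (!all(is.finite(dat$q)) || stats::sd(dat$q) == 0)
    return(flag_sigmoid())
  vh0 <- stats::approx(dat$q, dat$v, xout = 0.5, ties = mean)$y
  if (!is.finite(vh0)) vh0 <- stats::median(dat$v)
  starts <- list(list(qmax = 1, q50 = vh0, s = 4),
                 list(qmax = 1.1, q50 = vh0 - 5, s = 8),
                 list(qmax = 1, q50 = vh0 + 5, s = 2))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(q ~ qmax / (1 + exp((q50 - v) / s)), data = dat,
                        start = st, lower = c(1e-3, -120, 0.1),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) return(flag_sigmoid())
  cf <- stats::coef(best$fit)
  tss <- sum((dat$q - mean(dat$q))^2)
  r2 <- 1 - best$rss / tss
  # a proper fit also needs its midpoint inside the sampled voltage range:
  # otherwise the "sigmoid" is an extrapolation, not a description
  in_range <- cf[["q50"]] >= min(dat$v) && cf[["q50"]] <= max(dat$v)
  sf <- sigmoid_fit(cf[["qmax"]], cf[["q50"]], cf[["s"]],
                    rmse = sqrt(best$rss / nrow(dat)), r2 = r2,
                    fit_ok = r2 >= r2_min && in_range)
  sf$data <- dat
  sf
}

# assemble a sigmoid_fit with its closed-form derived quantities
sigmoid_fit <- function(q_max, q50, slope, rmse = NA_real_, r2 = NA_real_,
                        fit_ok = TRUE) {
  structure(list(
    q_max = q_max, q50 = q50, slope = slope,
    q10 = q50 - slope * log(9), q90 = q50 + slope * log(9),
    dynamic_range = slope * log(81),
    rmse = rmse, r2 = r2, fit_ok = fit_ok
  ), class = "sigmoid_fit")
}

flag_sigmoid <- function() {
  structure(list(q_max = NaN, q50 = NaN, slope = NaN, q10 = NaN, q90 = NaN,
                 dynamic_range = NaN, rmse = NaN, r2 = NaN, fit_ok = FALSE),
            class = "sigmoid_fit")
}

#' Quantiles and dynamic range of the release sigmoid
#'
#' For \eqn{Q(V) = Q_{max}/(1+e^{(Q_{50}-V)/s})}, the voltage at which
#' release reaches a fraction `p` of maximum is
#' \eqn{V_p = Q_{50} + s \ln(p/(1-p))}, so the 10%-release voltage is
#' \eqn{Q_{50} - s\ln 9} and the 10--90% dynamic range is \eqn{s \ln 81}.
#'
#' @param q50 half-maximal voltage (mV).
#' @param slope slope factor (mV).
#' @param p release fraction in (0, 1).
#' @return voltage (mV) / dynamic range (mV).
#' @examples
#' sigmoid_quantile(-47.76, 4.16, 0.10)   # voltage of 10% release
#' sigmoid_dynamic_range(4.16)            # 10-90% span
#' @export
sigmoid_quantile <- function(q50, slope, p) {
  stopifnot(p > 0, p < 1)
  q50 + slope * log(p / (1 - p))
}

#' @rdname sigmoid_quantile
#' @export
sigmoid_dynamic_range <- function(slope) slope * log(81)

#' @export
coef.sigmoid_fit <- function(object, ...) {
  c(q_max = object$q_max, q50 = object$q50, slope = object$slope)
}

#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  v <- if (is.null(newdata)) object$data$v else
    if (is.data.frame(newdata)) newdata$v else newdata
  object$q_max / (1 + exp((object$q50 - v) / object$slope))
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (!isTRUE(x$fit_ok) && !is.finite(x$q50)) {
    cat("<sigmoid_fit> failed to converge (fit_ok = FALSE)\n")
    return(invisible(x))
  }
  cat(sprintf("<sigmoid_fit> Q50 = %.2f mV, slope = %.2f mV (Qmax %.3g)%s\n",
              x$q50, x$slope, x$q_max,
              if (x$fit_ok) "" else "  [excluded: poor fit]"))
  cat(sprintf("  Q10 = %.2f mV, Q90 = %.2f mV, dynamic range = %.2f mV, R2 = %.3f\n",
              x$q10, x$q90, x$dynamic_range, x$r2))
  invisible(x)
}

#' Fit the power-law Ca2+ cooperativity
#'
#' Fits \eqn{Q_{EPSC} = a \, Q_{Ca}^m} to paired charge magnitudes by least
#' squares on the raw scale (log-log fitting is unusable because subthreshold
#' steps give \eqn{Q_{EPSC} = 0}). Release saturation is handled by an
#' automatic plateau rule replacing by-eye truncation: points are ordered by
#' `q_ca`, an isotonic regression of `q_epsc` on `q_ca` estimates the
#' plateau through the noise, and trailing points are dropped from where the
#' isotonic fit first exceeds `plateau_frac` (default 95%) of its top level.
#'
#' @param q_ca Ca2+ charge magnitudes (fC), strictly positive.
#' @param q_epsc EPSC charge magnitudes (fC), zeros allowed.
#' @param plateau_frac plateau-detection fraction of the maximum.
#' @param truncate apply the plateau rule (default TRUE).
#' @return object of class `"powerlaw_fit"` with `a`, `m`, `n_used`,
#'   `truncated`, `rmse`, `fit_ok`.
#' @export
fit_cooperativity <- function(q_ca, q_epsc, plateau_frac = 0.95,
                              truncate = TRUE) {
  if (length(q_ca) != length(q_epsc)) stop("q_ca and q_epsc lengths differ")
  ok <- is.finite(q_ca) & is.finite(q_epsc) & q_ca > 0
  q_ca <- q_ca[ok]; q_epsc <- q_epsc[ok]
  if (length(q_ca) < 4) stop("need at least 4 points with positive q_ca")
  o <- order(q_ca)
  q_ca <- q_ca[o]; q_epsc <- q_epsc[o]
  truncated <- FALSE
  if (truncate && any(q_epsc > 0)) {
    hit <- plateau_cut(q_ca, q_epsc, plateau_frac)
    if (hit < length(q_ca)) {
      q_ca <- q_ca[1:hit]; q_epsc <- q_epsc[1:hit]
      truncated <- TRUE
    }
  }
  if (length(q_ca) < 4)
    return(flag_powerlaw(truncated))
  pos <- q_epsc > 0 & q_ca > 0
  if (sum(pos) >= 2) {
    lf <- stats::lm(log(q_epsc[pos]) ~ log(q_ca[pos]))
    m0 <- max(0.1, min(6, stats::coef(lf)[[2]]))
    a0 <- exp(stats::coef(lf)[[1]])
  } else {
    m0 <- 1; a0 <- max(q_epsc) / max(q_ca)
  }
  dat <- data.frame(x = q_ca, y = q_epsc)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * x^m, data = dat,
                      start = list(a = a0, m = m0),
                      lower = c(1e-12, 0.01),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) return(flag_powerlaw(truncated))
  cf <- stats::coef(fit)
  structure(list(a = cf[["a"]], m = cf[["m"]], n_used = nrow(dat),
                 truncated = truncated,
                 rmse = sqrt(mean(stats::resid(fit)^2)), fit_ok = TRUE,
                 data = dat),
            class = "powerlaw_fit")
}

# index of the first point at the release plateau (points ordered by q_ca):
# the plateau level is the mean of the three largest q_epsc values, which is
# robust to single-point noise; truncation keeps everything before the first
# crossing of plateau_frac * level
plateau_cut <- function(q_ca, q_epsc, plateau_frac) {
  top <- mean(sort(q_epsc, decreasing = TRUE)[seq_len(min(3, length(q_epsc)))])
  if (top <= 0) return(length(q_ca))
  hit <- which(q_epsc >= plateau_frac * top)[1]
  if (is.na(hit)) length(q_ca) else hit
}

flag_powerlaw <- function(truncated = FALSE) {
  structure(list(a = NaN, m = NaN, n_used = 0L, truncated = truncated,
                 rmse = NaN, fit_ok = FALSE),
            class = "powerlaw_fit")
}

#' @export
coef.powerlaw_fit <- function(object, ...) c(a = object$a, m = object$m)

#' @export
print.powerlaw_fit <- function(x, ...) {
  if (!x$fit_ok) {
    cat("<powerlaw_fit> flagged failure (too few usable points or no convergence)\n")
    return(invisible(x))
  }
  cat(sprintf("<powerlaw_fit> m = %.3f (a = %.3g), %d points%s, RMSE %.3g\n",
              x$m, x$a, x$n_used,
              if (x$truncated) " after plateau truncation" else "", x$rmse))
  invisible(x)
}

#' Pooled Ca2+ cooperativity by SR class
#'
#' Per pair, `q_epsc` is normalized by its maximum and `q_ca` by its value
#' at the plateau-truncation point (or its maximum when no truncation
#' applies); the normalized points are pooled within each SR class and a
#' single power law is fitted per class.
#'
#' @param pairs list; each element a list with `q_ca`, `q_epsc` and
#'   `sr_class` (`"high"`/`"low"`).
#' @param plateau_frac plateau-detection fraction (see
#'   [fit_cooperativity()]).
#' @return list with elements `high` and `low` ([fit_cooperativity()]
#'   results, or `NULL` with a warning for an empty class).
#' @export
pooled_cooperativity <- function(pairs, plateau_frac = 0.95) {
  norm_one <- function(p) {
    o <- order(p$q_ca)
    q_ca <- p$q_ca[o]; q_epsc <- p$q_epsc[o]
    keep <- is.finite(q_ca) & is.finite(q_epsc) & q_ca > 0
    q_ca <- q_ca[keep]; q_epsc <- q_epsc[keep]
    if (!length(q_ca) || max(q_epsc) <= 0) return(NULL)
    hit <- plateau_cut(q_ca, q_epsc, plateau_frac)
    data.frame(q_ca = q_ca / q_ca[hit], q_epsc = q_epsc / max(q_epsc))
  }
  fit_class <- function(cls) {
    sel <- Filter(function(p) identical(p$sr_class, cls), pairs)
    if (length(sel) < 2) {
      warning("fewer than 2 pairs in class '", cls, "'; skipped")
      return(NULL)
    }
    pooled <- do.call(rbind, Filter(Negate(is.null), lapply(sel, norm_one)))
    if (is.null(pooled) || nrow(pooled) < 4) return(NULL)
    fit_cooperativity(pooled$q_ca, pooled$q_epsc, plateau_frac = plateau_frac,
                      truncate = FALSE)
  }
  list(high = fit_class("high"), low = fit_class("low"))
}
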