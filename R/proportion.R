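#' @name proportion-estimators
#' @title Proportion below threshold from arm-level summaries
#'
#' @description
#' Each trial arm reports its outcome in one of four forms. These estimators
#' convert every form into a common currency: the estimated proportion of
#' women below the clinical threshold (80 mL menstrual blood loss, or 100
#' PBAC points), a standard error for that proportion, and the equivalent
#' "effective" binomial count pair \code{(y_eff, n_eff)} whose sampling
#' variance matches the squared standard error. Direct event counts pass
#' through unchanged; mean/SD and median-based summaries are mapped through
#' a moment-matched normal or lognormal distribution, with the standard
#' error obtained by the delta method from the sampling variances of the
#' mean (\eqn{s^2/n}) and SD (\eqn{s^2/(2(n-1))}), treated as independent.
#'
#' Median-based forms first recover (mean, SD): median + range via the Hozo
#' estimator with its n-dependent divisor, median + quartiles via the
#' Wan-type rules (mean \eqn{(q_1+m+q_3)/3}, SD \eqn{(q_3-q_1)/1.349} under
#' normality; the same rules on the log scale under lognormality). Because
#' quantile-based spread estimates are less efficient than a sample SD, the
#' delta-method variance components are inflated by fixed relative-
#' efficiency factors (\eqn{\pi/2} on the mean term for median-derived
#' means; 2.0 and 2.7 on the SD term for range- and IQR-derived SDs).
#'
#' @param y number of women below threshold.
#' @param n arm size at the follow-up time.
#' @param mean,sd arm mean and standard deviation of the outcome.
#' @param median,min,max,q1,q3 reported order statistics of the outcome.
#' @param family distribution assumed for individual outcomes,
#'   \code{"LOGNORMAL"} (default; blood-loss measures are positive and
#'   right-skewed) or \code{"NORMAL"}.
#' @param threshold clinical threshold in outcome units (80 for MBL in mL,
#'   100 for PBAC points).
#' @param continuity continuity constant added only when \code{y} is 0 or
#'   \code{n} (default 0.5), keeping the logit finite without biasing
#'   interior proportions.
#' @return A one-row data.frame (an effective observation) with columns
#'   \code{p_hat}, \code{se}, \code{y_eff}, \code{n_eff}, \code{provenance}.
NULL

new_effective_obs <- function(p_hat, se, y_eff, n_eff, provenance) {
  data.frame(p_hat = p_hat, se = se, y_eff = y_eff, n_eff = n_eff,
             provenance = provenance, stringsAsFactors = FALSE)
}

#' @rdname proportion-estimators
#' @export
prop_from_counts <- function(y, n, continuity = 0.5) {
  stopifnot(length(y) == 1L, length(n) == 1L)
  if (is.na(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  if (is.na(y) || y < 0 || y > n) stop("need 0 <= y <= n", call. = FALSE)
  if (y == 0 || y == n) {
    p <- (y + continuity) / (n + 2 * continuity)
  } else {
    p <- y / n
  }
  se <- sqrt(p * (1 - p) / n)
  new_effective_obs(p, se, y, n, "DIRECT_COUNTS")
}

# moment-match (mean, sd) to the assumed family and return P(X < threshold)
# plus its partial derivatives with respect to mean and sd
below_threshold_prob <- function(mean, sd, threshold, family) {
  if (family == "NORMAL") {
    z <- (threshold - mean) / sd
    p <- stats::pnorm(z)
    dpdm <- -stats::dnorm(z) / sd
    dpds <- -stats::dnorm(z) * z / sd
  } else { # LOGNORMAL
    if (mean <= 0) stop("lognormal family requires mean > 0", call. = FALSE)
    f <- function(m, s) {
      sig2 <- log(1 + (s / m)^2)
      mu <- log(m) - sig2 / 2
      stats::plnorm(threshold, mu, sqrt(sig2))
    }
    p <- f(mean, sd)
    hm <- 1e-6 * max(1, abs(mean))
    hs <- 1e-6 * max(1, abs(sd))
    dpdm <- (f(mean + hm, sd) - f(mean - hm, sd)) / (2 * hm)
    dpds <- (f(mean, sd + hs) - f(mean, sd - hs)) / (2 * hs)
  }
  list(p = p, dpdm = dpdm, dpds = dpds)
}

# shared delta-method core; inflate_* are relative-efficiency penalties for
# summary-derived moments
prop_from_moments <- function(mean, sd, n, threshold, family, provenance,
                              inflate_mean = 1, inflate_sd = 1) {
  if (is.na(sd) || sd <= 0) stop("sd must be > 0", call. = FALSE)
  if (is.na(n) || n < 2) stop("n must be >= 2", call. = FALSE)
  g <- below_threshold_prob(mean, sd, threshold, family)
  var_mean <- inflate_mean * sd^2 / n
  var_sd <- inflate_sd * sd^2 / (2 * (n - 1))
  se <- sqrt(g$dpdm^2 * var_mean + g$dpds^2 * var_sd)
  eps <- 1e-10
  p <- min(max(g$p, eps), 1 - eps)
  se <- max(se, 1e-8)
  n_eff <- min(p * (1 - p) / se^2, n)
  new_effective_obs(p, se, p * n_eff, n_eff, provenance)
}

#' @rdname proportion-estimators
#' @export
prop_from_mean_sd <- function(mean, sd, n, threshold,
                              family = c("LOGNORMAL", "NORMAL")) {
  family <- match.arg(family)
  prop_from_moments(mean, sd, n, threshold, family, "FROM_MEAN_SD")
}

# Hozo range-based recovery of (mean, sd); log scale under lognormality
hozo_moments <- function(median, min, max, n, family) {
  if (family == "LOGNORMAL") {
    if (min <= 0) stop("lognormal family requires min > 0", call. = FALSE)
    mu <- (log(min) + 2 * log(median) + log(max)) / 4
    sig <- hozo_sd(log(min), log(median), log(max), n)
    m <- exp(mu + sig^2 / 2)
    s <- m * sqrt(expm1(sig^2))
  } else {
    m <- (min + 2 * median + max) / 4
    s <- hozo_sd(min, median, max, n)
  }
  c(mean = m, sd = s)
}

hozo_sd <- function(a, m, b, n) {
  if (n <= 15) {
    sqrt(((a - 2 * m + b)^2 / 4 + (b - a)^2) / 12)
  } else if (n <= 70) {
    (b - a) / 4
  } else {
    (b - a) / 6
  }
}

#' @rdname proportion-estimators
#' @export
prop_from_median_range <- function(median, min, max, n, threshold,
                                   family = c("LOGNORMAL", "NORMAL")) {
  family <- match.arg(family)
  if (any(is.na(c(median, min, max)))) stop("incomplete summary", call. = FALSE)
  if (!(min <= median && median <= max)) {
    stop("need min <= median <= max", call. = FALSE)
  }
  if (min == max) stop("degenerate spread: min == max", call. = FALSE)
  if (is.na(n) || n < 3) stop("n must be >= 3", call. = FALSE)
  ms <- hozo_moments(median, min, max, n, family)
  prop_from_moments(ms[["mean"]], ms[["sd"]], n, threshold, family,
                    "FROM_MEDIAN_RANGE",
                    inflate_mean = pi / 2, inflate_sd = 2.0)
}

#' @rdname proportion-estimators
#' @export
prop_from_median_iqr <- function(median, q1, q3, n, threshold,
                                 family = c("LOGNORMAL", "NORMAL")) {
  family <- match.arg(family)
  if (any(is.na(c(median, q1, q3)))) stop("incomplete summary", call. = FALSE)
  if (!(q1 <= median && median <= q3)) {
    stop("need q1 <= median <= q3", call. = FALSE)
  }
  if (q1 == q3) stop("degenerate spread: q1 == q3", call. = FALSE)
  if (is.na(n) || n < 3) stop("n must be >= 3", call. = FALSE)
  # 1.349 = qnorm(.75) - qnorm(.25): IQR-to-SD conversion under normality
  if (family == "LOGNORMAL") {
    if (q1 <= 0) stop("lognormal family requires q1 > 0", call. = FALSE)
    mu <- (log(q1) + log(median) + log(q3)) / 3
    sig <- (log(q3) - log(q1)) / (2 * stats::qnorm(0.75))
    m <- exp(mu + sig^2 / 2)
    s <- m * sqrt(expm1(sig^2))
  } else {
    m <- (q1 + median + q3) / 3
    s <- (q3 - q1) / (2 * stats::qnorm(0.75))
  }
  prop_from_moments(m, s, n, threshold, family, "FROM_MEDIAN_IQR",
                    inflate_mean = pi / 2, inflate_sd = 2.7)
}

#' Effective binomial counts of an estimated proportion
#'
#' Inverts the binomial standard-error formula: the effective sample size is
#' the binomial denominator whose sampling variance equals the estimate's
#' squared standard error, \eqn{n_{eff} = \hat p(1-\hat p)/se^2}, and
#' \eqn{y_{eff} = \hat p \, n_{eff}}. Observations that arrived as direct
#' counts pass through unchanged.
#'
#' @param obs data.frame of effective observations (rows with \code{p_hat},
#'   \code{se}, \code{provenance}, and for direct counts \code{y_eff},
#'   \code{n_eff}).
#' @return The same data.frame with \code{y_eff}, \code{n_eff} filled in.
#' @export
to_effective_counts <- function(obs) {
  stopifnot(all(c("p_hat", "se", "provenance") %in% names(obs)))
  if (any(obs$se <= 0)) stop("se must be > 0", call. = FALSE)
  derived <- obs$provenance != "DIRECT_COUNTS"
  n_eff <- obs$p_hat * (1 - obs$p_hat) / obs$se^2
  obs$n_eff[derived] <- n_eff[derived]
  obs$y_eff[derived] <- obs$p_hat[derived] * obs$n_eff[derived]
  obs
}

#' Estimate below-threshold proportions for every arm of a network
#'
#' Applies the form-appropriate estimator to each arm-time record, producing
#' the unified effective-observation table that feeds the hierarchical
#' model. PBAC-scale arms use the 100-point threshold and are otherwise
#' processed identically to MBL arms (the two scales are treated as
#' equivalent definitions of response).
#'
#' @param net an [evidence_network()].
#' @param family assumed outcome distribution for summary-based arms,
#'   \code{"LOGNORMAL"} (default) or \code{"NORMAL"}.
#' @param threshold_mbl,threshold_pbac response thresholds (mL; PBAC points).
#' @param continuity continuity constant for boundary counts.
#' @return data.frame with one row per arm-time record: identifiers,
#'   \code{p_hat}, \code{se}, \code{y_eff}, \code{n_eff}, \code{provenance},
#'   \code{baseline_mean}; the assumed family is recorded in attribute
#'   \code{"family"} and in column \code{family}.
#' @export
estimate_proportions <- function(net, family = c("LOGNORMAL", "NORMAL"),
                                 threshold_mbl = 80, threshold_pbac = 100,
                                 continuity = 0.5) {
  stopifnot(inherits(net, "evidence_network"))
  family <- match.arg(family)
  arms <- net$arms
  rows <- vector("list", nrow(arms))
  for (k in seq_len(nrow(arms))) {
    a <- arms[k, ]
    thr <- if (a$scale == "PBAC") threshold_pbac else threshold_mbl
    est <- switch(a$form,
      COUNTS = prop_from_counts(a$y, a$n, continuity),
      MEAN_SD = prop_from_mean_sd(a$mean, a$sd, a$n, thr, family),
      MEDIAN_RANGE = prop_from_median_range(a$median, a$min, a$max, a$n,
                                            thr, family),
      MEDIAN_IQR = prop_from_median_iqr(a$median, a$q1, a$q3, a$n,
                                        thr, family))
    rows[[k]] <- cbind(
      a[, c("study_id", "arm", "class", "time_months", "scale",
            "baseline_mean")],
      est, family = family, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "family") <- family
  out
}
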