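#' Standardize baseline mean blood loss
#'
#' Baseline mean MBL enters the model as a standardized covariate: observed
#' values are centred on the mean over all study-arm combinations with
#' non-missing data and divided by their standard deviation. Missing entries
#' are flagged for imputation as model parameters.
#'
#' @param raw numeric vector of per-(study, class) baseline means in mL;
#'   \code{NA} for arms whose study did not report a baseline.
#' @return list with \code{center} (mL), \code{scale} (mL), \code{x}
#'   (standardized values, \code{NA} where missing) and
#'   \code{missing_mask} (logical).
#' @export
standardize_baselines <- function(raw) {
  obs <- !is.na(raw)
  if (sum(obs) < 2L) {
    stop("need at least 2 non-missing baseline values", call. = FALSE)
  }
  center <- mean(raw[obs])
  scale <- stats::sd(raw[obs])
  if (scale == 0) stop("baseline values have zero spread", call. = FALSE)
  x <- (raw - center) / scale
  list(center = center, scale = scale, x = x, missing_mask = !obs)
}

#' Pool same-class arms within a study
#'
#' Several source trials randomised two arms of the same treatment class
#' (e.g. two ablation techniques). The model has a single study-by-class
#' effect, so such arms are combined into one observation by summing their
#' effective event and trial counts; the pooled proportion is the
#' count-weighted mean of the constituents, and the provenance column
#' records the merge.
#'
#' @param obs effective-observation table from [estimate_proportions()].
#' @return The table with one row per (study, class, time, scale).
#' @export
pool_same_class_arms <- function(obs) {
  key <- paste(obs$study_id, obs$class, obs$time_months, obs$scale,
               sep = "\r")
  if (!anyDuplicated(key)) return(obs)
  pooled <- lapply(split(seq_len(nrow(obs)), key), function(idx) {
    sub <- obs[idx, , drop = FALSE]
    if (nrow(sub) == 1L) return(sub)
    row <- sub[1L, , drop = FALSE]
    row$y_eff <- sum(sub$y_eff)
    row$n_eff <- sum(sub$n_eff)
    row$p_hat <- row$y_eff / row$n_eff
    row$se <- sqrt(row$p_hat * (1 - row$p_hat) / row$n_eff)
    row$provenance <- paste0("POOLED[",
                             paste(sub$provenance, collapse = "+"), "]")
    bl <- sub$baseline_mean[!is.na(sub$baseline_mean)]
    row$baseline_mean <- if (length(bl)) mean(bl) else NA_real_
    row$arm <- min(sub$arm)
    row
  })
  out <- do.call(rbind, c(unname(pooled), list(make.row.names = FALSE)))
  out <- out[order(out$study_id, out$class, out$time_months, out$scale), ]
  rownames(out) <- NULL
  out
}

#' Build the hierarchical binomial-logit model
#'
#' Indexes the effective observations and defines the joint model
#' \deqn{y_{ijt} \sim \mathrm{Binomial}(n_{ijt}, p_{ijt}), \quad
#'       \mathrm{logit}(p_{ijt}) = \alpha_0 + \eta_i + \theta_{ij} +
#'       \gamma_{jt}}
#' with study effects \eqn{\eta_i \sim N(0, \sigma_\eta^2)}, study-by-class
#' effects \eqn{\theta_{ij} \sim N(\delta_j + \alpha_1 x_{ij}, \tau_j^2)}
#' given the class effect \eqn{\delta_j} and the standardized baseline
#' covariate \eqn{x_{ij}}, and class-by-time effects \eqn{\gamma_{jt}}
#' defined only for (class, time) pairs observed in the data. Priors:
#' \eqn{\alpha_0, \delta_j \sim N(0, 10^4)}, \eqn{\gamma_{jt} \sim N(0,
#' 100)}, \eqn{\alpha_1 \sim U(-5, 5)}, \eqn{\tau_j \sim U(0, 100)},
#' \eqn{1/\sigma_\eta^2 \sim \mathrm{Gamma}(0.1, 0.1)} (shape-rate), and
#' \eqn{x_{ij} \sim N(0, 1)} for missing standardized baselines (missing at
#' random). Effective counts may be non-integer; the likelihood uses the
#' continuous binomial generalization (gamma-function binomial
#' coefficient).
#'
#' The parameterization is deliberately redundant (\eqn{\alpha_0},
#' \eqn{\delta_j} and \eqn{\gamma_{jt}} all carry vague priors with no
#' contrast constraint); only sums such as \eqn{\alpha_0 + \delta_j +
#' \gamma_{jt}} are identifiable, and posterior reporting uses only those
#' sums. \code{constrain = TRUE} instead fixes \eqn{\delta_j = 0} for the
#' reference class (placebo if present) and \eqn{\gamma_{jt} = 0} at each
#' class's earliest observed time, removing the flat directions so that
#' raw-parameter diagnostics become interpretable; the identifiable sums
#' are unchanged. In either mode, judge convergence on the identifiable
#' sums (see [convergence_report()]), not on \eqn{\alpha_0},
#' \eqn{\delta_j} or \eqn{\gamma_{jt}} individually.
#'
#' @param obs effective-observation table (pass through
#'   [pool_same_class_arms()] first if any study has same-class arms).
#' @param constrain logical; apply the identifiability corner constraint.
#' @return An object of class \code{mtc_model} with index tables, the
#'   standardized covariate, fixed-parameter map and parameter names.
#' @export
build_mtc_model <- function(obs, constrain = FALSE) {
  need <- c("study_id", "class", "time_months", "y_eff", "n_eff")
  stopifnot(all(need %in% names(obs)))
  obs <- obs[order(obs$study_id, obs$class, obs$time_months), , drop = FALSE]
  rownames(obs) <- NULL

  studies <- sort(unique(obs$study_id))
  sc_key <- paste(obs$study_id, obs$class, sep = "\r")
  sc_first <- !duplicated(sc_key)
  sc <- data.frame(study_id = obs$study_id[sc_first],
                   class = obs$class[sc_first], stringsAsFactors = FALSE)
  # baseline is a per-(study, class) quantity; take first non-missing
  if ("baseline_mean" %in% names(obs)) {
    sc$baseline_mean <- vapply(seq_len(nrow(sc)), function(k) {
      b <- obs$baseline_mean[obs$study_id == sc$study_id[k] &
                               obs$class == sc$class[k]]
      b <- b[!is.na(b)]
      if (length(b)) b[1L] else NA_real_
    }, numeric(1))
  } else {
    sc$baseline_mean <- NA_real_
  }
  ct_key <- paste(obs$class, obs$time_months, sep = "\r")
  ct_first <- !duplicated(ct_key)
  ct <- data.frame(class = obs$class[ct_first],
                   time = obs$time_months[ct_first], stringsAsFactors = FALSE)
  ct <- ct[order(ct$class, ct$time), , drop = FALSE]
  rownames(ct) <- NULL
  classes <- sort(unique(obs$class))

  std <- standardize_baselines(sc$baseline_mean)
  sc$x <- std$x
  sc$x_obs <- !std$missing_mask

  obs$study_idx <- match(obs$study_id, studies)
  obs$sc_idx <- match(sc_key, paste(sc$study_id, sc$class, sep = "\r"))
  obs$ct_idx <- match(ct_key, paste(ct$class, ct$time, sep = "\r"))
  sc$class_idx <- match(sc$class, classes)
  ct$class_idx <- match(ct$class, classes)

  fixed <- numeric(0)
  if (constrain) {
    ref <- if ("PLACEBO" %in% classes) "PLACEBO" else classes[1L]
    fixed[paste0("delta[", ref, "]")] <- 0
    for (cl in classes) {
      t0 <- min(ct$time[ct$class == cl])
      fixed[paste0("gamma[", cl, ":", t0, "]")] <- 0
    }
  }

  par_names <- c(
    "alpha0", "alpha1",
    paste0("eta[", studies, "]"),
    paste0("theta[", sc$study_id, ":", sc$class, "]"),
    paste0("gamma[", ct$class, ":", ct$time, "]"),
    paste0("delta[", classes, "]"),
    paste0("tau[", classes, "]"),
    "sigma_eta",
    paste0("x[", sc$study_id[!sc$x_obs], ":", sc$class[!sc$x_obs], "]"))
  par_names <- setdiff(par_names, names(fixed))

  structure(list(
    obs = obs, studies = studies, sc = sc, ct = ct, classes = classes,
    center = std$center, scale = std$scale,
    constrain = constrain, fixed = fixed, par_names = par_names,
    prior = list(sd_alpha0 = 100, sd_delta = 100, sd_gamma = 10,
                 alpha1_bounds = c(-5, 5), tau_bounds = c(0, 100),
                 prec_eta_shape = 0.1, prec_eta_rate = 0.1)),
    class = "mtc_model")
}

#' @export
print.mtc_model <- function(x, ...) {
  cat("Hierarchical binomial-logit MTC model\n")
  cat("  ", nrow(x$obs), "observations;", length(x$studies), "studies;",
      length(x$classes), "classes;", nrow(x$ct), "(class, time) cells\n")
  cat("  ", sum(!x$sc$x_obs), "of", nrow(x$sc),
      "baseline covariates missing (imputed)\n")
  cat("  ", length(x$par_names), "free parameters",
      if (x$constrain) "(corner-constrained)" else "(unconstrained)", "\n")
  invisible(x)
}

# look up a parameter by name, falling back to the fixed map
param_value <- function(params, model, name) {
  if (name %in% names(params)) return(unname(params[[name]]))
  if (name %in% names(model$fixed)) return(unname(model$fixed[[name]]))
  stop("no parameter '", name, "' in this model", call. = FALSE)
}

# expand a named parameter vector into the blocks the density needs
expand_params <- function(params, model) {
  getv <- function(names) {
    vapply(names, function(nm) param_value(params, model, nm), numeric(1))
  }
  sc <- model$sc
  x <- sc$x
  if (any(!sc$x_obs)) {
    x[!sc$x_obs] <- getv(paste0("x[", sc$study_id[!sc$x_obs], ":",
                                sc$class[!sc$x_obs], "]"))
  }
  list(
    alpha0 = param_value(params, model, "alpha0"),
    alpha1 = param_value(params, model, "alpha1"),
    eta = getv(paste0("eta[", model$studies, "]")),
    theta = getv(paste0("theta[", sc$study_id, ":", sc$class, "]")),
    gamma = getv(paste0("gamma[", model$ct$class, ":", model$ct$time, "]")),
    delta = getv(paste0("delta[", model$classes, "]")),
    tau = getv(paste0("tau[", model$classes, "]")),
    sigma_eta = param_value(params, model, "sigma_eta"),
    x = x)
}

#' Linear predictor of the response probability
#'
#' Returns \eqn{\alpha_0 + \eta_i + \theta_{ij} + \gamma_{jt}} on the logit
#' scale. Studies observed at several follow-up times share \eqn{\eta_i}
#' and \eqn{\theta_{ij}}; only \eqn{\gamma_{jt}} varies with time.
#'
#' @param params named numeric vector of parameter values (names as in
#'   \code{model$par_names}).
#' @param model an \code{mtc_model}.
#' @param i study id.
#' @param j treatment class.
#' @param t follow-up time in months.
#' @return Logit-scale linear predictor (length-1 numeric).
#' @export
linear_predictor <- function(params, model, i, j, t) {
  j <- canonical_class(j)
  hit <- model$obs$study_id == i & model$obs$class == j &
    model$obs$time_months == t
  if (!any(hit)) {
    stop("(study, class, time) = (", i, ", ", j, ", ", t,
         ") is not indexed in this model", call. = FALSE)
  }
  param_value(params, model, "alpha0") +
    param_value(params, model, paste0("eta[", i, "]")) +
    param_value(params, model, paste0("theta[", i, ":", j, "]")) +
    param_value(params, model, paste0("gamma[", j, ":", t, "]"))
}

# continuous binomial log-density (gamma-function coefficient); p clipped
# 1e-12 from each boundary
binom_logdens <- function(y, n, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  lgamma(n + 1) - lgamma(y + 1) - lgamma(n - y + 1) +
    y * log(p) + (n - y) * log1p(-p)
}

#' Joint log-likelihood of the effective observations
#'
#' Sum of (continuous-generalized) binomial log-densities of the effective
#' counts at the model's linear predictor.
#'
#' @inheritParams linear_predictor
#' @return Length-1 numeric log-density; 0 for a model with no data.
#' @export
log_likelihood <- function(params, model) {
  if (nrow(model$obs) == 0L) return(0)
  b <- expand_params(params, model)
  lp <- b$alpha0 + b$eta[model$obs$study_idx] + b$theta[model$obs$sc_idx] +
    b$gamma[model$obs$ct_idx]
  sum(binom_logdens(model$obs$y_eff, model$obs$n_eff, invlogit(lp)))
}

#' Joint log-prior of the model parameters
#'
#' Sum of the stated prior components, including the hierarchical terms for
#' \eqn{\eta_i}, \eqn{\theta_{ij}} and missing \eqn{x_{ij}}. The study-
#' effect variance is parameterized through its precision
#' \eqn{1/\sigma_\eta^2} (BUGS shape-rate convention); the returned density
#' is the joint density in that parameterization. Values outside the
#' support (\eqn{\tau_j \notin (0, 100)}, \eqn{\sigma_\eta \le 0},
#' \eqn{\alpha_1 \notin (-5, 5)}) return \code{-Inf}.
#'
#' @inheritParams linear_predictor
#' @return Length-1 numeric log-density.
#' @export
log_prior <- function(params, model) {
  b <- expand_params(params, model)
  pr <- model$prior
  if (b$alpha1 <= pr$alpha1_bounds[1] || b$alpha1 >= pr$alpha1_bounds[2]) {
    return(-Inf)
  }
  if (any(b$tau <= pr$tau_bounds[1] | b$tau >= pr$tau_bounds[2])) {
    return(-Inf)
  }
  if (b$sigma_eta <= 0) return(-Inf)

  fixed_delta <- paste0("delta[", model$classes, "]") %in% names(model$fixed)
  fixed_gamma <- paste0("gamma[", model$ct$class, ":", model$ct$time, "]") %in%
    names(model$fixed)

  lp <- stats::dnorm(b$alpha0, 0, pr$sd_alpha0, log = TRUE) +
    stats::dunif(b$alpha1, pr$alpha1_bounds[1], pr$alpha1_bounds[2],
                 log = TRUE) +
    sum(stats::dnorm(b$delta[!fixed_delta], 0, pr$sd_delta, log = TRUE)) +
    sum(stats::dnorm(b$gamma[!fixed_gamma], 0, pr$sd_gamma, log = TRUE)) +
    sum(stats::dunif(b$tau, pr$tau_bounds[1], pr$tau_bounds[2], log = TRUE)) +
    stats::dgamma(1 / b$sigma_eta^2, shape = pr$prec_eta_shape,
                  rate = pr$prec_eta_rate, log = TRUE) +
    sum(stats::dnorm(b$eta, 0, b$sigma_eta, log = TRUE))
  theta_mean <- b$delta[model$sc$class_idx] + b$alpha1 * b$x
  lp <- lp + sum(stats::dnorm(b$theta, theta_mean,
                              b$tau[model$sc$class_idx], log = TRUE))
  if (any(!model$sc$x_obs)) {
    lp <- lp + sum(stats::dnorm(b$x[!model$sc$x_obs], 0, 1, log = TRUE))
  }
  lp
}

#' Serialize a model specification to JSON
#'
#' Writes the observation table, index maps, covariate standardization
#' constants, constraint map and prior hyperparameters, so a run is fully
#' reproducible from the file alone.
#'
#' @param model an \code{mtc_model}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
model_to_json <- function(model, path) {
  jsonlite::write_json(
    list(obs = model$obs, constrain = model$constrain,
         center = model$center, scale = model$scale,
         fixed = as.list(model$fixed), prior = model$prior),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Rebuild a model from its JSON specification
#'
#' @param path path written by [model_to_json()].
#' @return An \code{mtc_model}.
#' @export
model_from_json <- function(path) {
  spec <- jsonlite::fromJSON(path)
  build_mtc_model(spec$obs, constrain = isTRUE(spec$constrain))
}
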