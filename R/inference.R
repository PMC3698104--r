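#' Sampler configuration presets
#'
#' \code{"paper"} is the full protocol of the source analysis (3 chains,
#' 60,000 burn-in iterations, 60,000 saved); \code{"desk"} is a scaled
#' profile (3 chains, 2,000 + 2,000) for interactive use and testing.
#'
#' @param name \code{"paper"} or \code{"desk"}.
#' @return list with \code{chains}, \code{burn_in}, \code{draws}.
#' @export
sampler_preset <- function(name = c("desk", "paper")) {
  name <- match.arg(name)
  switch(name,
         paper = list(chains = 3L, burn_in = 60000L, draws = 60000L),
         desk = list(chains = 3L, burn_in = 2000L, draws = 2000L))
}

#' Random-walk Metropolis kernel
#'
#' Minimal scalar/vector random-walk Metropolis sampler over an arbitrary
#' log-density. This is the elementary kernel underlying the blocked
#' updates of [run_sampler()]; it is exported so the sampling machinery can
#' be validated against closed-form posteriors on conjugate toy problems.
#'
#' @param log_target function taking a numeric state, returning a
#'   log-density (possibly \code{-Inf}).
#' @param init initial state (finite log-density required).
#' @param n_iter number of iterations (each is one proposal per component).
#' @param scale proposal standard deviation (recycled over components).
#' @return matrix of states, \code{n_iter} rows.
#' @export
rw_metropolis <- function(log_target, init, n_iter, scale = 1) {
  d <- length(init)
  scale <- rep_len(scale, d)
  out <- matrix(NA_real_, n_iter, d)
  cur <- init
  cur_lp <- log_target(cur)
  if (!is.finite(cur_lp)) stop("non-finite log-density at init", call. = FALSE)
  for (it in seq_len(n_iter)) {
    prop <- cur + stats::rnorm(d) * scale
    prop_lp <- log_target(prop)
    if (is.finite(prop_lp) && log(stats::runif(1)) < prop_lp - cur_lp) {
      cur <- prop
      cur_lp <- prop_lp
    }
    out[it, ] <- cur
  }
  out
}

# binomial log-likelihood kernel (constant terms dropped), clipped
ll_kernel <- function(lp, y, n) {
  p <- pmin(pmax(invlogit(lp), 1e-12), 1 - 1e-12)
  y * log(p) + (n - y) * log1p(-p)
}

#' Sample the posterior of the hierarchical MTC model
#'
#' Blocked Metropolis-within-Gibbs sampler over the joint density
#' \code{\link{log_likelihood}} + \code{\link{log_prior}}. Location blocks
#' (\eqn{\alpha_0}, \eqn{\eta_i}, \eqn{\theta_{ij}}, \eqn{\gamma_{jt}},
#' \eqn{\tau_j}) use vectorised single-site random-walk Metropolis with
#' per-component proposal scales adapted towards 44\% acceptance during
#' burn-in and frozen afterwards; \eqn{\delta_j}, \eqn{\alpha_1} (truncated
#' normal), the study-effect precision (conjugate gamma) and missing
#' standardized baselines (conjugate normal) are exact Gibbs updates.
#' Initial values are drawn from the priors truncated to [-2, 2] on
#' location parameters, with up to 10 retries on a non-finite density.
#' Identical seed and configuration give identical draws.
#'
#' @param model an \code{mtc_model} from [build_mtc_model()].
#' @param chains number of chains (default 3).
#' @param burn_in adaptation/warm-up iterations discarded per chain.
#' @param draws saved iterations per chain.
#' @param seed integer RNG seed for the whole run.
#' @param prior_only logical; sample the joint prior instead of the
#'   posterior (the prior is a directed model, so this uses exact
#'   ancestral sampling).
#' @param preset optional name passed to [sampler_preset()]; overrides
#'   \code{chains}/\code{burn_in}/\code{draws}.
#' @return An object of class \code{mtc_draws}: saved draws per chain
#'   (matrices with one named column per free parameter), the model, and
#'   the run configuration.
#' @export
run_sampler <- function(model, chains = 3L, burn_in = 2000L, draws = 2000L,
                        seed = 1L, prior_only = FALSE, preset = NULL) {
  stopifnot(inherits(model, "mtc_model"))
  if (!is.null(preset)) {
    cfg <- sampler_preset(preset)
    chains <- cfg$chains; burn_in <- cfg$burn_in; draws <- cfg$draws
  }
  stopifnot(chains >= 1L, burn_in >= 0L, draws >= 1L)
  set.seed(as.integer(seed))

  obs <- model$obs
  sc <- model$sc
  ct <- model$ct
  S <- length(model$studies)
  SC <- nrow(sc)
  CT <- nrow(ct)
  J <- length(model$classes)
  mis <- which(!sc$x_obs)
  M <- length(mis)
  oi <- obs$study_idx; os <- obs$sc_idx; oc <- obs$ct_idx
  y <- obs$y_eff; n <- obs$n_eff
  sc_cl <- sc$class_idx
  m_per_class <- tabulate(sc_cl, J)
  pr <- model$prior
  gamma_fixed <- paste0("gamma[", ct$class, ":", ct$time, "]") %in%
    names(model$fixed)
  delta_fixed <- paste0("delta[", model$classes, "]") %in% names(model$fixed)

  chain_draws <- vector("list", chains)
  accept <- NULL
  for (ch in seq_len(chains)) {
    # init from truncated priors; retry on non-finite density
    for (attempt in 1:10) {
      st <- list(
        a0 = stats::runif(1, -2, 2),
        a1 = stats::runif(1, -1, 1),
        eta = stats::runif(S, -2, 2),
        theta = stats::runif(SC, -2, 2),
        gamma = ifelse(gamma_fixed, 0, stats::runif(CT, -2, 2)),
        delta = ifelse(delta_fixed, 0, stats::runif(J, -2, 2)),
        tau = stats::runif(J, 0.5, 2),
        sig_eta = stats::runif(1, 0.5, 2),
        xmis = stats::rnorm(M))
      xv <- sc$x
      if (M) xv[mis] <- st$xmis
      lp <- st$a0 + st$eta[oi] + st$theta[os] + st$gamma[oc]
      if (all(is.finite(ll_kernel(lp, y, n)))) break
      if (attempt == 10) stop("non-finite log-density at initialization",
                              call. = FALSE)
    }

    # adaptive proposal scales (log scale), frozen after burn-in
    ls <- list(a0 = 0, eta = rep(0, S), theta = rep(0, SC),
               gamma = rep(0, CT), tau = rep(-0.7, J))
    acc <- list(a0 = 0, eta = rep(0, S), theta = rep(0, SC),
                gamma = rep(0, CT), tau = rep(0, J))
    win <- 50L
    win_no <- 0L

    saved <- matrix(NA_real_, draws,
                    2L + S + SC + sum(!gamma_fixed) + sum(!delta_fixed) +
                      J + 1L + M)
    total <- burn_in + draws
    for (it in seq_len(total)) {
      if (prior_only) {
        # the joint prior is a directed model: sample it exactly,
        # ancestrally (parents before children)
        st$a0 <- stats::rnorm(1, 0, pr$sd_alpha0)
        st$a1 <- stats::runif(1, pr$alpha1_bounds[1], pr$alpha1_bounds[2])
        st$delta[!delta_fixed] <- stats::rnorm(sum(!delta_fixed), 0,
                                               pr$sd_delta)
        st$gamma[!gamma_fixed] <- stats::rnorm(sum(!gamma_fixed), 0,
                                               pr$sd_gamma)
        st$tau <- stats::runif(J, pr$tau_bounds[1], pr$tau_bounds[2])
        st$sig_eta <- 1 / sqrt(stats::rgamma(1, shape = pr$prec_eta_shape,
                                             rate = pr$prec_eta_rate))
        st$eta <- stats::rnorm(S, 0, st$sig_eta)
        st$xmis <- stats::rnorm(M)
        xv <- sc$x
        if (M) xv[mis] <- st$xmis
        st$theta <- stats::rnorm(SC, st$delta[sc_cl] + st$a1 * xv,
                                 st$tau[sc_cl])
        if (it > burn_in) {
          saved[it - burn_in, ] <- c(st$a0, st$a1, st$eta, st$theta,
                                     st$gamma[!gamma_fixed],
                                     st$delta[!delta_fixed],
                                     st$tau, st$sig_eta, st$xmis)
        }
        next
      }
      ll_obs <- ll_kernel(lp, y, n)

      # alpha0: scalar random walk
      d <- stats::rnorm(1) * exp(ls$a0)
      dlp <- sum(ll_kernel(lp + d, y, n)) - sum(ll_obs) +
        stats::dnorm(st$a0 + d, 0, pr$sd_alpha0, log = TRUE) -
        stats::dnorm(st$a0, 0, pr$sd_alpha0, log = TRUE)
      if (log(stats::runif(1)) < dlp) {
        st$a0 <- st$a0 + d
        lp <- lp + d
        acc$a0 <- acc$a0 + 1
        ll_obs <- ll_kernel(lp, y, n)
      }

      # eta: vectorised single-site (studies partition the observations)
      d <- stats::rnorm(S) * exp(ls$eta)
      dll <- rowsum(ll_kernel(lp + d[oi], y, n) - ll_obs, oi)[, 1]
      dpr <- stats::dnorm(st$eta + d, 0, st$sig_eta, log = TRUE) -
        stats::dnorm(st$eta, 0, st$sig_eta, log = TRUE)
      ok <- log(stats::runif(S)) < dll + dpr
      if (any(ok)) {
        st$eta[ok] <- st$eta[ok] + d[ok]
        lp <- lp + (d * ok)[oi]
        acc$eta <- acc$eta + ok
        ll_obs <- ll_kernel(lp, y, n)
      }

      # theta: vectorised single-site; prior N(delta_j + alpha1 x, tau_j)
      xv <- sc$x
      if (M) xv[mis] <- st$xmis
      th_mean <- st$delta[sc_cl] + st$a1 * xv
      th_sd <- st$tau[sc_cl]
      d <- stats::rnorm(SC) * exp(ls$theta)
      dll <- rowsum(ll_kernel(lp + d[os], y, n) - ll_obs, os)[, 1]
      dpr <- stats::dnorm(st$theta + d, th_mean, th_sd, log = TRUE) -
        stats::dnorm(st$theta, th_mean, th_sd, log = TRUE)
      ok <- log(stats::runif(SC)) < dll + dpr
      if (any(ok)) {
        st$theta[ok] <- st$theta[ok] + d[ok]
        lp <- lp + (d * ok)[os]
        acc$theta <- acc$theta + ok
        ll_obs <- ll_kernel(lp, y, n)
      }

      # gamma: vectorised single-site; prior N(0, 10); fixed entries skipped
      d <- stats::rnorm(CT) * exp(ls$gamma)
      d[gamma_fixed] <- 0
      dll <- rowsum(ll_kernel(lp + d[oc], y, n) - ll_obs, oc)[, 1]
      dpr <- stats::dnorm(st$gamma + d, 0, pr$sd_gamma, log = TRUE) -
        stats::dnorm(st$gamma, 0, pr$sd_gamma, log = TRUE)
      ok <- (log(stats::runif(CT)) < dll + dpr) & !gamma_fixed
      if (any(ok)) {
        st$gamma[ok] <- st$gamma[ok] + d[ok]
        lp <- lp + (d * ok)[oc]
        acc$gamma <- acc$gamma + ok
      }

      # delta: exact Gibbs (normal-normal given theta)
      resid <- st$theta - st$a1 * xv
      s1 <- rowsum(resid / st$tau[sc_cl]^2, sc_cl)[, 1]
      prec <- 1 / pr$sd_delta^2 + m_per_class / st$tau^2
      dm <- s1 / prec
      new_delta <- stats::rnorm(J, dm, 1 / sqrt(prec))
      st$delta[!delta_fixed] <- new_delta[!delta_fixed]

      # alpha1: exact Gibbs, normal truncated to (-5, 5)
      r2 <- st$theta - st$delta[sc_cl]
      prec1 <- sum(xv^2 / st$tau[sc_cl]^2)
      if (prec1 < 1e-12) {
        st$a1 <- stats::runif(1, pr$alpha1_bounds[1], pr$alpha1_bounds[2])
      } else {
        mu1 <- sum(xv * r2 / st$tau[sc_cl]^2) / prec1
        sd1 <- 1 / sqrt(prec1)
        lo <- stats::pnorm(pr$alpha1_bounds[1], mu1, sd1)
        hi <- stats::pnorm(pr$alpha1_bounds[2], mu1, sd1)
        if (hi - lo > 1e-12) {
          st$a1 <- stats::qnorm(stats::runif(1, lo, hi), mu1, sd1)
        } else {
          st$a1 <- max(min(mu1, pr$alpha1_bounds[2] - 1e-6),
                       pr$alpha1_bounds[1] + 1e-6)
        }
      }

      # missing x: exact Gibbs (prior N(0,1), likelihood through theta)
      if (M) {
        tj <- st$tau[sc_cl[mis]]
        precx <- 1 + st$a1^2 / tj^2
        mux <- (st$a1 * (st$theta[mis] - st$delta[sc_cl[mis]]) / tj^2) / precx
        st$xmis <- stats::rnorm(M, mux, 1 / sqrt(precx))
        xv[mis] <- st$xmis
      }

      # tau: vectorised random walk on the SD, uniform(0, 100) prior
      th_mean <- st$delta[sc_cl] + st$a1 * xv
      d <- stats::rnorm(J) * exp(ls$tau)
      tprop <- st$tau + d
      valid <- tprop > pr$tau_bounds[1] & tprop < pr$tau_bounds[2]
      tprop[!valid] <- st$tau[!valid]
      dpr <- rowsum(stats::dnorm(st$theta, th_mean, tprop[sc_cl], log = TRUE) -
                      stats::dnorm(st$theta, th_mean, st$tau[sc_cl],
                                   log = TRUE), sc_cl)[, 1]
      ok <- valid & (log(stats::runif(J)) < dpr)
      st$tau[ok] <- tprop[ok]
      acc$tau <- acc$tau + ok

      # study-effect precision: conjugate gamma Gibbs
      prec_eta <- stats::rgamma(1, shape = pr$prec_eta_shape + S / 2,
                                rate = pr$prec_eta_rate + sum(st$eta^2) / 2)
      st$sig_eta <- 1 / sqrt(prec_eta)

      # proposal-scale adaptation during burn-in
      if (it <= burn_in && it %% win == 0L) {
        win_no <- win_no + 1L
        step <- 1 / sqrt(win_no)
        tune <- function(l, a) {
          pmin(pmax(l + (a / win - 0.44) * step, -8), 8)
        }
        ls$a0 <- tune(ls$a0, acc$a0)
        ls$eta <- tune(ls$eta, acc$eta)
        ls$theta <- tune(ls$theta, acc$theta)
        ls$gamma <- tune(ls$gamma, acc$gamma)
        ls$tau <- tune(ls$tau, acc$tau)
        acc <- list(a0 = 0, eta = rep(0, S), theta = rep(0, SC),
                    gamma = rep(0, CT), tau = rep(0, J))
      }

      if (it > burn_in) {
        saved[it - burn_in, ] <- c(st$a0, st$a1, st$eta, st$theta,
                                   st$gamma[!gamma_fixed],
                                   st$delta[!delta_fixed],
                                   st$tau, st$sig_eta, st$xmis)
      }
    }
    colnames(saved) <- model$par_names
    chain_draws[[ch]] <- saved
  }

  structure(list(draws = chain_draws, par_names = model$par_names,
                 model = model, chains = chains, burn_in = burn_in,
                 draws_per_chain = draws, seed = as.integer(seed),
                 prior_only = prior_only),
            class = "mtc_draws")
}

#' @export
print.mtc_draws <- function(x, ...) {
  cat("Posterior draws:", x$chains, "chain(s) x", x$draws_per_chain,
      "iterations (", x$burn_in, "burn-in discarded ), ",
      length(x$par_names), "parameters, seed", x$seed, "\n")
  invisible(x)
}

#' @export
as.matrix.mtc_draws <- function(x, ...) do.call(rbind, x$draws)

#' Per-draw values of an identifiable linear combination
#'
#' Evaluates \code{alpha0 + delta[class] + gamma[class:time]} (resolving
#' corner-constrained parameters to 0) for every saved draw.
#'
#' @param fit an \code{mtc_draws}.
#' @param class treatment class code.
#' @param time follow-up time in months.
#' @param by_chain logical; return an iterations-by-chains matrix instead
#'   of one concatenated vector.
#' @return Numeric vector, one value per saved draw (chains concatenated),
#'   or a matrix with one column per chain when \code{by_chain = TRUE}.
#' @export
identifiable_sum <- function(fit, class, time, by_chain = FALSE) {
  class <- canonical_class(class)
  gname <- paste0("gamma[", class, ":", time, "]")
  dname <- paste0("delta[", class, "]")
  model <- fit$model
  if (!gname %in% fit$par_names && !gname %in% names(model$fixed)) {
    stop("no parameter for (", class, ", ", time,
         "): this (class, time) pair was not observed", call. = FALSE)
  }
  one <- function(m) {
    col_or_fixed <- function(nm) {
      if (nm %in% colnames(m)) m[, nm] else rep(model$fixed[[nm]], nrow(m))
    }
    m[, "alpha0"] + col_or_fixed(dname) + col_or_fixed(gname)
  }
  if (by_chain) {
    vapply(fit$draws, one, numeric(fit$draws_per_chain))
  } else {
    one(as.matrix(fit))
  }
}

#' Convergence report on identifiable quantities
#'
#' The default redundant parameterization leaves \eqn{\alpha_0},
#' \eqn{\delta_j} and \eqn{\gamma_{jt}} individually unidentified, so their
#' raw-parameter scale reduction factors are uninformative. This report
#' computes the Brooks-Gelman PSRF on what the analysis actually uses: the
#' identifiable sum \eqn{\alpha_0 + \delta_j + \gamma_{jt}} for every
#' observed (class, time) cell, plus the interpretable scalars
#' (\eqn{\alpha_1}, \eqn{\sigma_\eta}, the \eqn{\tau_j}).
#'
#' @param fit an \code{mtc_draws} with at least 2 chains.
#' @param threshold flag quantities whose PSRF exceeds this (default 1.1).
#' @return data.frame with \code{quantity}, \code{psrf}, \code{flagged}.
#' @export
convergence_report <- function(fit, threshold = 1.1) {
  stopifnot(inherits(fit, "mtc_draws"))
  if (fit$chains < 2L) stop("at least 2 chains are required", call. = FALSE)
  ct <- fit$model$ct
  sums <- lapply(seq_len(nrow(ct)), function(k) {
    identifiable_sum(fit, ct$class[k], ct$time[k], by_chain = TRUE)
  })
  scalars <- intersect(c("alpha1", "sigma_eta",
                         paste0("tau[", fit$model$classes, "]")),
                       fit$par_names)
  labels <- c(paste0("level[", ct$class, ":", ct$time, "]"), scalars)
  chains <- lapply(seq_len(fit$chains), function(ch) {
    m <- cbind(do.call(cbind, lapply(sums, function(s) s[, ch])),
               fit$draws[[ch]][, scalars, drop = FALSE])
    colnames(m) <- labels
    m
  })
  out <- gelman_rubin(chains)
  names(out)[names(out) == "param"] <- "quantity"
  out$flagged <- !is.na(out$psrf) & out$psrf > threshold
  out
}

#' Brooks-Gelman potential scale reduction factor
#'
#' Computes the Gelman-Rubin convergence diagnostic with the Brooks-Gelman
#' sampling-variability correction: \eqn{\hat R = \sqrt{\frac{d+3}{d+1}
#' \hat V / W}} where \eqn{W} is the mean within-chain variance, \eqn{\hat
#' V} the pooled variance estimate and \eqn{d} the estimated degrees of
#' freedom of \eqn{\hat V}. Values near 1 indicate convergence.
#'
#' @param fit an \code{mtc_draws} with at least 2 chains, or a list of
#'   numeric matrices/vectors (one per chain).
#' @param pars optional character vector restricting the parameters.
#' @return data.frame with columns \code{param} and \code{psrf}
#'   (\code{NA} with a warning for degenerate zero-variance chains).
#' @export
gelman_rubin <- function(fit, pars = NULL) {
  chains <- if (inherits(fit, "mtc_draws")) fit$draws else fit
  chains <- lapply(chains, function(x) {
    x <- as.matrix(x)
    if (is.null(colnames(x))) colnames(x) <- paste0("par", seq_len(ncol(x)))
    x
  })
  m <- length(chains)
  if (m < 2L) stop("at least 2 chains are required", call. = FALSE)
  n <- nrow(chains[[1L]])
  if (n < 10L) stop("need at least 10 draws per chain", call. = FALSE)
  params <- colnames(chains[[1L]])
  if (!is.null(pars)) params <- intersect(params, pars)
  psrf <- vapply(params, function(p) {
    xs <- vapply(chains, function(ch) ch[, p], numeric(n))
    xbar <- colMeans(xs)
    s2 <- apply(xs, 2, stats::var)
    W <- mean(s2)
    if (W == 0) return(NA_real_)
    B <- n * stats::var(xbar)
    vhat <- (n - 1) / n * W + (1 + 1 / m) * B / n
    muhat <- mean(xbar)
    cov_s2_xbar2 <- stats::cov(s2, xbar^2)
    cov_s2_xbar <- stats::cov(s2, xbar)
    var_vhat <- ((n - 1) / n)^2 / m * stats::var(s2) +
      ((m + 1) / (m * n))^2 * 2 / (m - 1) * B^2 +
      2 * (m + 1) * (n - 1) / (m * n^2) * n / m *
      (cov_s2_xbar2 - 2 * muhat * cov_s2_xbar)
    d <- 2 * vhat^2 / var_vhat
    sqrt((d + 3) / (d + 1) * vhat / W)
  }, numeric(1))
  if (anyNA(psrf)) {
    warning("zero within-chain variance for: ",
            paste(params[is.na(psrf)], collapse = ", "),
            "; PSRF undefined", call. = FALSE)
  }
  data.frame(param = params, psrf = unname(psrf), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Deterministic trace statistics
#'
#' Per-parameter segment means (the numeric content of a trace plot) and
#' lag-1 autocorrelation, averaged over chains. Constant series are flagged
#' with \code{NA} autocorrelation.
#'
#' @param fit an \code{mtc_draws} or a list of per-chain matrices.
#' @param pars optional character vector restricting the parameters.
#' @param segments number of equal iteration segments (default 4).
#' @return data.frame with the overall mean, one column per segment mean,
#'   \code{lag1_acf}, and a \code{degenerate} flag.
#' @export
trace_summary <- function(fit, pars = NULL, segments = 4L) {
  chains <- if (inherits(fit, "mtc_draws")) fit$draws else fit
  chains <- lapply(chains, as.matrix)
  n <- nrow(chains[[1L]])
  stopifnot(n >= segments)
  params <- colnames(chains[[1L]])
  if (is.null(params)) params <- paste0("par", seq_len(ncol(chains[[1L]])))
  if (!is.null(pars)) params <- intersect(params, pars)
  seg_id <- cut(seq_len(n), segments, labels = FALSE)
  rows <- lapply(params, function(p) {
    xs <- vapply(chains, function(ch) ch[, p], numeric(n))
    segs <- vapply(seq_len(segments), function(s) {
      mean(xs[seg_id == s, ])
    }, numeric(1))
    ac <- mean(vapply(seq_len(ncol(xs)), function(ch) {
      x <- xs[, ch]
      if (stats::sd(x) == 0) return(NA_real_)
      stats::cor(x[-1], x[-length(x)])
    }, numeric(1)))
    out <- data.frame(param = p, mean = mean(xs), stringsAsFactors = FALSE)
    for (s in seq_len(segments)) out[[paste0("seg", s)]] <- segs[s]
    out$lag1_acf <- ac
    out$degenerate <- is.na(ac)
    out
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Persist posterior draws as a columnar table
#'
#' Writes one row per saved iteration with chain and iteration indices
#' followed by the parameter columns (CSV), readable with any tabular tool.
#'
#' @param fit an \code{mtc_draws}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "mtc_draws"))
  tabs <- lapply(seq_along(fit$draws), function(ch) {
    cbind(data.frame(chain = ch, iteration = seq_len(nrow(fit$draws[[ch]]))),
          as.data.frame(fit$draws[[ch]]))
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}
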