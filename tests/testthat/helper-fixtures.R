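# shared in-code fixtures for the test suite

# minimal two-study, four-arm counts network
tiny_network <- function() {
  evidence_network(data.frame(
    study_id = c("A", "A", "B", "B"),
    class = c("LNG_IUS", "PLACEBO", "TXA", "PLACEBO"),
    time_months = 3L,
    scale = "MBL", form = "COUNTS",
    y = c(18, 4, 12, 5), n = c(20, 20, 25, 24),
    baseline_mean = c(150, 150, 210, 210),
    stringsAsFactors = FALSE))
}

# small effective-observation table with known indices for model tests;
# two studies, three classes, two times, one missing baseline
tiny_obs <- function() {
  data.frame(
    study_id = c("A", "A", "A", "B", "B"),
    arm = 1L,
    class = c("LNG_IUS", "PLACEBO", "PLACEBO", "TXA", "PLACEBO"),
    time_months = c(3L, 3L, 6L, 3L, 3L),
    scale = "MBL",
    p_hat = c(0.9, 0.2, 0.25, 0.5, 0.2),
    se = sqrt(c(0.9 * 0.1 / 20, 0.2 * 0.8 / 20, 0.25 * 0.75 / 20,
                0.5 * 0.5 / 25, 0.2 * 0.8 / 24)),
    y_eff = c(18, 4, 5, 12.5, 4.8),
    n_eff = c(20, 20, 20, 25, 24),
    provenance = "DIRECT_COUNTS",
    baseline_mean = c(150, 150, 150, NA, 210),
    stringsAsFactors = FALSE)
}

# named parameter vector with every component of a model set to zero
# (variance parameters set to the given positive values)
zero_params <- function(model, tau = 1, sigma_eta = 1) {
  p <- stats::setNames(rep(0, length(model$par_names)), model$par_names)
  p[grep("^tau\\[", names(p))] <- tau
  p["sigma_eta"] <- sigma_eta
  p
}

# construct an mtc_draws object from a bare matrix of draws (one chain)
fake_fit <- function(model, mat) {
  colnames(mat) <- model$par_names
  structure(list(draws = list(mat), par_names = model$par_names,
                 model = model, chains = 1L, burn_in = 0L,
                 draws_per_chain = nrow(mat), seed = 0L,
                 prior_only = FALSE),
            class = "mtc_draws")
}

# batch-means Monte Carlo standard error for a (possibly autocorrelated)
# chain of draws
batch_se <- function(x, n_batches = 40L) {
  n <- length(x)
  bm <- tapply(x, cut(seq_len(n), n_batches, labels = FALSE), mean)
  stats::sd(bm) / sqrt(n_batches)
}

# brute-force union-find over class pairs: independent oracle for
# connected components
uf_components <- function(edges, nodes) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      ra <- find(edges$a[k]); rb <- find(edges$b[k])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(nodes, find, character(1))
  unname(lapply(split(nodes, roots), sort))
}
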