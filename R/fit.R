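#' MCMC configuration for TPB model fits
#'
#' Defaults follow the package's standard run settings: four parallel
#' chains of 5,000 iterations with 2,000 warmups for fits without data
#' imputation, and (via [replicate_fit_and_pool()]) 2,000 iterations with
#' 1,500 warmups, thinned 1/2, for each imputed replicate.
#'
#' @param chains Number of chains (>= 2 for convergence diagnostics).
#' @param iter Iterations per chain, including warmup.
#' @param warmup Warmup iterations (`< iter`).
#' @param thin Thinning rate applied after warmup: `1` keeps everything,
#'   `1/2` keeps every second draw.
#' @param seed Integer seed for the sampler.
#' @param adapt_delta Target acceptance statistic for step-size adaptation.
#' @param max_treedepth Cap on NUTS doublings per iteration.
#' @param rhat_threshold Convergence is flagged when any rank-normalized
#'   split-Rhat exceeds this (default 1.01).
#' @return A list of class `tpb_config`.
#' @export
tpb_config <- function(chains = 4, iter = 5000, warmup = 2000, thin = 1,
                       seed = 1, adapt_delta = 0.8, max_treedepth = 10,
                       rhat_threshold = 1.01) {
  stopifnot(chains >= 1, warmup < iter, thin > 0, thin <= 1)
  structure(list(chains = chains, iter = iter, warmup = warmup, thin = thin,
                 seed = seed, adapt_delta = adapt_delta,
                 max_treedepth = max_treedepth,
                 rhat_threshold = rhat_threshold), class = "tpb_config")
}

#' Fit a TPB joint log-density by NUTS
#'
#' Samples a [tpb_model1()] / [tpb_model2()] density with [nuts_sample()],
#' transforms draws to the constrained scale (including the derived
#' per-record occurrence frequencies `p[i]`), applies thinning, and attaches
#' rank-normalized split-Rhat diagnostics and divergence counts.
#'
#' @param model A `tpb_model` object.
#' @param config A [tpb_config()].
#' @return An object of class `tpb_fit` whose `draws` element is an
#'   iterations x chains x parameters array on the constrained scale.
#' @export
tpb_sample <- function(model, config = tpb_config()) {
  stopifnot(inherits(model, "tpb_model"))
  init <- function(ch) {
    set.seed(.mix_seed(config$seed, 1000L + ch))
    stats::runif(model$n_par, -0.5, 0.5)
  }
  raw <- nuts_sample(model$lp_grad, init, n_par = model$n_par,
                     iter = config$iter, warmup = config$warmup,
                     chains = config$chains, seed = config$seed,
                     control = list(adapt_delta = config$adapt_delta,
                                    max_treedepth = config$max_treedepth))
  con <- lapply(raw$draws, function(m) .constrain_draws(model, m))
  fit <- .as_tpb_fit(con, model, config, raw)
  if (config$thin < 1) fit <- thin_draws(fit, config$thin)
  fit
}

.as_tpb_fit <- function(con_list, model, config, raw) {
  pn <- colnames(con_list[[1L]])
  d <- array(NA_real_, dim = c(nrow(con_list[[1L]]), length(con_list),
                               length(pn)),
             dimnames = list(NULL, NULL, pn))
  for (ch in seq_along(con_list)) d[, ch, ] <- con_list[[ch]]
  rh <- apply(d, 3, function(m) rhat(m))
  structure(list(
    draws = d, model_type = model$type, species = model$species,
    records_n = length(model$y), y = model$y, N = model$N,
    reported = model$reported, j = model$j,
    env_cols = model$env_cols, sp_cols = model$sp_cols,
    config = config,
    diagnostics = list(rhat = rh, divergences = raw$divergences,
                       step_size = raw$step_size,
                       treedepth = raw$treedepth,
                       accept_stat = raw$accept_stat),
    converged = all(is.na(rh) | rh <= config$rhat_threshold),
    pooled = FALSE
  ), class = "tpb_fit")
}

## unconstrained draw matrix (iter x n_par) -> constrained named matrix
.constrain_draws <- function(model, m) {
  ix <- model$index
  j <- model$j
  n <- length(model$y)
  theta <- exp(m[, ix$log_theta, drop = FALSE])
  tau <- theta[, j, drop = FALSE] * m[, ix$tau_raw, drop = FALSE]
  if (model$type == "model1") {
    alpha <- m[, ix$alpha, drop = FALSE]
    eta <- alpha[, j, drop = FALSE] + tau
    out <- cbind(
      if (model$est_psi) stats::plogis(m[, ix$psi]),
      alpha, theta, tau, stats::plogis(eta))
    colnames(out) <- c(if (model$est_psi) "psi",
                       paste0("alpha[", model$species, "]"),
                       paste0("theta[", model$species, "]"),
                       paste0("tau[", seq_len(n), "]"),
                       paste0("p[", seq_len(n), "]"))
  } else {
    s <- length(model$env_cols); t_ <- length(model$sp_cols)
    I0 <- m[, ix$I]
    omega <- exp(m[, ix$log_omega])
    phi <- omega * m[, ix$phi_raw, drop = FALSE]
    alpha <- I0 + phi
    if (t_) alpha <- alpha +
        m[, ix$eps, drop = FALSE] %*% t(model$Xsp)
    eta <- alpha[, j, drop = FALSE] + tau
    if (s) eta <- eta + m[, ix$beta, drop = FALSE] %*% t(model$Xenv)
    out <- cbind(
      if (model$est_psi) stats::plogis(m[, ix$psi]),
      I0,
      if (s) m[, ix$beta, drop = FALSE],
      if (t_) m[, ix$eps, drop = FALSE],
      omega, phi, alpha, theta, tau, stats::plogis(eta))
    colnames(out) <- c(if (model$est_psi) "psi", "I",
                       if (s) paste0("beta[", model$env_cols, "]"),
                       if (t_) paste0("eps[", model$sp_cols, "]"),
                       "omega",
                       paste0("phi[", model$species, "]"),
                       paste0("alpha[", model$species, "]"),
                       paste0("theta[", model$species, "]"),
                       paste0("tau[", seq_len(n), "]"),
                       paste0("p[", seq_len(n), "]"))
  }
  out
}

#' Thin the draws of a fit
#'
#' Keeps one of every `1/rate` consecutive post-warmup draws (so
#' `rate = 1/2` keeps every second draw), per chain, to reduce
#' autocorrelation in stored posteriors.
#'
#' @param fit A `tpb_fit`.
#' @param rate Thinning rate in (0, 1]; `1` is the identity.
#' @return The thinned `tpb_fit`.
#' @export
thin_draws <- function(fit, rate) {
  stopifnot(inherits(fit, "tpb_fit"), is.numeric(rate), rate > 0, rate <= 1)
  step <- as.integer(round(1 / rate))
  if (step == 1L) return(fit)
  keep <- seq(step, dim(fit$draws)[1L], by = step)
  fit$draws <- fit$draws[keep, , , drop = FALSE]
  fit
}

#' Fit a two-part binomial occurrence model
#'
#' Front end for the package's models of frequency-of-occurrence data with
#' missing-not-at-random reporting. `model = 1` estimates a per-species mean
#' occurrence frequency (species intercepts only); `model = 2` regresses the
#' logit frequency on record-level environmental predictors and
#' species-level predictors (log body mass, phylogenetic eigenvectors).
#' `method` selects how records that mention occurrence without quantifying
#' it are handled: ignored as unreported (`"none"`), imputed with uniform
#' random frequencies (`"random"`), or imputed from the posterior of the
#' non-imputed fit (`"posterior"`); the imputed variants fit
#' `n_replicates` imputed datasets and pool the posteriors
#' (see [replicate_fit_and_pool()]).
#'
#' @param records Record data frame (see [read_diet_records()] for the
#'   column contract).
#' @param species Species-level data frame (required for `model = 2`).
#' @param model `1` or `2`.
#' @param method `"none"`, `"random"` or `"posterior"`.
#' @param config A [tpb_config()]; for imputed methods this is the
#'   per-replicate sampler configuration.
#' @param psi_source For `method = "posterior"`: a converged non-imputed
#'   `tpb_fit` of the same model supplying the `p[i]` posteriors for
#'   imputation and the `psi` posterior. Defaults to fitting it internally.
#' @param n_replicates Number of imputation replicates to pool (default 10).
#' @param ... Passed on to [replicate_fit_and_pool()] for imputed methods.
#' @return A `tpb_fit` with `print`, `summary`, `coef`, `predict`, `plot`,
#'   `simulate` and `residuals` methods.
#' @examples
#' \donttest{
#' sim <- simulate_diet_data(simulation_truth(n_species = 6, seed = 1),
#'                           diet_design(n_records = 40, n_species = 6,
#'                                       seed = 1))
#' fit <- tpb(sim$records, model = 1,
#'            config = tpb_config(iter = 600, warmup = 300, chains = 2))
#' summary(fit, pars = "psi")
#' }
#' @export
tpb <- function(records, species = NULL,
                model = if (is.null(species)) 1 else 2,
                method = c("none", "random", "posterior"),
                config = tpb_config(), psi_source = NULL,
                n_replicates = 10, ...) {
  method <- match.arg(method)
  stopifnot(model %in% c(1, 2))
  if (model == 2 && is.null(species))
    stop("model 2 requires a species-level covariate table")
  if (method == "none") {
    m <- if (model == 1) tpb_model1(records)
         else tpb_model2(records, species)
    return(tpb_sample(m, config))
  }
  replicate_fit_and_pool(records, species = species, model = model,
                         method = method, n_replicates = n_replicates,
                         config = config, psi_source = psi_source, ...)
}

#' Persist a fit's draws and diagnostics
#'
#' Writes the posterior draws in long CSV format (`chain`, `iteration`,
#' `parameter`, `value`) plus a YAML diagnostics sidecar (Rhat per
#' parameter, divergences, step sizes, configuration).
#'
#' @param fit A `tpb_fit`.
#' @param dir Output directory (created if needed).
#' @param pars Parameters to persist (default: the summary set; use
#'   `dimnames(fit$draws)[[3]]` for everything).
#' @return The directory, invisibly.
#' @export
write_tpb_fit <- function(fit, dir, pars = NULL) {
  stopifnot(inherits(fit, "tpb_fit"))
  if (is.null(pars)) pars <- .summary_pars(fit)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(fit$draws)
  long <- do.call(rbind, lapply(pars, function(pp) {
    m <- draw_matrix(fit, pp)
    data.frame(chain = rep(seq_len(d[2L]), each = d[1L]),
               iteration = rep(seq_len(d[1L]), times = d[2L]),
               parameter = pp, value = as.vector(m),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, file.path(dir, "draws.csv"), row.names = FALSE)
  diag <- list(
    model_type = fit$model_type, pooled = isTRUE(fit$pooled),
    converged = fit$converged,
    rhat = as.list(fit$diagnostics$rhat[pars]),
    divergences = as.integer(fit$diagnostics$divergences),
    step_size = as.numeric(fit$diagnostics$step_size),
    config = unclass(fit$config))
  yaml::write_yaml(diag, file.path(dir, "diagnostics.yml"))
  invisible(dir)
}

#' Read a persisted draw table
#'
#' Inverse of [write_tpb_fit()] for the draw table only: returns the long
#' data frame written to `draws.csv`.
#'
#' @param dir Directory written by [write_tpb_fit()].
#' @return Data frame with columns `chain`, `iteration`, `parameter`,
#'   `value`.
#' @export
read_tpb_draws <- function(dir) {
  utils::read.csv(file.path(dir, "draws.csv"), stringsAsFactors = FALSE)
}

#' @export
print.tpb_fit <- function(x, ...) {
  d <- dim(x$draws)
  cat("Two-part binomial fit (", x$model_type,
      if (isTRUE(x$pooled)) ", pooled over imputation replicates", ")\n",
      sep = "")
  cat("  records:", x$records_n, " species:", length(x$species), "\n")
  cat("  draws:", d[1L], "iterations x", d[2L], "chains\n")
  rh <- x$diagnostics$rhat
  cat(sprintf("  max Rhat: %.3f  divergences: %d  converged: %s\n",
              max(rh, na.rm = TRUE), sum(x$diagnostics$divergences),
              x$converged))
  invisible(x)
}

#' Extract posterior draws of one parameter
#'
#' @param fit A `tpb_fit`.
#' @param par Parameter name, e.g. `"psi"`, `"eps[log_body_mass]"`,
#'   `"p[12]"`.
#' @param as_matrix Return an iterations x chains matrix instead of a
#'   single pooled vector.
#' @return Numeric vector (or matrix) of posterior draws.
#' @export
tpb_draws <- function(fit, par, as_matrix = FALSE) {
  stopifnot(inherits(fit, "tpb_fit"))
  if (as_matrix) draw_matrix(fit, par) else draw_vector(fit, par)
}

## draws for one parameter as an iterations x chains matrix
draw_matrix <- function(fit, par) {
  stopifnot(par %in% dimnames(fit$draws)[[3L]])
  fit$draws[, , par, drop = TRUE]
}

## all draws for one parameter as a single vector
draw_vector <- function(fit, par) as.vector(draw_matrix(fit, par))

## parameters reported in coefficient/frequency summary tables
.summary_pars <- function(fit) {
  pn <- dimnames(fit$draws)[[3L]]
  if (fit$model_type == "model1") {
    pn[!grepl("^(tau|p|theta)\\[", pn)]
  } else {
    pn[!grepl("^(tau|p|alpha|phi|theta)\\[", pn)]
  }
}

#' Summarize a TPB fit
#'
#' One row per parameter with the package's posterior summary set: MAP
#' (posterior mode via kernel density), 89% HDI, EAP (posterior mean), 95%
#' and 90% equal-tailed credible intervals, the fraction of 89%-HDI draws
#' inside the ROPE \[-0.1, 0.1\], the two significance verdicts (HDI+ROPE and
#' 95% CI excluding zero), and Rhat.
#'
#' @param object A `tpb_fit`.
#' @param pars Parameter names (default: model coefficients and global
#'   parameters; per-record quantities are excluded).
#' @param rope ROPE bounds for the equivalence decision.
#' @param hdi_mass HDI probability mass (default 0.89).
#' @param ... Unused.
#' @return A data frame of class `summary.tpb_fit`.
#' @export
summary.tpb_fit <- function(object, pars = NULL, rope = rope_spec(),
                            hdi_mass = 0.89, ...) {
  if (is.null(pars)) pars <- .summary_pars(object)
  rows <- lapply(pars, function(pp) {
    x <- draw_vector(object, pp)
    h <- hdi(x, hdi_mass)
    c95 <- credible_interval(x, 0.95)
    c90 <- credible_interval(x, 0.90)
    rd <- rope_decision(x, rope, hdi_mass)
    data.frame(parameter = pp,
               MAP = map_estimate(x),
               hdi_lower = h[1L], hdi_upper = h[2L],
               EAP = mean(x),
               ci95_lower = c95[1L], ci95_upper = c95[2L],
               ci90_lower = c90[1L], ci90_upper = c90[2L],
               pct_hdi_in_rope = rd$pct_inside,
               significant_rope = rd$significant,
               significant_ci = ci_significance(x, 0.95),
               rhat = unname(object$diagnostics$rhat[pp]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("summary.tpb_fit", "data.frame")
  out
}

#' @export
print.summary.tpb_fit <- function(x, digits = 3, ...) {
  y <- x
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' @export
coef.tpb_fit <- function(object, estimate = c("EAP", "MAP"), ...) {
  estimate <- match.arg(estimate)
  pars <- .summary_pars(object)
  vapply(pars, function(pp) {
    x <- draw_vector(object, pp)
    if (estimate == "EAP") mean(x) else map_estimate(x)
  }, numeric(1))
}

#' @export
predict.tpb_fit <- function(object, type = c("frequency", "count"),
                            estimate = c("EAP", "MAP"), ...) {
  type <- match.arg(type); estimate <- match.arg(estimate)
  p <- vapply(seq_len(object$records_n), function(i) {
    x <- draw_vector(object, paste0("p[", i, "]"))
    if (estimate == "EAP") mean(x) else map_estimate(x)
  }, numeric(1))
  if (type == "frequency") p else p * object$N
}

#' @export
residuals.tpb_fit <- function(object, ...) {
  p <- predict(object, type = "frequency")
  ifelse(object$reported, object$y / object$N - p, NA_real_)
}

#' @export
simulate.tpb_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$records_n
  d <- dim(object$draws)
  total <- d[1L] * d[2L]
  idx <- sample.int(total, nsim, replace = nsim > total)
  P <- matrix(object$draws[, , paste0("p[", seq_len(n), "]"), drop = FALSE],
              nrow = total)
  out <- matrix(NA_integer_, nsim, n)
  for (k in seq_len(nsim))
    out[k, ] <- stats::rbinom(n, object$N, P[idx[k], ])
  out
}

#' @export
plot.tpb_fit <- function(x, pars = NULL, rope = rope_spec(), ...) {
  s <- summary(x, pars = pars)
  k <- nrow(s)
  graphics::plot(NULL, xlim = range(s$hdi_lower, s$hdi_upper, 0),
                 ylim = c(0.5, k + 0.5), yaxt = "n",
                 xlab = "MAP estimate with 89% HDI", ylab = "",
                 main = "Posterior coefficient intervals")
  graphics::rect(rope[1L], 0.5, rope[2L], k + 0.5,
                 col = grDevices::grey(0.9), border = NA)
  graphics::abline(v = 0)
  graphics::segments(s$hdi_lower, seq_len(k), s$hdi_upper, seq_len(k))
  graphics::points(s$MAP, seq_len(k), pch = 16)
  graphics::axis(2, at = seq_len(k), labels = s$parameter, las = 1,
                 cex.axis = 0.7)
  invisible(s)
}
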