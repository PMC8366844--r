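## round half up, then clamp into [1, N]: a mentioned record implies at
## least one positive sample
.impute_count <- function(p, N) pmin(pmax(floor(p * N + 0.5), 1), N)

#' Impute mentioned-but-unquantified records with random frequencies
#'
#' For each record that mentions occurrence without quantifying it, an
#' occurrence frequency is drawn uniformly from the grid 0.01, 0.02, ...,
#' 1.00 and the count imputed as `y = clamp(round(p * N), 1, N)`. All other
#' rows are untouched.
#'
#' @param records Validated record data frame.
#' @param seed Integer seed.
#' @return The records with imputed `y` on mentioned rows (which become
#'   reported for likelihood purposes), carrying attributes `method`,
#'   `seed` and `imputed_rows`.
#' @export
impute_random <- function(records, seed = 1) {
  df <- as.data.frame(records)
  rows <- which(as.logical(df$mentioned) & is.na(df$y))
  if (!length(rows)) {
    warning("no mentioned-but-unquantified records; nothing to impute")
    return(structure(df, method = "random", seed = seed,
                     imputed_rows = integer(0)))
  }
  set.seed(seed)
  p <- sample(seq(0.01, 1, by = 0.01), length(rows), replace = TRUE)
  df$y[rows] <- as.integer(.impute_count(p, df$N[rows]))
  df$reported <- !is.na(df$y)
  structure(df, method = "random", seed = seed, imputed_rows = rows,
            imputed_p = p)
}

#' Bin a record's posterior occurrence frequency
#'
#' Histogram of the posterior draws of `p[i]` on a uniform grid over
#' (0, 1], with the bin containing zero excluded before renormalization
#' (only nonzero frequencies can be imputed for a record that mentions
#' occurrence). Bin widths of 0.005 (species-intercept model) and 0.01
#' (covariate model) keep the zero bin from swallowing the whole posterior.
#'
#' @param fit A `tpb_fit` containing draws of `p[record]`.
#' @param record Record index (position in the fitted record table).
#' @param bin_width Uniform bin width dividing 1.
#' @return Object of class `posterior_bins`: `bin_mid`, `prob` (sums to 1),
#'   `bin_width`.
#' @export
bin_posterior <- function(fit, record, bin_width = 0.01) {
  stopifnot(inherits(fit, "tpb_fit"), bin_width > 0, bin_width < 1)
  p <- draw_vector(fit, paste0("p[", record, "]"))
  edges <- seq(0, 1, by = bin_width)
  if (abs(edges[length(edges)] - 1) > 1e-12) edges <- c(edges, 1)
  counts <- tabulate(findInterval(p, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  counts[1L] <- 0L  # the bin containing zero is excluded
  if (sum(counts) == 0L)
    stop("all posterior draws fall in the zero bin; use a finer bin_width")
  mid <- (edges[-length(edges)] + edges[-1L]) / 2
  keep <- counts > 0L
  structure(list(bin_mid = mid[keep], prob = counts[keep] / sum(counts),
                 bin_width = bin_width, record = record),
            class = "posterior_bins")
}

#' Impute mentioned records from posterior bin distributions
#'
#' For each mentioned record, an occurrence frequency is sampled from that
#' record's binned posterior (bins represented by their midpoints) and the
#' count imputed as `y = clamp(round(p * N), 1, N)`.
#'
#' @param records Validated record data frame.
#' @param bins Named list of [bin_posterior()] results, one per mentioned
#'   record, names = record row indices as character.
#' @param seed Integer seed.
#' @return As [impute_random()], with `method = "posterior"`.
#' @export
impute_from_posterior <- function(records, bins, seed = 1) {
  df <- as.data.frame(records)
  rows <- which(as.logical(df$mentioned) & is.na(df$y))
  if (!length(rows)) {
    warning("no mentioned-but-unquantified records; nothing to impute")
    return(structure(df, method = "posterior", seed = seed,
                     imputed_rows = integer(0)))
  }
  miss <- setdiff(as.character(rows), names(bins))
  if (length(miss))
    stop("no posterior bins supplied for mentioned record(s) ",
         paste(miss, collapse = ", "))
  set.seed(seed)
  p <- vapply(as.character(rows), function(k) {
    b <- bins[[k]]
    if (length(b$bin_mid) == 1L) b$bin_mid else
      sample(b$bin_mid, 1L, prob = b$prob)
  }, numeric(1))
  df$y[rows] <- as.integer(.impute_count(p, df$N[rows]))
  df$reported <- !is.na(df$y)
  structure(df, method = "posterior", seed = seed, imputed_rows = rows,
            imputed_p = unname(p))
}

#' Replicate imputed fits and pool their posteriors
#'
#' The imputed-data protocol: repeat `n_replicates` times with distinct
#' seeds — impute the mentioned records ([impute_random()] or
#' [impute_from_posterior()]), fit the model, thin at 1/2 — and concatenate
#' the post-warmup draws across replicates. Under the posterior method,
#' the reporting probability is not re-estimated on the imputed data
#' (imputing makes its Bernoulli factors meaningless); instead `psi` draws
#' are resampled from the non-imputed fit's posterior, matching the draw
#' layout of the pooled fit.
#'
#' @param records Validated record data frame.
#' @param species Species table (required for `model = 2`).
#' @param model `1` or `2`.
#' @param method `"random"` or `"posterior"`.
#' @param n_replicates Number of imputation replicates (default 10).
#' @param config Per-replicate [tpb_config()]; the defaults for imputed
#'   fits are 2,000 iterations with 1,500 warmups.
#' @param psi_source A converged non-imputed `tpb_fit` of the same model;
#'   it supplies the `psi` posterior for both methods and additionally the
#'   `p[i]` posteriors for `method = "posterior"`. Fitted internally with
#'   the non-imputed defaults when `NULL`.
#' @param bin_width Posterior bin width; defaults to 0.005 for model 1 and
#'   0.01 for model 2.
#' @param thin_rate Thinning applied per replicate (default 1/2).
#' @return A pooled `tpb_fit` (`pooled = TRUE`) whose draws stack the
#'   thinned replicate draws; `replicates` holds per-replicate seeds and
#'   convergence diagnostics.
#' @export
replicate_fit_and_pool <- function(records, species = NULL, model = 1,
                                   method = c("random", "posterior"),
                                   n_replicates = 10,
                                   config = tpb_config(iter = 2000,
                                                       warmup = 1500),
                                   psi_source = NULL,
                                   bin_width = NULL, thin_rate = 1 / 2) {
  method <- match.arg(method)
  stopifnot(model %in% c(1, 2), n_replicates >= 1)
  records <- as.data.frame(records)
  if (model == 2 && is.null(species))
    stop("model 2 requires a species-level covariate table")
  if (is.null(bin_width)) bin_width <- if (model == 1) 0.005 else 0.01

  if (is.null(psi_source)) {
    m0 <- if (model == 1) tpb_model1(records)
          else tpb_model2(records, species)
    psi_source <- tpb_sample(m0, tpb_config(seed = .mix_seed(config$seed,
                                                             901L)))
  }
  if (!isTRUE(psi_source$converged))
    warning("psi_source fit is flagged non-converged")
  psi_bar <- mean(draw_vector(psi_source, "psi"))
  bins <- NULL
  if (method == "posterior") {
    rows <- which(as.logical(records$mentioned) & is.na(records$y))
    bins <- stats::setNames(
      lapply(rows, function(i) bin_posterior(psi_source, i, bin_width)),
      as.character(rows))
  }

  fits <- vector("list", n_replicates)
  rep_seeds <- vapply(seq_len(n_replicates),
                      function(r) .mix_seed(config$seed, 100L + r),
                      integer(1))
  for (r in seq_len(n_replicates)) {
    imp <- if (method == "random")
      impute_random(records, seed = rep_seeds[r])
    else
      impute_from_posterior(records, bins, seed = rep_seeds[r])
    cfg <- config
    cfg$seed <- rep_seeds[r]
    ## psi is never re-estimated on imputed data: its Bernoulli factors
    ## are constants here, and psi draws come from the non-imputed fit
    m <- if (model == 1) tpb_model1(imp, psi_fixed = psi_bar)
         else tpb_model2(imp, species, psi_fixed = psi_bar)
    f <- tpb_sample(m, cfg)
    f <- thin_draws(f, thin_rate)
    if (!f$converged)
      warning("replicate ", r, " flagged non-converged (max Rhat ",
              sprintf("%.3f", max(f$diagnostics$rhat, na.rm = TRUE)), ")")
    fits[[r]] <- f
  }

  pooled <- fits[[1L]]
  if (n_replicates > 1) {
    pooled$draws <- do.call(abind_iterations,
                            lapply(fits, function(f) f$draws))
  }
  {
    ## psi is externally sampled from the non-imputed posterior
    psi_draws <- draw_vector(psi_source, "psi")
    d <- dim(pooled$draws)
    set.seed(.mix_seed(config$seed, 777L))
    psi_arr <- array(sample(psi_draws, d[1L] * d[2L], replace = TRUE),
                     dim = c(d[1L], d[2L], 1L))
    nm <- c(dimnames(pooled$draws)[[3L]], "psi")
    pooled$draws <- array(c(pooled$draws, psi_arr),
                          dim = c(d[1L], d[2L], d[3L] + 1L),
                          dimnames = list(NULL, NULL, nm))
  }
  per_rep_rhat <- vapply(fits, function(f)
    max(f$diagnostics$rhat, na.rm = TRUE), numeric(1))
  pooled$pooled <- TRUE
  pooled$replicates <- list(
    method = method, n_replicates = n_replicates, seeds = rep_seeds,
    max_rhat = per_rep_rhat,
    converged = vapply(fits, function(f) f$converged, logical(1)),
    divergences = vapply(fits, function(f)
      sum(f$diagnostics$divergences), integer(1)))
  pooled$diagnostics$rhat <- apply(pooled$draws, 3, rhat)
  pooled$converged <- all(pooled$replicates$converged)
  pooled
}

## stack draw arrays along the iteration dimension
abind_iterations <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1L]])
  stopifnot(all(vapply(arrs, function(a)
    identical(dim(a)[2:3], d[2:3]), logical(1))))
  iters <- vapply(arrs, function(a) dim(a)[1L], integer(1))
  out <- array(NA_real_, dim = c(sum(iters), d[2L], d[3L]),
               dimnames = list(NULL, NULL, dimnames(arrs[[1L]])[[3L]]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1L]), , ] <- a
    at <- at + dim(a)[1L]
  }
  out
}
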