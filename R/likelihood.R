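#' Two-part binomial log-likelihood
#'
#' Log-likelihood of one or more records under the two-part binomial (TPB)
#' observation model: whether a study reports the occurrence count at all is
#' Bernoulli with reporting probability `psi`; when the count is reported it
#' is Binomial(N, p). Unreported records therefore contribute
#' `log(1 - psi)` and carry no information about `p`; reported records
#' contribute `log(psi) + log dbinom(y, N, p)`.
#'
#' @param y Integer vector of occurrence counts; `NA` marks an unreported
#'   record.
#' @param N Integer vector of sample sizes (recycled against `y`).
#' @param psi Reporting probability, scalar in (0, 1).
#' @param p Per-record occurrence frequency in (0, 1) (recycled). Ignored
#'   for unreported records. Boundary values of `p` are admitted only when
#'   `y` sits at the matching boundary (`p = 0` with `y = 0`, `p = 1` with
#'   `y = N`).
#' @return Numeric vector of per-record log-likelihood contributions.
#' @examples
#' tpb_loglik(NA, 20, psi = 0.5, p = 0.3)   # log(0.5), p irrelevant
#' tpb_loglik(3, 10, psi = 0.37, p = 0.2)
#' @export
tpb_loglik <- function(y, N, psi, p) {
  stopifnot(length(psi) == 1L, is.finite(psi), psi > 0, psi < 1)
  n <- max(length(y), length(N), length(p))
  y <- rep_len(y, n); N <- rep_len(N, n); p <- rep_len(p, n)
  if (any(N < 1 | N != floor(N), na.rm = TRUE))
    stop("N must be a positive integer sample size")
  rep_ok <- !is.na(y)
  if (any(y[rep_ok] < 0 | y[rep_ok] > N[rep_ok]))
    stop("reported records require 0 <= y <= N")
  out <- numeric(n)
  out[!rep_ok] <- log1p(-psi)
  if (any(rep_ok)) {
    out[rep_ok] <- log(psi) +
      stats::dbinom(y[rep_ok], N[rep_ok], p[rep_ok], log = TRUE)
  }
  out
}

## columns of the record table that enter Model 2 as record-level predictors,
## in the order the coefficient table reports them
tpb_env_cols <- function() {
  c("island", "precip", "tmax", "tmin", "ndvi",
    "spring", "summer", "autumn", "winter", "dry", "wet", "sample_type")
}

.check_records_min <- function(records) {
  need <- c("species_id", "y", "N")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("record table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(records$N < 1)) stop("all N must be >= 1")
  rep_ok <- !is.na(records$y)
  bad <- which(rep_ok & (records$y < 0 | records$y > records$N))
  if (length(bad))
    stop("row ", bad[1L], ": reported y outside [0, N]")
  invisible(records)
}

#' Joint log-density of Model 1 (species-intercept model)
#'
#' Builds the unnormalized joint log-posterior of the hierarchical TPB model
#' in which each species has its own mean occurrence frequency:
#' `logit(p_i) = alpha_j + tau_i` with `tau_i ~ Normal(0, theta_j^2)`, a
#' per-species record-level overdispersion scale `theta_j`. Priors:
#' `alpha_j ~ Student-t(3, 0, 5)`, `theta_j ~ Exponential(1)`, and a
#' Uniform(0, 1) prior on the reporting probability `psi`.
#'
#' The returned object holds the log-density and its analytic gradient on an
#' unconstrained parameterization (logit for `psi`, log for `theta`,
#' non-centered `tau_i = theta_j * tau_raw_i`); the non-centering changes
#' sampler geometry only, never the density value on the constrained scale.
#'
#' @param records Record data frame with at least `species_id`, `y`
#'   (`NA` = unreported), `N`. The species set is taken from the records,
#'   so a species with zero records never enters the parameter vector.
#' @param psi_fixed Optional fixed value for `psi`; when supplied, `psi` is
#'   removed from the parameter vector and its Bernoulli factors become
#'   constants (used by imputed refits where `psi` is sampled externally).
#' @return An object of class `tpb_model`; see [tpb()] for fitting.
#' @seealso [tpb_model2()], [tpb()], [nuts_sample()]
#' @export
tpb_model1 <- function(records, psi_fixed = NULL) {
  records <- as.data.frame(records)
  .check_records_min(records)
  species <- unique(as.character(records$species_id))
  sp <- factor(as.character(records$species_id), levels = species)
  j <- as.integer(sp)
  J <- length(species)
  n <- nrow(records)
  y <- records$y
  N <- records$N
  reported <- !is.na(y)
  est_psi <- is.null(psi_fixed)

  idx <- list()
  k <- 0L
  if (est_psi) { idx$psi <- 1L; k <- 1L }
  idx$alpha <- k + seq_len(J);      k <- k + J
  idx$log_theta <- k + seq_len(J);  k <- k + J
  idx$tau_raw <- k + seq_len(n);    k <- k + n

  y0 <- as.double(ifelse(reported, y, 0))
  Nd <- as.double(N)
  j0 <- j - 1L
  sum_lchoose <- sum(lchoose(N[reported], y[reported]))
  psi_pass <- if (est_psi) 0.5 else psi_fixed

  lp_grad <- function(q) {
    .model1_lp_grad_cpp(q, j0, y0, Nd, reported, J, est_psi, psi_pass,
                        sum_lchoose)
  }

  structure(list(
    type = "model1", lp_grad = lp_grad, n_par = k, index = idx,
    species = species, j = j, y = y, N = N, reported = reported,
    est_psi = est_psi, psi_fixed = psi_fixed,
    par_names = c(if (est_psi) "psi_logit",
                  paste0("alpha[", species, "]"),
                  paste0("log_theta[", species, "]"),
                  paste0("tau_raw[", seq_len(n), "]"))
  ), class = "tpb_model")
}

#' Joint log-density of Model 2 (covariate regression model)
#'
#' Extends Model 1 by regressing the logit occurrence frequency on
#' record-level environmental predictors and species-level predictors
#' (log body mass and phylogenetic eigenvectors):
#' `logit(p_i) = alpha_j + sum_k beta_k X_env[i,k] + tau_i` with
#' `alpha_j = I + sum_l eps_l X_sp[j,l] + phi_j`,
#' `phi_j ~ Normal(0, omega^2)`, `tau_i ~ Normal(0, theta_j^2)`. Priors:
#' Student-t(3, 0, 5) on `I`, `beta`, `eps`; Exponential(1) on `omega` and
#' each `theta_j`; Uniform(0, 1) on `psi`.
#'
#' @inheritParams tpb_model1
#' @param species Species-level data frame with `species_id` plus the
#'   columns named in `sp_cols`; must cover every species in `records`.
#' @param env_cols Record-table columns used as environmental predictors
#'   (default [tpb_env_cols()]); any subset, possibly empty.
#' @param sp_cols Species-table predictor columns; defaults to
#'   `log_body_mass` followed by every `PV*` column present.
#' @return An object of class `tpb_model`.
#' @export
tpb_model2 <- function(records, species, env_cols = tpb_env_cols(),
                       sp_cols = NULL, psi_fixed = NULL) {
  records <- as.data.frame(records)
  species <- as.data.frame(species)
  .check_records_min(records)
  sp_levels <- unique(as.character(records$species_id))
  if (!all(sp_levels %in% as.character(species$species_id)))
    stop("species table is missing species present in the records")
  species <- species[match(sp_levels, as.character(species$species_id)), ,
                     drop = FALSE]
  if (is.null(sp_cols)) {
    sp_cols <- intersect("log_body_mass", names(species))
    sp_cols <- c(sp_cols, grep("^PV[0-9]+$", names(species), value = TRUE))
  }
  miss <- setdiff(env_cols, names(records))
  if (length(miss))
    stop("record table lacks predictor column(s): ",
         paste(miss, collapse = ", "))
  miss <- setdiff(sp_cols, names(species))
  if (length(miss))
    stop("species table lacks predictor column(s): ",
         paste(miss, collapse = ", "))

  jf <- factor(as.character(records$species_id), levels = sp_levels)
  j <- as.integer(jf)
  J <- length(sp_levels)
  n <- nrow(records)
  Xenv <- as.matrix(records[, env_cols, drop = FALSE])
  Xsp <- as.matrix(species[, sp_cols, drop = FALSE])
  storage.mode(Xenv) <- "double"; storage.mode(Xsp) <- "double"
  if (anyNA(Xenv) || anyNA(Xsp)) stop("predictors must not contain NA")
  s <- ncol(Xenv); t_ <- ncol(Xsp)
  y <- records$y; N <- records$N
  reported <- !is.na(y)
  est_psi <- is.null(psi_fixed)

  idx <- list(); k <- 0L
  if (est_psi) { idx$psi <- 1L; k <- 1L }
  idx$I <- k + 1L; k <- k + 1L
  if (s) { idx$beta <- k + seq_len(s); k <- k + s }
  if (t_) { idx$eps <- k + seq_len(t_); k <- k + t_ }
  idx$log_omega <- k + 1L; k <- k + 1L
  idx$phi_raw <- k + seq_len(J); k <- k + J
  idx$log_theta <- k + seq_len(J); k <- k + J
  idx$tau_raw <- k + seq_len(n); k <- k + n

  y0 <- as.double(ifelse(reported, y, 0))
  Nd <- as.double(N)
  j0 <- j - 1L
  sum_lchoose <- sum(lchoose(N[reported], y[reported]))
  psi_pass <- if (est_psi) 0.5 else psi_fixed

  lp_grad <- function(q) {
    .model2_lp_grad_cpp(q, j0, y0, Nd, reported, Xenv, Xsp, J, est_psi,
                        psi_pass, sum_lchoose)
  }

  structure(list(
    type = "model2", lp_grad = lp_grad, n_par = k, index = idx,
    species = sp_levels, j = j, y = y, N = N, reported = reported,
    Xenv = Xenv, Xsp = Xsp, env_cols = env_cols, sp_cols = sp_cols,
    est_psi = est_psi, psi_fixed = psi_fixed,
    par_names = c(if (est_psi) "psi_logit", "I",
                  if (s) paste0("beta[", env_cols, "]"),
                  if (t_) paste0("eps[", sp_cols, "]"),
                  "log_omega",
                  paste0("phi_raw[", sp_levels, "]"),
                  paste0("log_theta[", sp_levels, "]"),
                  paste0("tau_raw[", seq_len(n), "]"))
  ), class = "tpb_model")
}

#' @export
print.tpb_model <- function(x, ...) {
  cat("Two-part binomial joint log-density (", x$type, ")\n", sep = "")
  cat("  records:", length(x$y), " species:", length(x$species), "\n")
  cat("  parameters:", x$n_par,
      if (x$est_psi) "(psi estimated)" else
        sprintf("(psi fixed at %.3f)", x$psi_fixed), "\n")
  invisible(x)
}
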