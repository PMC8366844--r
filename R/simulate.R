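#' Simulate a random ultrametric phylogeny
#'
#' Coalescent-style random topology with exponential waiting times, giving
#' strictly positive branch lengths; any such tree exercises the
#' phylogenetic eigenvector machinery. Deterministic for a fixed seed.
#'
#' @param n_species Number of tips (>= 2).
#' @param seed Integer seed.
#' @return A `phylo` object with tip labels `sp01, sp02, ...`.
#' @export
simulate_phylogeny <- function(n_species, seed = 1) {
  if (n_species < 2) stop("need at least 2 species")
  set.seed(.mix_seed(seed, 17L))
  tr <- ape::rcoal(n_species,
                   tip.label = sprintf("sp%02d", seq_len(n_species)))
  ## guard against zero-length edges from coalescent ties
  tr$edge.length <- pmax(tr$edge.length, 1e-6)
  tr
}

#' Ground truth for the synthetic-data generator
#'
#' Collects the generative parameters of the covariate model: reporting
#' probability `psi`, global logit-scale intercept, environmental and
#' species-covariate coefficients, the species-effect SD `omega` and the
#' per-species record-effect SDs `theta`. Defaults emulate the structure of
#' the carnivore plant-occurrence literature data: 24 species, reporting
#' probability 0.37, a clear negative body-mass effect and no environmental
#' effects, with appreciable between-record and between-species
#' overdispersion.
#'
#' @param n_species Number of species.
#' @param psi Reporting probability in (0, 1].
#' @param global_intercept Logit-scale intercept `I`.
#' @param env_coefficients Named vector over [tpb_env_cols()] (defaults to
#'   all zero; unnamed vectors must have length 12).
#' @param species_coefficients Coefficients of the species covariates, body
#'   mass first then PV axes; default `c(log_body_mass = -0.8)` and zero
#'   for `n_pv_axes` eigenvector axes.
#' @param omega SD of the species-level effect `phi_j` (> 0).
#' @param theta Vector of per-species record-effect SDs (> 0; recycled).
#' @param n_pv_axes Number of eigenvector axes carrying (zero by default)
#'   true coefficients.
#' @param mentioned_prob Probability that an unreported record with latent
#'   `y >= 1` is flagged "mentioned-but-unquantified" (default 0.12,
#'   echoing 23 mentioned of 198 unreported records).
#' @param seed Integer seed used by [simulate_diet_data()].
#' @return Object of class `simulation_truth`.
#' @export
simulation_truth <- function(n_species = 24, psi = 0.37,
                             global_intercept = -2,
                             env_coefficients = NULL,
                             species_coefficients = NULL,
                             omega = 0.5, theta = 0.8, n_pv_axes = 5,
                             mentioned_prob = 0.12, seed = 1) {
  stopifnot(psi > 0, psi <= 1, omega > 0, all(theta > 0), n_species >= 2)
  env_names <- tpb_env_cols()
  if (is.null(env_coefficients)) {
    env_coefficients <- stats::setNames(rep(0, length(env_names)), env_names)
  } else {
    if (is.null(names(env_coefficients))) {
      stopifnot(length(env_coefficients) == length(env_names))
      names(env_coefficients) <- env_names
    } else {
      full <- stats::setNames(rep(0, length(env_names)), env_names)
      full[names(env_coefficients)] <- env_coefficients
      env_coefficients <- full
    }
  }
  if (is.null(species_coefficients)) {
    species_coefficients <- c(log_body_mass = -0.8,
                              stats::setNames(rep(0, n_pv_axes),
                                              paste0("PV", seq_len(n_pv_axes))))
  }
  structure(list(
    n_species = n_species, psi = psi, global_intercept = global_intercept,
    env_coefficients = env_coefficients,
    species_coefficients = species_coefficients,
    omega = omega, theta = rep_len(theta, n_species),
    n_pv_axes = n_pv_axes, mentioned_prob = mentioned_prob,
    species_intercepts = NULL, record_effects = NULL, seed = seed
  ), class = "simulation_truth")
}

#' Record-layout design for the synthetic-data generator
#'
#' How many records each species contributes, the sample sizes, and the
#' covariate distributions. Defaults mirror the shape of the literature
#' dataset: 316 records over 24 species with a strongly skewed allocation
#' (a few well-studied species, several singletons), sample sizes of 10 or
#' more, continuous covariates uniform over plausible ranges, and seasons
#' as mutually exclusive dummies with an all-zero "whole-year" option.
#'
#' @param n_records Total number of records.
#' @param n_species Number of species (must match the truth).
#' @param record_counts Optional integer vector of per-species record
#'   counts summing to `n_records`; default: a skewed allocation with at
#'   least one record per species.
#' @param N_range Range of per-record sample sizes (uniform integer draw).
#' @param precip_range,tmax_range,ndvi_range Ranges of the raw covariates;
#'   `tmin` is drawn 5-20 degrees below `tmax`.
#' @param p_island,p_digestive Probabilities of the island flag and of the
#'   digestive-tract sample type.
#' @param seed Integer seed for the allocation draw.
#' @return Object of class `diet_design`.
#' @export
diet_design <- function(n_records = 316, n_species = 24,
                        record_counts = NULL, N_range = c(10, 300),
                        precip_range = c(0, 400), tmax_range = c(-5, 40),
                        ndvi_range = c(0, 0.9), p_island = 0.2,
                        p_digestive = 0.3, seed = 1) {
  stopifnot(n_records >= n_species, N_range[1L] >= 1)
  if (is.null(record_counts)) {
    set.seed(.mix_seed(seed, 23L))
    w <- sort(stats::rexp(n_species, rate = 1), decreasing = TRUE)
    record_counts <- rep(1L, n_species)
    extra <- stats::rmultinom(1, n_records - n_species, prob = w)[, 1L]
    record_counts <- record_counts + extra
  }
  if (length(record_counts) != n_species || sum(record_counts) != n_records)
    stop("record_counts must have one entry per species and sum to n_records")
  structure(list(
    n_records = n_records, n_species = n_species,
    record_counts = as.integer(record_counts), N_range = N_range,
    precip_range = precip_range, tmax_range = tmax_range,
    ndvi_range = ndvi_range, p_island = p_island,
    p_digestive = p_digestive, seed = seed
  ), class = "diet_design")
}

#' Simulate a diet-record dataset with known ground truth
#'
#' Generates a full synthetic bundle mirroring the generative assumptions
#' of the analysis: a random phylogeny and body masses; species intercepts
#' `alpha_j = I + X_sp %*% eps + phi_j` with `phi_j ~ N(0, omega^2)` where
#' the species design holds log body mass and the leading phylogenetic
#' eigenvectors of the simulated tree; record-level logits
#' `logit(p_i) = alpha_j + X_env %*% beta + tau_i` with
#' `tau_i ~ N(0, theta_j^2)`; counts `y_i ~ Binomial(N_i, p_i)`; each
#' record reported with probability `psi`; and a `mentioned_prob` fraction
#' of unreported records with latent `y >= 1` flagged
#' mentioned-but-unquantified. The precipitation entering the linear
#' predictor is the min-max normalized value of the generated sample, as
#' in the analysis pipeline.
#'
#' @param truth A [simulation_truth()].
#' @param design A [diet_design()] with matching `n_species`.
#' @return List of class `tpb_sim`: `records` (with `y = NA` where
#'   unreported), `species_table` (body mass, log body mass, PV scores),
#'   `tree`, and `truth` augmented with the realized `species_intercepts`,
#'   `record_effects`, latent counts and per-record `p`.
#' @export
simulate_diet_data <- function(truth, design) {
  stopifnot(inherits(truth, "simulation_truth"),
            inherits(design, "diet_design"))
  if (design$n_species != truth$n_species)
    stop("design and truth disagree on the number of species")
  J <- truth$n_species
  n <- design$n_records
  tree <- simulate_phylogeny(J, truth$seed)
  set.seed(.mix_seed(truth$seed, 29L))

  species_id <- tree$tip.label
  body_mass <- exp(stats::rnorm(J, log(8), 1))    # kg, felid-like spread
  log_body_mass <- log(body_mass)
  pv <- pv_design(pcoa_axes(patristic_distances(tree)),
                  species = species_id, n_axes = truth$n_pv_axes)
  Xsp <- cbind(log_body_mass = log_body_mass, pv)
  sp_coef <- truth$species_coefficients
  if (length(sp_coef) != ncol(Xsp))
    stop("species_coefficients length must be 1 + n_pv_axes")
  phi <- stats::rnorm(J, 0, truth$omega)
  alpha <- truth$global_intercept + drop(Xsp %*% sp_coef) + phi

  j <- rep(seq_len(J), times = design$record_counts)
  N <- sample(design$N_range[1L]:design$N_range[2L], n, replace = TRUE)
  season <- sample(0:6, n, replace = TRUE)  # 0 = whole-year study
  rec <- data.frame(
    record_id = sprintf("r%04d", seq_len(n)),
    species_id = species_id[j],
    y = NA_integer_,
    N = N,
    mentioned = FALSE,
    sample_type = as.integer(stats::runif(n) < design$p_digestive),
    island = as.integer(stats::runif(n) < design$p_island),
    spring = as.integer(season == 1), summer = as.integer(season == 2),
    autumn = as.integer(season == 3), winter = as.integer(season == 4),
    dry = as.integer(season == 5), wet = as.integer(season == 6),
    precip = stats::runif(n, design$precip_range[1L],
                          design$precip_range[2L]),
    tmax = NA_real_, tmin = NA_real_,
    ndvi = stats::runif(n, design$ndvi_range[1L], design$ndvi_range[2L]),
    stringsAsFactors = FALSE
  )
  rec$tmax <- stats::runif(n, design$tmax_range[1L], design$tmax_range[2L])
  rec$tmin <- rec$tmax - stats::runif(n, 5, 20)

  env <- rec[, tpb_env_cols()]
  env$precip <- normalize_minmax(env$precip)
  beta <- truth$env_coefficients[tpb_env_cols()]
  tau <- stats::rnorm(n, 0, truth$theta[j])
  eta <- alpha[j] + drop(as.matrix(env) %*% beta) + tau
  p <- stats::plogis(eta)
  y_latent <- stats::rbinom(n, N, p)
  reported <- stats::runif(n) < truth$psi
  rec$y[reported] <- y_latent[reported]
  mention_candidates <- !reported & y_latent >= 1
  rec$mentioned <- mention_candidates &
    stats::runif(n) < truth$mentioned_prob
  rec$reported <- reported

  truth$species_intercepts <- stats::setNames(alpha, species_id)
  truth$record_effects <- tau
  truth$latent_y <- y_latent
  truth$p <- p
  truth$phi <- phi

  structure(list(
    records = rec,
    species_table = data.frame(species_id = species_id,
                               body_mass = body_mass,
                               log_body_mass = log_body_mass, pv,
                               stringsAsFactors = FALSE),
    tree = tree, truth = truth
  ), class = "tpb_sim")
}

#' @export
print.tpb_sim <- function(x, ...) {
  cat("Synthetic diet-record bundle:", nrow(x$records), "records,",
      length(x$tree$tip.label), "species\n")
  cat(sprintf("  reported: %d (psi = %.2f)  mentioned-but-unquantified: %d\n",
              sum(x$records$reported), x$truth$psi,
              sum(x$records$mentioned)))
  invisible(x)
}

#' Write a synthetic bundle to disk
#'
#' Record and species tables as CSV, the tree as Newick, and the ground
#' truth as a YAML sidecar.
#'
#' @param sim A `tpb_sim` bundle.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_tpb_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "tpb_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_diet_records(sim$records, file.path(dir, "records.csv"))
  utils::write.csv(sim$species_table, file.path(dir, "species.csv"),
                   row.names = FALSE)
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  tr <- sim$truth
  tr_out <- list(
    psi = tr$psi, global_intercept = tr$global_intercept,
    env_coefficients = as.list(tr$env_coefficients),
    species_coefficients = as.list(tr$species_coefficients),
    omega = tr$omega, theta = as.numeric(tr$theta),
    mentioned_prob = tr$mentioned_prob, seed = tr$seed,
    species_intercepts = as.list(tr$species_intercepts)
  )
  yaml::write_yaml(tr_out, file.path(dir, "truth.yml"))
  invisible(dir)
}
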