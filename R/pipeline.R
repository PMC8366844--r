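#' Run the full analysis pipeline
#'
#' Orchestrates the six analysis variants end-to-end from CSV + Newick
#' inputs: load and validate the tables, min-max normalize precipitation,
#' run the collinearity screen, compute the phylogenetic eigenvector
#' design (for model 2), fit the non-imputed models, fit and pool the
#' imputation replicates, and write summary tables, posterior predictive
#' checks and a run manifest into the output directory. Variant naming
#' follows the model/method grid: `model1_none`, `model1_random`,
#' `model1_posterior`, and likewise for model 2.
#'
#' @param record_csv,species_csv,tree_newick Input paths.
#' @param out_dir Output directory (created; inputs are never modified).
#' @param models Integer subset of `c(1, 2)`.
#' @param methods Character subset of `c("none", "random", "posterior")`;
#'   `"posterior"` requires (and reuses) the `"none"` fit of the same
#'   model, which is fitted regardless.
#' @param config [tpb_config()] for the non-imputed fits; `master_seed`
#'   overrides its seed and drives every derived seed stream.
#' @param impute_config [tpb_config()] for each imputed replicate.
#' @param n_replicates Imputation replicates per imputed variant.
#' @param n_pv_axes Number of eigenvector axes in the species design
#'   (default: broken-stick retention).
#' @param master_seed Master seed; all sampler, imputation and PPC seeds
#'   derive from it deterministically.
#' @return Invisibly, a list with the fits, summaries and output paths.
#' @export
run_tpb_pipeline <- function(record_csv, species_csv, tree_newick, out_dir,
                             models = c(1, 2),
                             methods = c("none", "random", "posterior"),
                             config = tpb_config(),
                             impute_config = tpb_config(iter = 2000,
                                                        warmup = 1500),
                             n_replicates = 10, n_pv_axes = NULL,
                             master_seed = 1) {
  stopifnot(all(models %in% c(1, 2)),
            all(methods %in% c("none", "random", "posterior")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "tpbinom",
    version = as.character(utils::packageVersion("tpbinom")),
    date = format(Sys.Date()),
    models = models, methods = methods, master_seed = master_seed,
    inputs = as.list(tools::md5sum(c(record_csv, species_csv,
                                     tree_newick))),
    config = unclass(config), impute_config = unclass(impute_config),
    n_replicates = n_replicates, status = "started")
  write_manifest <- function()
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
  write_manifest()
  on.exit(write_manifest())

  species <- read_species_covariates(species_csv)
  records <- read_diet_records(record_csv, species = species)
  tree <- ape::read.tree(tree_newick)
  records$precip <- normalize_minmax(records$precip)

  screen <- collinearity_screen(
    as.matrix(records[, tpb_env_cols()]))
  utils::write.csv(screen, file.path(out_dir, "collinearity_flags.csv"),
                   row.names = FALSE)

  es <- NULL
  if (2 %in% models) {
    es <- pcoa_axes(patristic_distances(tree))
    pv <- pv_design(es, species = as.character(species$species_id),
                    n_axes = n_pv_axes)
    eig <- data.frame(axis = seq_along(es$relative_eigenvalues),
                      eigenvalue = es$eigenvalues[
                        seq_along(es$relative_eigenvalues)],
                      relative = es$relative_eigenvalues,
                      retained = seq_along(es$relative_eigenvalues) %in%
                        es$retained)
    utils::write.csv(eig, file.path(out_dir, "pcoa_eigenvalues.csv"),
                     row.names = FALSE)
    species <- cbind(species[, setdiff(names(species),
                                       colnames(pv)), drop = FALSE], pv)
    utils::write.csv(species, file.path(out_dir, "pv_design.csv"),
                     row.names = FALSE)
  }

  fits <- list()
  summaries <- list()
  for (model in models) {
    cfg <- config; cfg$seed <- .mix_seed(master_seed, 10L * model)
    m0 <- if (model == 1) tpb_model1(records)
          else tpb_model2(records, species)
    fit0 <- tpb_sample(m0, cfg)
    fits[[sprintf("model%d_none", model)]] <- fit0

    for (method in setdiff(methods, "none")) {
      icfg <- impute_config
      icfg$seed <- .mix_seed(master_seed,
                             100L * model + match(method,
                                                  c("random", "posterior")))
      fits[[sprintf("model%d_%s", model, method)]] <-
        replicate_fit_and_pool(records, species = species, model = model,
                               method = method,
                               n_replicates = n_replicates,
                               config = icfg, psi_source = fit0)
    }
  }

  for (nm in names(fits)) {
    fit <- fits[[nm]]
    model <- as.integer(substr(nm, 6, 6))
    smry <- if (model == 1) species_frequency(fit, records)
            else summary(fit)
    summaries[[nm]] <- smry
    utils::write.csv(format(as.data.frame(smry), digits = 15, trim = TRUE,
                            scientific = FALSE),
                     file.path(out_dir, paste0("summary_", nm, ".csv")),
                     row.names = FALSE)
    ppc <- posterior_predictive(fit, seed = .mix_seed(master_seed, 500L))
    utils::write.csv(ppc, file.path(out_dir, paste0("ppc_", nm, ".csv")),
                     row.names = FALSE)
  }

  manifest$status <- "completed"
  manifest$converged <- lapply(fits, function(f) f$converged)
  invisible(list(fits = fits, summaries = summaries, out_dir = out_dir,
                 screen = screen, pcoa = es, manifest = manifest))
}

#' Per-species occurrence frequency table
#'
#' Posterior summaries of each species' mean occurrence frequency
#' `plogis(alpha_j)` from a model-1 fit: MAP with 89% HDI and EAP with 95%
#' CI, plus the number of records (reported in parentheses in the source
#' tables).
#'
#' @param fit A model-1 `tpb_fit`.
#' @param records The record table the model was fitted to (for record
#'   counts); optional.
#' @return Data frame, one row per species.
#' @export
species_frequency <- function(fit, records = NULL) {
  stopifnot(inherits(fit, "tpb_fit"), fit$model_type == "model1")
  rows <- lapply(fit$species, function(sp) {
    a <- draw_vector(fit, paste0("alpha[", sp, "]"))
    p <- stats::plogis(a)
    h <- hdi(p, 0.89); ci <- credible_interval(p, 0.95)
    data.frame(species_id = sp,
               n_records = if (is.null(records)) NA_integer_ else
                 sum(records$species_id == sp),
               n_reported = if (is.null(records)) NA_integer_ else
                 sum(records$species_id == sp & !is.na(records$y)),
               MAP = map_estimate(p), hdi_lower = h[1L], hdi_upper = h[2L],
               EAP = mean(p), ci95_lower = ci[1L], ci95_upper = ci[2L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare parameter estimates across imputation methods
#'
#' Per-parameter table of MAP/EAP estimates and significance verdicts
#' across two or more fits of the same model, with a flag where the
#' significance verdicts disagree.
#'
#' @param ... Named `tpb_fit` objects (or a single named list) of the same
#'   model type.
#' @param pars Parameters to compare (default: the shared summary set).
#' @return Data frame with one row per parameter x method and an
#'   `any_disagreement` attribute listing parameters whose HDI+ROPE or CI
#'   verdicts differ between methods.
#' @export
compare_tpb_methods <- function(..., pars = NULL) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1L]]) &&
      !inherits(fits[[1L]], "tpb_fit")) fits <- fits[[1L]]
  if (length(fits) < 2L) stop("need at least two fits to compare")
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("fit", seq_along(fits))
  types <- vapply(fits, function(f) f$model_type, character(1))
  if (length(unique(types)) != 1L)
    stop("all fits must be of the same model type")
  if (is.null(pars)) {
    common <- Reduce(intersect, lapply(fits, function(f)
      dimnames(f$draws)[[3L]]))
    pars <- intersect(.summary_pars(fits[[1L]]), common)
  }
  rows <- list()
  for (nm in names(fits)) {
    s <- summary(fits[[nm]], pars = pars)
    s <- s[, c("parameter", "MAP", "EAP", "significant_rope",
               "significant_ci")]
    s$method <- nm
    rows[[nm]] <- s
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  dis <- vapply(pars, function(pp) {
    sub <- out[out$parameter == pp, ]
    length(unique(sub$significant_rope)) > 1L ||
      length(unique(sub$significant_ci)) > 1L
  }, logical(1))
  attr(out, "any_disagreement") <- pars[dis]
  out
}
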