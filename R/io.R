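## Column contract for the record table. `y` is the count of samples
## containing the item (empty cell = not reported); `mentioned` flags
## records whose source mentions the item without quantifying it.
.record_cols <- function() {
  c("record_id", "species_id", "y", "N", "mentioned",
    "sample_type", "island",
    "spring", "summer", "autumn", "winter", "dry", "wet",
    "precip", "tmax", "tmin", "ndvi")
}

#' Read and validate a diet record table
#'
#' Reads the record-level CSV (one row per study-record) and enforces the
#' data contract: `N >= 1`; a reported row has `0 <= y <= N`; an empty `y`
#' cell marks an unreported record; `mentioned` may be 1 only on unreported
#' rows. Row order is preserved and a derived logical `reported` column is
#' added.
#'
#' @param path CSV file with header columns `record_id, species_id, y, N,
#'   mentioned, sample_type, island, spring, summer, autumn, winter, dry,
#'   wet, precip, tmax, tmin, ndvi`.
#' @param species Optional species table; when given, record species must
#'   all be present in it.
#' @return Validated data frame of records.
#' @export
read_diet_records <- function(path, species = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_diet_records(df, species = species)
}

#' Validate an in-memory record table
#'
#' @param records Data frame with the record-table columns.
#' @inheritParams read_diet_records
#' @return The records with a derived `reported` column, after validation.
#' @export
validate_diet_records <- function(records, species = NULL) {
  df <- as.data.frame(records)
  miss <- setdiff(.record_cols(), names(df))
  if (length(miss))
    stop("record table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyNA(df$N) || any(df$N < 1 | df$N != floor(df$N)))
    stop("N must be a positive integer in every row")
  reported <- !is.na(df$y)
  bad <- which(reported & (df$y < 0 | df$y > df$N))
  if (length(bad))
    stop("row ", bad[1L], ": reported y=", df$y[bad[1L]],
         " outside [0, N=", df$N[bad[1L]], "]")
  df$mentioned <- as.integer(df$mentioned) == 1L
  bad <- which(df$mentioned & reported)
  if (length(bad))
    stop("row ", bad[1L], ": mentioned flag set on a reported record")
  if (!is.null(species)) {
    unknown <- setdiff(unique(df$species_id),
                       as.character(species$species_id))
    if (length(unknown))
      stop("unknown species in record table: ",
           paste(unknown, collapse = ", "))
  }
  df$reported <- reported
  df
}

#' Write a record table as CSV
#'
#' Inverse of [read_diet_records()]: unreported `y` is written as an empty
#' cell; the derived `reported` column is not written. Loading the file
#' back reproduces the records exactly.
#'
#' @param records Validated record data frame.
#' @param path Output CSV path.
#' @export
write_diet_records <- function(records, path) {
  df <- as.data.frame(records)[, .record_cols()]
  df$mentioned <- as.integer(df$mentioned)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a species covariate table
#'
#' @param path CSV with columns `species_id`, `body_mass` (kg, > 0) and
#'   optionally precomputed `PV*` columns.
#' @param log_base Base for the body-mass log transform (default natural
#'   log); recorded in the returned table's `log_base` attribute.
#' @return Data frame with an added `log_body_mass` column.
#' @export
read_species_covariates <- function(path, log_base = exp(1)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species_id", "body_mass") %in% names(df)))
    stop("species table needs columns species_id and body_mass")
  if (anyNA(df$body_mass) || any(df$body_mass <= 0))
    stop("body_mass must be positive in every row")
  df$log_body_mass <- log(df$body_mass, base = log_base)
  attr(df, "log_base") <- log_base
  df
}

#' Min-max normalization to \[0, 1\]
#'
#' `(x - min) / (max - min)`, the transform applied to mean monthly
#' precipitation before model fitting to aid MCMC convergence.
#'
#' @param values Numeric vector with at least two distinct finite values.
#' @return Vector in \[0, 1\] with min mapping to 0 and max to 1.
#' @export
normalize_minmax <- function(values) {
  x <- as.numeric(values)
  if (any(!is.finite(x))) stop("values must be finite")
  r <- range(x)
  if (r[1L] == r[2L])
    stop("cannot min-max normalize a constant vector")
  (x - r[1L]) / (r[2L] - r[1L])
}

#' Pairwise collinearity screen
#'
#' Pearson correlation for every pair of predictor columns; pairs at or
#' above the threshold (default |r| >= 0.80) are returned as warnings to
#' review, not hard errors. Zero-variance columns are reported as having
#' undefined correlations rather than silently skipped.
#'
#' @param X Numeric matrix or data frame of predictors (>= 3 rows).
#' @param threshold Absolute correlation flag level.
#' @return Data frame of flagged pairs (`var1`, `var2`, `r`), possibly
#'   empty (the screen passes), with constant columns listed in
#'   `attr(, "undefined")`.
#' @export
collinearity_screen <- function(X, threshold = 0.80) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("need at least 3 rows")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  undefined <- colnames(X)[sds == 0]
  ok <- which(sds > 0)
  flagged <- data.frame(var1 = character(0), var2 = character(0),
                        r = numeric(0), stringsAsFactors = FALSE)
  if (length(ok) >= 2) {
    r <- stats::cor(X[, ok, drop = FALSE])
    pairs <- which(upper.tri(r) & abs(r) >= threshold, arr.ind = TRUE)
    if (nrow(pairs)) {
      flagged <- data.frame(var1 = colnames(r)[pairs[, 1L]],
                            var2 = colnames(r)[pairs[, 2L]],
                            r = r[pairs], stringsAsFactors = FALSE)
      for (i in seq_len(nrow(flagged)))
        warning(sprintf("|r| = %.3f between %s and %s", abs(flagged$r[i]),
                        flagged$var1[i], flagged$var2[i]), call. = FALSE)
    }
  }
  if (length(undefined))
    warning("constant column(s) with undefined correlation: ",
            paste(undefined, collapse = ", "), call. = FALSE)
  attr(flagged, "undefined") <- undefined
  attr(flagged, "threshold") <- threshold
  flagged
}
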