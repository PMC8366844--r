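#' Posterior mode (MAP estimate)
#'
#' Mode of a Gaussian kernel density estimate of the draws, located on a
#' fine grid over the draw range. The bandwidth rule (Silverman,
#' `stats::bw.nrd0`) and grid size are fixed for determinism.
#'
#' @param draws Numeric vector of posterior draws (at least 100).
#' @param n_grid Grid resolution for the density evaluation.
#' @return The MAP estimate.
#' @export
map_estimate <- function(draws, n_grid = 2048) {
  draws <- as.numeric(draws)
  if (length(draws) < 100)
    stop("MAP estimation needs at least 100 draws; run the sampler longer")
  if (diff(range(draws)) == 0) return(draws[1L])
  d <- stats::density(draws, bw = "nrd0", n = n_grid,
                      from = min(draws), to = max(draws))
  d$x[which.max(d$y)]
}

#' Highest density interval
#'
#' Shortest contiguous interval of the empirical distribution containing
#' `ceiling(mass * n)` draws; among tied-width windows the one with the
#' lowest start is chosen.
#'
#' @param draws Numeric vector of posterior draws.
#' @param mass Probability mass in (0, 1); default 0.89, the package's
#'   reporting convention (more stable than 0.95 for effective sample
#'   sizes under 10,000).
#' @return Numeric vector `c(lower, upper)`.
#' @export
hdi <- function(draws, mass = 0.89) {
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0 || mass >= 1)
    stop("mass must be in (0, 1)")
  x <- sort(as.numeric(draws))
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1L], x[n]))
  widths <- x[m:n] - x[1:(n - m + 1L)]
  i <- which.min(widths)           # which.min takes the first (lowest start)
  c(x[i], x[i + m - 1L])
}

#' Equal-tailed credible interval
#'
#' @param draws Numeric vector of posterior draws.
#' @param level Interval mass in (0, 1), e.g. 0.95.
#' @return Numeric vector `c(lower, upper)` of the `(1-level)/2` and
#'   `1-(1-level)/2` empirical quantiles.
#' @export
credible_interval <- function(draws, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("level must be in (0, 1)")
  a <- (1 - level) / 2
  unname(stats::quantile(as.numeric(draws), c(a, 1 - a), names = FALSE))
}

#' Region of practical equivalence
#'
#' Default bounds \[-0.1, 0.1\]: half of the conventional small-effect size,
#' the package's null region for logit-scale coefficients.
#'
#' @param lower,upper ROPE bounds, `lower < upper`.
#' @return Numeric vector `c(lower, upper)`.
#' @export
rope_spec <- function(lower = -0.1, upper = 0.1) {
  stopifnot(lower < upper)
  c(lower, upper)
}

#' HDI + ROPE equivalence decision
#'
#' Computes the fraction of HDI draws falling inside the ROPE (the
#' draw-count convention; a length-overlap convention is available via
#' `convention = "length"` — both agree at the decision-relevant values 0
#' and 1). The effect is declared significant when the entire HDI lies
#' outside the ROPE.
#'
#' @param draws Numeric vector of posterior draws.
#' @param rope A [rope_spec()].
#' @param mass HDI mass (default 0.89).
#' @param convention `"draws"` (default) or `"length"`.
#' @return List with `pct_inside` (fraction in \[0, 1\]), `significant`
#'   (logical), and the `hdi` used.
#' @export
rope_decision <- function(draws, rope = rope_spec(), mass = 0.89,
                          convention = c("draws", "length")) {
  convention <- match.arg(convention)
  h <- hdi(draws, mass)
  if (convention == "draws") {
    x <- as.numeric(draws)
    inside_hdi <- x >= h[1L] & x <= h[2L]
    pct <- if (any(inside_hdi))
      mean(x[inside_hdi] >= rope[1L] & x[inside_hdi] <= rope[2L]) else 0
  } else {
    overlap <- max(0, min(h[2L], rope[2L]) - max(h[1L], rope[1L]))
    width <- h[2L] - h[1L]
    pct <- if (width > 0) overlap / width else
      as.numeric(h[1L] >= rope[1L] & h[1L] <= rope[2L])
  }
  significant <- h[2L] < rope[1L] || h[1L] > rope[2L]
  list(pct_inside = pct, significant = significant, hdi = h)
}

#' Significance by credible interval
#'
#' `TRUE` when zero lies outside the equal-tailed credible interval.
#'
#' @inheritParams credible_interval
#' @export
ci_significance <- function(draws, level = 0.95) {
  ci <- credible_interval(draws, level)
  ci[1L] > 0 || ci[2L] < 0
}

#' Rank-normalized split-Rhat
#'
#' Potential scale reduction factor computed on rank-normalized draws after
#' splitting each chain in half, taking the maximum of the bulk statistic
#' and the tail statistic on folded draws (Vehtari et al. 2021). Values
#' near 1 indicate convergence; the package flags fits at 1.01.
#'
#' @param x Matrix of draws, iterations x chains (at least 2 chains after
#'   splitting, so any single chain is split into two halves).
#' @return The Rhat value, or `NA` for constant draws.
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4L) return(NA_real_)
  half <- n %/% 2L
  sp <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1L):n, , drop = FALSE])
  if (diff(range(sp)) == 0) return(NA_real_)
  bulk <- .rhat_basic(.z_scale(sp))
  folded <- abs(sp - stats::median(sp))
  tail <- .rhat_basic(.z_scale(folded))
  max(bulk, tail)
}

.z_scale <- function(m) {
  r <- rank(m, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(m) + 1 / 4))
  matrix(z, nrow = nrow(m))
}

.rhat_basic <- function(m) {
  n <- nrow(m)
  w <- mean(apply(m, 2, stats::var))
  if (w == 0) return(NA_real_)
  b <- n * stats::var(colMeans(m))
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Posterior predictive check for reported counts
#'
#' Simulates replicated counts `y_rep ~ Binomial(N_i, p_i)` for each
#' reported record over a subsample of posterior draws and summarizes how
#' the observed counts sit within their replicated distributions. The
#' overall calibration statistic is the proportion of reported records
#' whose observed `y` falls inside the central 95% of its `y_rep`
#' distribution.
#'
#' @param fit A `tpb_fit`.
#' @param seed Integer seed for the replicate simulation.
#' @param n_draws Number of posterior draws used (subsampled evenly).
#' @return Data frame of class `tpb_ppc` (one row per reported record:
#'   observed `y`, `N`, mean and central-95% bounds of `y_rep`, `inside`)
#'   with the overall coverage in `attr(, "coverage95")`.
#' @export
posterior_predictive <- function(fit, seed = 1, n_draws = 500) {
  stopifnot(inherits(fit, "tpb_fit"))
  set.seed(seed)
  rep_idx <- which(fit$reported)
  if (!length(rep_idx)) stop("no reported records to check")
  d <- dim(fit$draws)
  total <- d[1L] * d[2L]
  n_draws <- min(n_draws, total)
  use <- unique(round(seq(1, total, length.out = n_draws)))
  rows <- lapply(rep_idx, function(i) {
    p <- as.vector(fit$draws[, , paste0("p[", i, "]")])[use]
    yrep <- stats::rbinom(length(p), fit$N[i], p)
    q <- stats::quantile(yrep, c(0.025, 0.975), type = 1, names = FALSE)
    data.frame(record = i, y = fit$y[i], N = fit$N[i],
               yrep_mean = mean(yrep), yrep_lower = q[1L],
               yrep_upper = q[2L],
               inside = fit$y[i] >= q[1L] && fit$y[i] <= q[2L])
  })
  out <- do.call(rbind, rows)
  attr(out, "coverage95") <- mean(out$inside)
  class(out) <- c("tpb_ppc", "data.frame")
  out
}

#' @export
print.tpb_ppc <- function(x, ...) {
  cat("Posterior predictive check:", nrow(x), "reported records\n")
  cat(sprintf("  central-95%% coverage of observed y: %.3f\n",
              attr(x, "coverage95")))
  invisible(x)
}
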