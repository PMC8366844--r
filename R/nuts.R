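#' No-U-Turn Sampler for a differentiable log-density
#'
#' Hamiltonian Monte Carlo with the No-U-Turn termination criterion
#' (dynamic trajectory length), dual-averaging step-size adaptation toward
#' a target acceptance statistic, and diagonal mass-matrix adaptation from
#' warmup draws. This is the sampling engine behind [tpb()]; it is exported
#' so that reduced or custom densities can be sampled with the same
#' machinery.
#'
#' @param lp_grad Function of the unconstrained parameter vector returning
#'   `list(lp = <log density>, grad = <gradient vector>)`.
#' @param init Either a numeric initial vector, or a function `(chain)`
#'   returning one; chains are initialized independently.
#' @param n_par Number of parameters (checked against `init`).
#' @param iter Total iterations per chain, including warmup.
#' @param warmup Number of warmup (adaptation) iterations, `< iter`.
#' @param chains Number of chains, run sequentially (default 4).
#' @param seed Integer seed; chain `c` uses an RNG stream derived from
#'   `seed` and `c`, so results are reproducible and chains independent.
#' @param control List of tuning options: `adapt_delta` (target acceptance,
#'   default 0.8), `max_treedepth` (default 10), `init_step` (optional
#'   fixed initial step size).
#' @return List with `draws` (list of post-warmup matrices, one per chain,
#'   iterations x parameters), `divergences` (post-warmup count per chain),
#'   `step_size`, `treedepth` (mean post-warmup tree depth per chain),
#'   `accept_stat`.
#' @references Hoffman, M. D. and Gelman, A. (2014). The No-U-Turn Sampler:
#'   adaptively setting path lengths in Hamiltonian Monte Carlo. JMLR 15.
#' @export
nuts_sample <- function(lp_grad, init, n_par = NULL, iter = 2000,
                        warmup = 1000, chains = 4, seed = 1,
                        control = list()) {
  stopifnot(iter > warmup, warmup >= 20, chains >= 1)
  adapt_delta <- control$adapt_delta %||% 0.8
  max_depth <- control$max_treedepth %||% 10
  draws <- vector("list", chains)
  div <- integer(chains); ss <- numeric(chains)
  depth_mean <- numeric(chains); acc <- numeric(chains)
  for (ch in seq_len(chains)) {
    q0 <- if (is.function(init)) init(ch) else init
    if (is.null(n_par)) n_par <- length(q0)
    stopifnot(length(q0) == n_par)
    res <- .nuts_chain(lp_grad, q0, iter, warmup, adapt_delta, max_depth,
                       seed = .mix_seed(seed, ch),
                       init_step = control$init_step)
    draws[[ch]] <- res$draws
    div[ch] <- res$divergences
    ss[ch] <- res$step_size
    depth_mean[ch] <- res$treedepth
    acc[ch] <- res$accept_stat
  }
  list(draws = draws, divergences = div, step_size = ss,
       treedepth = depth_mean, accept_stat = acc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## deterministic sub-stream seeds below 2^31
.mix_seed <- function(seed, k) {
  s <- (as.numeric(seed) %% 2147483647)
  as.integer((s * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}

.nuts_chain <- function(lp_grad, q, iter, warmup, adapt_delta, max_depth,
                        seed, init_step = NULL) {
  set.seed(seed)
  n_par <- length(q)
  inv_mass <- rep(1, n_par)
  state <- lp_grad(q)
  if (!is.finite(state$lp)) stop("initial point has non-finite log density")

  eps <- if (is.null(init_step)) .find_epsilon(lp_grad, q, inv_mass) else init_step
  ## dual averaging (Hoffman & Gelman 2014, sec. 3.2)
  da <- .da_init(eps)
  ## mass adaptation schedule: init buffer, doubling estimation windows,
  ## terminal step-size-only buffer (as in Stan's windowed adaptation)
  buf_init <- max(20L, floor(0.15 * warmup))
  buf_term <- max(10L, floor(0.10 * warmup))
  win_end <- .adapt_windows(buf_init, warmup - buf_term)
  wf <- .welford_init(n_par)

  keep <- iter - warmup
  out <- matrix(NA_real_, keep, n_par)
  n_div <- 0L; depth_sum <- 0; acc_sum <- 0

  for (it in seq_len(iter)) {
    mom <- stats::rnorm(n_par, 0, 1) / sqrt(inv_mass)
    step <- .nuts_transition(lp_grad, q, state, mom, eps, inv_mass, max_depth)
    q <- step$q; state <- step$state
    if (it <= warmup) {
      da <- .da_update(da, step$accept_prob, adapt_delta)
      eps <- da$eps
      if (it > buf_init && it <= warmup - buf_term) {
        wf <- .welford_add(wf, q)
        if (it %in% win_end) {
          v <- .welford_var(wf)
          inv_mass <- v * wf$n / (wf$n + 5) + 1e-3 * (5 / (wf$n + 5))
          wf <- .welford_init(n_par)
          eps <- .find_epsilon(lp_grad, q, inv_mass)
          da <- .da_init(eps)
        }
      }
      if (it == warmup) eps <- exp(da$log_eps_bar)
    } else {
      out[it - warmup, ] <- q
      if (step$divergent) n_div <- n_div + 1L
      depth_sum <- depth_sum + step$depth
      acc_sum <- acc_sum + step$accept_prob
    }
  }
  list(draws = out, divergences = n_div, step_size = eps,
       treedepth = depth_sum / keep, accept_stat = acc_sum / keep)
}

.da_init <- function(eps) {
  list(eps = eps, mu = log(10 * eps), log_eps_bar = 0, h_bar = 0, m = 0,
       gamma = 0.05, t0 = 10, kappa = 0.75)
}

.da_update <- function(da, accept_prob, delta) {
  m <- da$m + 1
  h_bar <- (1 - 1 / (m + da$t0)) * da$h_bar +
    (delta - accept_prob) / (m + da$t0)
  log_eps <- da$mu - sqrt(m) / da$gamma * h_bar
  w <- m^(-da$kappa)
  log_eps_bar <- w * log_eps + (1 - w) * da$log_eps_bar
  list(eps = exp(log_eps), mu = da$mu, log_eps_bar = log_eps_bar,
       h_bar = h_bar, m = m, gamma = da$gamma, t0 = da$t0, kappa = da$kappa)
}

.adapt_windows <- function(from, to) {
  if (to <= from) return(integer(0))
  ends <- integer(0); w <- 25L; pos <- from
  repeat {
    pos <- pos + w
    if (pos + 2L * w > to) { ends <- c(ends, to); break }
    ends <- c(ends, pos)
    w <- 2L * w
  }
  ends
}

.welford_init <- function(n) list(n = 0, mean = numeric(n), m2 = numeric(n))
.welford_add <- function(w, x) {
  n <- w$n + 1
  d <- x - w$mean
  mean <- w$mean + d / n
  m2 <- w$m2 + d * (x - mean)
  list(n = n, mean = mean, m2 = m2)
}
.welford_var <- function(w) if (w$n > 1) w$m2 / (w$n - 1) else rep(1, length(w$m2))

## heuristic initial step size (Hoffman & Gelman 2014, Algorithm 4)
.find_epsilon <- function(lp_grad, q, inv_mass) {
  eps <- 1
  st <- lp_grad(q)
  p <- stats::rnorm(length(q), 0, 1) / sqrt(inv_mass)
  h0 <- st$lp - 0.5 * sum(p^2 * inv_mass)
  lf <- .leapfrog(lp_grad, q, p, eps, inv_mass)
  h1 <- if (is.finite(lf$state$lp))
    lf$state$lp - 0.5 * sum(lf$p^2 * inv_mass) else -Inf
  a <- if (h1 - h0 > log(0.5)) 1 else -1
  for (i in 1:50) {
    eps <- eps * 2^a
    lf <- .leapfrog(lp_grad, q, p, eps, inv_mass)
    h1 <- if (is.finite(lf$state$lp))
      lf$state$lp - 0.5 * sum(lf$p^2 * inv_mass) else -Inf
    if (a * (h1 - h0) <= a * log(0.5)) break
  }
  max(eps, 1e-10)
}

.leapfrog <- function(lp_grad, q, p, eps, inv_mass, state = NULL) {
  if (is.null(state)) state <- lp_grad(q)
  p <- p + 0.5 * eps * state$grad
  q <- q + eps * (p * inv_mass)
  state <- lp_grad(q)
  if (!is.finite(state$lp)) {
    state$lp <- -Inf
    state$grad <- numeric(length(q))
  }
  p <- p + 0.5 * eps * state$grad
  list(q = q, p = p, state = state)
}

## one NUTS transition (multinomial NUTS with biased progressive sampling,
## as in modern Stan; termination via the original no-U-turn criterion)
.nuts_transition <- function(lp_grad, q, state, p, eps, inv_mass, max_depth) {
  h0 <- state$lp - 0.5 * sum(p^2 * inv_mass)
  ## trajectory ends
  minus <- list(q = q, p = p, state = state)
  plus <- minus
  q_prop <- q; state_prop <- state
  log_sum_w <- 0        # log sum of weights exp(h - h0) over trajectory
  depth <- 0L
  divergent <- FALSE
  sum_alpha <- 0; n_alpha <- 0

  repeat {
    dir <- if (stats::runif(1) < 0.5) -1 else 1
    seed_node <- if (dir == 1) plus else minus
    sub <- .build_tree(lp_grad, seed_node, dir, depth, eps, inv_mass, h0)
    sum_alpha <- sum_alpha + sub$sum_alpha
    n_alpha <- n_alpha + sub$n_alpha
    if (dir == 1) plus <- sub$outer else minus <- sub$outer
    if (sub$divergent) { divergent <- TRUE; break }
    if (!sub$valid) break
    ## biased progressive sampling across subtrees
    if (log(stats::runif(1)) < sub$log_sum_w - log_sum_w) {
      q_prop <- sub$q_prop; state_prop <- sub$state_prop
    }
    log_sum_w <- .logaddexp(log_sum_w, sub$log_sum_w)
    if (.uturn(minus, plus, inv_mass)) break
    depth <- depth + 1L
    if (depth >= max_depth) break
  }
  list(q = q_prop, state = state_prop, depth = depth,
       divergent = divergent,
       accept_prob = if (n_alpha > 0) sum_alpha / n_alpha else 0)
}

.logaddexp <- function(a, b) {
  m <- max(a, b)
  if (!is.finite(m)) return(m)
  m + log(exp(a - m) + exp(b - m))
}

.uturn <- function(minus, plus, inv_mass) {
  dq <- plus$q - minus$q
  sum(dq * (minus$p * inv_mass)) < 0 || sum(dq * (plus$p * inv_mass)) < 0
}

.build_tree <- function(lp_grad, node, dir, depth, eps, inv_mass, h0) {
  if (depth == 0L) {
    lf <- .leapfrog(lp_grad, node$q, node$p, dir * eps, inv_mass, node$state)
    h <- if (is.finite(lf$state$lp))
      lf$state$lp - 0.5 * sum(lf$p^2 * inv_mass) else -Inf
    dh <- h - h0
    divergent <- !is.finite(dh) || dh < -1000
    alpha <- if (is.finite(dh)) min(1, exp(dh)) else 0
    return(list(outer = lf, q_prop = lf$q, state_prop = lf$state,
                log_sum_w = dh, valid = !divergent, divergent = divergent,
                inner_minus = lf, inner_plus = lf,
                sum_alpha = alpha, n_alpha = 1))
  }
  first <- .build_tree(lp_grad, node, dir, depth - 1L, eps, inv_mass, h0)
  if (!first$valid)
    return(first)
  second <- .build_tree(lp_grad, first$outer, dir, depth - 1L, eps,
                        inv_mass, h0)
  sum_alpha <- first$sum_alpha + second$sum_alpha
  n_alpha <- first$n_alpha + second$n_alpha
  if (!second$valid)
    return(list(outer = second$outer, q_prop = first$q_prop,
                state_prop = first$state_prop, log_sum_w = first$log_sum_w,
                valid = FALSE, divergent = second$divergent,
                inner_minus = first$inner_minus, inner_plus = second$inner_plus,
                sum_alpha = sum_alpha, n_alpha = n_alpha))
  log_sum_w <- .logaddexp(first$log_sum_w, second$log_sum_w)
  ## uniform progressive sampling within a subtree
  take_second <- log(stats::runif(1)) < second$log_sum_w - log_sum_w
  q_prop <- if (take_second) second$q_prop else first$q_prop
  state_prop <- if (take_second) second$state_prop else first$state_prop
  ## subtree U-turn check between its own ends
  ends_minus <- if (dir == 1) first$inner_minus else second$outer
  ends_plus <- if (dir == 1) second$outer else first$inner_minus
  valid <- !.uturn(ends_minus, ends_plus, inv_mass)
  list(outer = second$outer, q_prop = q_prop, state_prop = state_prop,
       log_sum_w = log_sum_w, valid = valid, divergent = FALSE,
       inner_minus = first$inner_minus, inner_plus = second$inner_plus,
       sum_alpha = sum_alpha, n_alpha = n_alpha)
}
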