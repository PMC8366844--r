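## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths: densities are summed term by term with stats::d*
## functions, distances walk the tree edge list directly, and the HDI oracle
## enumerates every contiguous window.

## small random record table
make_records <- function(n, J = 3, seed = 1, psi = 0.5,
                         with_env = FALSE, mentioned_prob = 0) {
  set.seed(seed)
  sp <- paste0("S", seq_len(J))
  j <- sample(seq_len(J), n, replace = TRUE)
  j[seq_len(min(J, n))] <- seq_len(min(J, n))  # every species present
  N <- sample(10:60, n, replace = TRUE)
  y <- rbinom(n, N, plogis(rnorm(J, -1.5, 1)[j] + rnorm(n, 0, 0.5)))
  reported <- runif(n) < psi
  yy <- ifelse(reported, y, NA_integer_)
  mentioned <- !reported & y >= 1 & runif(n) < mentioned_prob
  df <- data.frame(record_id = paste0("r", seq_len(n)),
                   species_id = sp[j], y = yy, N = N,
                   mentioned = mentioned, stringsAsFactors = FALSE)
  if (with_env) for (cn in tpbinom:::tpb_env_cols()) df[[cn]] <- runif(n)
  df
}

make_species <- function(records, n_pv = 2, seed = 1) {
  set.seed(seed + 7)
  sp <- unique(records$species_id)
  out <- data.frame(species_id = sp,
                    log_body_mass = rnorm(length(sp), 2, 1),
                    stringsAsFactors = FALSE)
  for (k in seq_len(n_pv))
    out[[paste0("PV", k)]] <- rnorm(length(sp), 0, 0.3)
  out
}

## brute-force joint log-density of Model 1 on the unconstrained scale:
## explicit per-record / per-species loops, stats::d* densities
oracle_lp_model1 <- function(model, q) {
  ix <- model$index
  sp <- model$species
  J <- length(sp)
  alpha <- q[ix$alpha]
  theta <- exp(q[ix$log_theta])
  tau_raw <- q[ix$tau_raw]
  lp <- 0
  if (model$est_psi) {
    psi <- plogis(q[ix$psi])
    lp <- lp + log(psi) + log(1 - psi)      # Uniform(0,1) + logit Jacobian
  } else psi <- model$psi_fixed
  for (k in seq_len(J))
    lp <- lp + dt(alpha[k] / 5, df = 3, log = TRUE) - log(5) +
      dexp(theta[k], 1, log = TRUE) + q[ix$log_theta][k]
  for (i in seq_along(model$y)) {
    lp <- lp + dnorm(tau_raw[i], log = TRUE)
    k <- model$j[i]
    if (model$reported[i]) {
      p <- plogis(alpha[k] + theta[k] * tau_raw[i])
      lp <- lp + log(psi) + dbinom(model$y[i], model$N[i], p, log = TRUE)
    } else {
      lp <- lp + log(1 - psi)
    }
  }
  lp
}

oracle_lp_model2 <- function(model, q) {
  ix <- model$index
  J <- length(model$species)
  s <- length(model$env_cols); t_ <- length(model$sp_cols)
  I0 <- q[ix$I]
  beta <- if (s) q[ix$beta] else numeric(0)
  eps <- if (t_) q[ix$eps] else numeric(0)
  omega <- exp(q[ix$log_omega])
  phi_raw <- q[ix$phi_raw]
  theta <- exp(q[ix$log_theta])
  tau_raw <- q[ix$tau_raw]
  lp <- 0
  if (model$est_psi) {
    psi <- plogis(q[ix$psi])
    lp <- lp + log(psi) + log(1 - psi)
  } else psi <- model$psi_fixed
  lp <- lp + dt(I0 / 5, df = 3, log = TRUE) - log(5)
  for (b in beta) lp <- lp + dt(b / 5, df = 3, log = TRUE) - log(5)
  for (e in eps) lp <- lp + dt(e / 5, df = 3, log = TRUE) - log(5)
  lp <- lp + dexp(omega, 1, log = TRUE) + q[ix$log_omega]
  alpha <- numeric(J)
  for (k in seq_len(J)) {
    lp <- lp + dnorm(phi_raw[k], log = TRUE) +
      dexp(theta[k], 1, log = TRUE) + q[ix$log_theta][k]
    alpha[k] <- I0 + sum(model$Xsp[k, ] * eps) + omega * phi_raw[k]
  }
  for (i in seq_along(model$y)) {
    lp <- lp + dnorm(tau_raw[i], log = TRUE)
    k <- model$j[i]
    if (model$reported[i]) {
      eta <- alpha[k] + sum(model$Xenv[i, ] * beta) +
        theta[k] * tau_raw[i]
      lp <- lp + log(psi) +
        dbinom(model$y[i], model$N[i], plogis(eta), log = TRUE)
    } else {
      lp <- lp + log(1 - psi)
    }
  }
  lp
}

## central-difference gradient
num_grad <- function(lp_grad, q, idx = seq_along(q), h = 1e-6) {
  vapply(idx, function(i) {
    qp <- q; qm <- q
    qp[i] <- q[i] + h; qm[i] <- q[i] - h
    (lp_grad(qp)$lp - lp_grad(qm)$lp) / (2 * h)
  }, numeric(1))
}

## exhaustive shortest-window HDI
oracle_hdi <- function(x, mass) {
  xs <- sort(x)
  n <- length(xs)
  m <- ceiling(mass * n)
  best <- c(xs[1], xs[m]); bw <- xs[m] - xs[1]
  if (m < n) for (i in 2:(n - m + 1)) {
    w <- xs[i + m - 1] - xs[i]
    if (w < bw - 1e-15) { bw <- w; best <- c(xs[i], xs[i + m - 1]) }
  }
  best
}

## patristic distance by walking edge paths to the root (independent of
## any distance routine: uses only the phylo edge list)
oracle_patristic <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(v) {
    nodes <- v
    while (v != root) { v <- parent[v]; nodes <- c(nodes, v) }
    nodes
  }
  D <- matrix(0, ntip, ntip,
              dimnames = list(tree$tip.label, tree$tip.label))
  for (a in seq_len(ntip)) for (b in seq_len(ntip)) if (a < b) {
    pa <- path_to_root(a); pb <- path_to_root(b)
    common <- intersect(pa, pb)
    lca <- common[1L]
    da <- sum(elen[pa[seq_len(which(pa == lca) - 1L)]])
    db <- sum(elen[pb[seq_len(which(pb == lca) - 1L)]])
    D[a, b] <- D[b, a] <- da + db
  }
  D
}
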