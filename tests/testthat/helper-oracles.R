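# Independent brute-force oracles, written as straight-line code with their
# own hard-coded task structure so they share nothing with the package
# implementation they check.

oracle_features <- list(AB = c("A", "B"), AC = c("A", "C"), B = "B", C = "C")

oracle_overlap <- function(s1, s2) {
  if (s1 == s2) return(0L)
  shared <- intersect(oracle_features[[s1]], oracle_features[[s2]])
  if (length(shared) > 0) 1L else 0L
}

# Plain-loop value/PE trace for any model kind.
oracle_trace <- function(seq, kind, alpha = 0, omega = 0, v0 = 0,
                         reset = TRUE) {
  seq <- seq[order(seq$run, seq$trial), , drop = FALSE]
  stims <- c("AB", "AC", "B", "C")
  feats <- c("A", "B", "C")
  n <- nrow(seq)
  v <- numeric(n); delta <- numeric(n); v_upd <- numeric(n)
  state_stim <- stats::setNames(rep(v0, 4), stims)
  state_feat <- stats::setNames(rep(v0, 3), feats)
  state_base <- v0
  cur_run <- seq$run[1]
  for (t in 1:n) {
    if (reset && seq$run[t] != cur_run) {
      state_stim <- stats::setNames(rep(v0, 4), stims)
      state_feat <- stats::setNames(rep(v0, 3), feats)
      state_base <- v0
      cur_run <- seq$run[t]
    }
    s <- seq$stimulus[t]; R <- seq$target[t]
    if (kind == "no_learning") {
      v[t] <- 0
    } else if (kind == "base_rate") {
      v[t] <- state_base
    } else if (kind == "feature") {
      v[t] <- sum(state_feat[oracle_features[[s]]])
    } else {
      v[t] <- state_stim[[s]]
    }
    delta[t] <- R - v[t]
    if (kind == "base_rate") {
      state_base <- state_base + alpha * delta[t]
      v_upd[t] <- state_base
    } else if (kind == "feature") {
      for (f in oracle_features[[s]]) {
        state_feat[[f]] <- state_feat[[f]] + alpha * delta[t]
      }
      v_upd[t] <- sum(state_feat[oracle_features[[s]]])
    } else if (kind %in% c("conjunctive", "value_spread")) {
      state_stim[[s]] <- state_stim[[s]] + alpha * delta[t]
      if (kind == "value_spread") {
        for (s2 in stims) {
          if (oracle_overlap(s, s2) == 1L) {
            state_stim[[s2]] <- state_stim[[s2]] + alpha * delta[t] * omega
          }
        }
      }
      v_upd[t] <- state_stim[[s]]
    }
  }
  data.frame(v = v, delta = delta, v_upd = v_upd)
}

# Sum of normal log-densities.
oracle_gauss_ll <- function(y, mu, sigma) {
  total <- 0
  for (i in seq_along(y)) {
    total <- total + log(stats::dnorm(y[i], mu[i], sigma))
  }
  total
}

# Pairwise Fisher-z correlation matrix by explicit loops.
oracle_psm <- function(x) {
  n <- nrow(x)
  out <- NULL
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      r <- stats::cor(x[i, ], x[j, ])
      r <- min(max(r, -(1 - 1e-7)), 1 - 1e-7)
      out <- rbind(out, data.frame(i = i, j = j, z = atanh(r)))
    }
  }
  out
}

# Brute-force importance-sampling estimate of the exact posterior
# exceedance probabilities for the hierarchical random-effects model:
# subject model assignments are proposed from each subject's evidence
# softmax, reweighted by the Dirichlet normalizer ratio, and frequencies r
# are drawn exactly given the assignments. (Verified against 1-D grid
# integration of the K = 2 posterior.)
oracle_xp_is <- function(ev, alpha0 = 1, n_samp = 2e5, seed = 1) {
  set.seed(seed)
  n <- nrow(ev); K <- ncol(ev)
  p <- exp(ev - apply(ev, 1, max)); p <- p / rowSums(p)
  cum <- t(apply(p, 1, cumsum))
  log_b <- function(a) sum(lgamma(a)) - lgamma(sum(a))
  log_b0 <- log_b(rep(alpha0, K))
  xp_w <- numeric(K); wsum <- 0
  for (b in seq_len(n_samp)) {
    u <- stats::runif(n)
    a <- max.col(cum >= u, ties.method = "first")
    counts <- tabulate(a, K)
    w <- exp(log_b(alpha0 + counts) - log_b0)
    r <- stats::rgamma(K, alpha0 + counts)
    k_win <- which.max(r)
    xp_w[k_win] <- xp_w[k_win] + w
    wsum <- wsum + w
  }
  xp_w / wsum
}

# Small behavioral dataset helper shared across tests.
make_subject <- function(seed, params = model_params("value_spread",
                                                     alpha = 0.3,
                                                     omega = 0.44),
                         seq = NULL, ...) {
  if (is.null(seq)) seq <- make_trial_sequence(seed = 1)
  simulate_behavior(seq, behavior_config(params = params, seed = seed, ...))
}
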