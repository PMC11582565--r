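# Shared fixtures: small chains and emission models built in code.

# Two-state open/closed pore with closing rate kc and opening rate ko (s^-1)
two_state_model <- function() {
  make_ctmc_model(
    states = c("open", "closed"),
    group = c(open = "open", closed = "closed"),
    free = c("kc", "ko"),
    build_Q = function(rates, conc) {
      matrix(c(-rates[["kc"]], rates[["kc"]],
               rates[["ko"]], -rates[["ko"]]),
             2, 2, byrow = TRUE,
             dimnames = list(c("open", "closed"), c("open", "closed")))
    },
    lid_closed = "closed", variant_id = "toy2")
}

two_state_emission <- function(mu = c(open = -200, closed = -221), sigma = 8) {
  emission_model(mu = mu, sigma = sigma,
                 group = c(open = "open", closed = "closed"))
}

# Three-state linear chain a <-> b <-> c
three_state_Q <- function(ab = 300, ba = 50, bc = 120, cb = 70) {
  Q <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  Q["a", "b"] <- ab; Q["b", "a"] <- ba
  Q["b", "c"] <- bc; Q["c", "b"] <- cb
  diag(Q) <- -rowSums(Q)
  Q
}

# High-order scaled Taylor-series matrix exponential: independent oracle for
# the scaling-and-squaring implementation
expm_series <- function(A, n_terms = 40, n_scale = 8) {
  B <- A / 2^n_scale
  S <- diag(nrow(A))
  P <- diag(nrow(A))
  for (k in seq_len(n_terms)) {
    P <- P %*% B / k
    S <- S + P
  }
  for (i in seq_len(n_scale)) S <- S %*% S
  S
}

# Exhaustive hidden-path enumeration of the likelihood
# L = sum over paths m_0..m_T of delta(m_0) prod_t G[m_{t-1},m_t] phi_t(m_t)
# (the prior is propagated one step before the first emission).
enumerate_loglik <- function(G, em, y, delta = stationary_distribution(G)) {
  n <- nrow(G)
  Tn <- length(y)
  states <- rownames(G)
  dens <- vapply(y, function(yy) emission_density_vector(yy, em, states),
                 numeric(n))
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), Tn + 1L)))
  total <- 0
  for (i in seq_len(nrow(paths))) {
    p <- unname(delta[paths[i, 1L]])
    for (t in seq_len(Tn)) {
      p <- p * G[paths[i, t], paths[i, t + 1L]] * dens[paths[i, t + 1L], t]
    }
    total <- total + p
  }
  unname(log(total))
}

# Unscaled direct likelihood product (overflow-safe only for short traces)
unscaled_loglik <- function(G, em, y, delta = stationary_distribution(G)) {
  states <- rownames(G)
  v <- rbind(delta)
  for (t in seq_along(y)) {
    v <- v %*% G %*% diag(emission_density_vector(y[t], em, states),
                          nrow = nrow(G))
  }
  log(sum(v))
}
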