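#' Exact CTMC sample path
#'
#' Stochastic simulation of the jump chain: exponential sojourns at each
#' state's total exit rate, jump targets proportional to off-diagonal
#' rates. The final sojourn is truncated at the requested duration.
#'
#' @param Q Generator matrix (s^-1).
#' @param duration_ms Path duration (ms, > 0).
#' @param p0 Initial distribution over states; defaults to the stationary
#'   distribution of the chain discretized at 0.2 ms.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return data.frame of class `ak_path` with columns `state` (name),
#'   `sojourn_ms`; attribute `duration_ms`.
#' @export
sample_ctmc_path <- function(Q, duration_ms, p0 = NULL, seed = NULL) {
  if (!is.numeric(duration_ms) || duration_ms <= 0)
    stop("duration_ms must be positive")
  states <- rownames(Q)
  if (is.null(states)) states <- as.character(seq_len(nrow(Q)))
  if (is.null(p0)) p0 <- stationary_distribution(discretize(Q, 0.2))
  if (length(p0) != nrow(Q) || any(p0 < 0) || abs(sum(p0) - 1) > 1e-8)
    stop("invalid initial distribution")
  raw <- with_seed(seed, .sample_ctmc(Q * 1e-3, duration_ms, as.numeric(p0)))
  out <- data.frame(state = states[raw$state], sojourn_ms = raw$sojourn_ms,
                    stringsAsFactors = FALSE)
  attr(out, "duration_ms") <- duration_ms
  class(out) <- c("ak_path", "data.frame")
  out
}

#' Sample a continuous path on a regular grid
#'
#' State occupied at each sampling instant `t = i * dt`,
#' `i = 1 .. floor(duration/dt)`. Sojourns shorter than `dt` that straddle
#' no sampling instant leave no sample (aliasing inherent to sampling).
#'
#' @param path [sample_ctmc_path()] result.
#' @param dt_ms Sampling interval (ms, > 0).
#' @return Character vector of state names, one per sampling instant.
#' @export
discretize_path <- function(path, dt_ms = 0.2) {
  if (dt_ms <= 0) stop("dt_ms must be positive")
  total <- sum(path$sojourn_ms)
  n <- floor(total / dt_ms + 1e-9)
  if (n < 1L) return(character(0))
  tt <- (1:n) * dt_ms
  ends <- cumsum(path$sojourn_ms)
  idx <- findInterval(tt, ends, left.open = TRUE) + 1L
  idx[idx > nrow(path)] <- nrow(path)
  path$state[idx]
}

#' Emit a Gaussian current trace from a hidden state sequence
#'
#' Independent normal noise per sample around the state's group mean.
#'
#' @param states Character vector of hidden states (one per sample).
#' @param em [emission_model()].
#' @param dt_ms Sampling interval (ms).
#' @param conc [ligand_conc()] metadata.
#' @param seed Optional integer seed.
#' @param label Provenance label.
#' @return [ak_trace()].
#' @export
emit_trace <- function(states, em = emission_model(), dt_ms = 0.2,
                       conc = ligand_conc(), seed = NULL, label = "sim") {
  g <- em$group[states]
  mu <- em$mu[g]
  sg <- em$sigma[g]
  y <- with_seed(seed, rnorm(length(states), mean = mu, sd = sg))
  tr <- ak_trace(y, dt_ms = dt_ms, conc = conc, label = label)
  tr$hidden_states <- states
  tr
}

#' Experiment design for the synthetic generator
#'
#' One row per concentration condition. Defaults reproduce the study's
#' ATP/AMP design: six ATP/AMP concentration pairs, 3 replicates each
#' (within the reported 2-4 per condition), trace durations drawn from the
#' reported 500-10000 ms range (default fixed at 2000 ms for tractable
#' simulation), 0.2 ms sampling.
#'
#' @param conditions data.frame with columns `atp_mM`, `amp_mM`
#'   (and/or `adp_mM`), `n_replicates`, `duration_ms`.
#' @param dt_ms Sampling interval.
#' @param em [emission_model()] used for emission.
#' @return List of class `ak_design`.
#' @export
experiment_design <- function(conditions = NULL, dt_ms = 0.2,
                              em = emission_model()) {
  if (is.null(conditions)) {
    conditions <- data.frame(
      atp_mM = c(0.01, 0.10, 1.00, 1.00, 1.00, 1.00),
      amp_mM = c(0.00, 0.00, 0.00, 0.01, 0.10, 1.00),
      adp_mM = 0,
      n_replicates = 3L,
      duration_ms = 2000)
  }
  if (is.null(conditions$adp_mM)) conditions$adp_mM <- 0
  if (is.null(conditions$atp_mM)) conditions$atp_mM <- 0
  if (is.null(conditions$amp_mM)) conditions$amp_mM <- 0
  if (nrow(conditions) > 0 &&
      any(conditions$duration_ms < dt_ms))
    stop("every condition must span at least one sample")
  structure(list(conditions = conditions, dt_ms = dt_ms, em = em),
            class = "ak_design")
}

#' ADP titration design
#'
#' The study's ADP series: 0.01, 0.02, 0.05, 0.10, 0.20, 0.50, 1.00 mM.
#' @inheritParams experiment_design
#' @param n_replicates,duration_ms Per-condition replicate count and length.
#' @export
adp_design <- function(n_replicates = 3L, duration_ms = 2000, dt_ms = 0.2,
                       em = emission_model()) {
  experiment_design(data.frame(
    atp_mM = 0, amp_mM = 0,
    adp_mM = c(0.01, 0.02, 0.05, 0.10, 0.20, 0.50, 1.00),
    n_replicates = n_replicates, duration_ms = duration_ms),
    dt_ms = dt_ms, em = em)
}

#' Simulate a full synthetic experiment
#'
#' One trace per replicate per condition: a CTMC path is sampled from the
#' variant's generator at the condition's concentrations (initial state
#' drawn from the stationary distribution), discretized at the design's
#' sampling interval, and emitted with grouped Gaussian noise. Fully
#' reproducible given the seed.
#'
#' @param rates Named rate vector (s^-1).
#' @param variant Variant id or [ak_model].
#' @param design [experiment_design()].
#' @param seed Integer master seed; per-trace seeds are derived from it.
#' @return List of [ak_trace()] objects (with `$hidden_states` attached).
#' @export
simulate_experiment <- function(rates = rate_vector(), variant = "V3",
                                design = experiment_design(), seed = 1) {
  model <- ak_model_of(variant)
  cond <- design$conditions
  traces <- list()
  k <- 0L
  for (i in seq_len(nrow(cond))) {
    conc <- ligand_conc(atp_mM = cond$atp_mM[i], amp_mM = cond$amp_mM[i],
                        adp_mM = cond$adp_mM[i])
    Q <- model$build_Q(rates, conc)
    p0 <- stationary_distribution(discretize(Q, design$dt_ms))
    for (r in seq_len(cond$n_replicates[i])) {
      k <- k + 1L
      sd_path <- as.integer((as.numeric(seed) * 1000 + k * 2) %%
                              .Machine$integer.max)
      path <- sample_ctmc_path(Q, cond$duration_ms[i], p0 = p0,
                               seed = sd_path)
      st <- discretize_path(path, design$dt_ms)
      traces[[k]] <- emit_trace(
        st, em = design$em, dt_ms = design$dt_ms, conc = conc,
        seed = sd_path + 1L,
        label = sprintf("cond%02d_rep%d", i, r))
    }
  }
  traces
}

#' Inject open-pore / shallow artifacts into a trace
#'
#' Overwrites stretches of the trace with Gaussian noise around an
#' open-pore level (~ -433 pA) or a shallow level (>= -160 pA), emulating
#' the excursions that segment selection must remove.
#'
#' @param trace [ak_trace()].
#' @param artifacts data.frame with columns `type` ("open_pore" or
#'   "shallow"), `at_ms` (start; `NA` = random position), `duration_ms`.
#' @param open_pore_pA,shallow_pA Artifact level means.
#' @param sigma Artifact noise sd (pA).
#' @param seed Optional integer seed.
#' @return The modified [ak_trace()]; artifact positions recorded in
#'   `attr(, "artifacts")`.
#' @export
inject_artifacts <- function(trace, artifacts, open_pore_pA = -433,
                             shallow_pA = -150, sigma = 8, seed = NULL) {
  if (is.null(artifacts) || nrow(artifacts) == 0L) return(trace)
  n <- length(trace$current_pA)
  with_seed(seed, {
    placed <- artifacts
    placed$start_idx <- NA_integer_
    for (i in seq_len(nrow(artifacts))) {
      len <- max(1L, round(artifacts$duration_ms[i] / trace$dt_ms))
      start <- if (is.na(artifacts$at_ms[i]))
        sample.int(max(1L, n - len + 1L), 1L)
      else max(1L, round(artifacts$at_ms[i] / trace$dt_ms) + 1L)
      idx <- start:min(n, start + len - 1L)
      level <- switch(artifacts$type[i],
                      open_pore = open_pore_pA,
                      shallow = shallow_pA,
                      stop("unknown artifact type: ", artifacts$type[i]))
      trace$current_pA[idx] <- rnorm(length(idx), level, sigma)
      placed$start_idx[i] <- start
    }
    attr(trace, "artifacts") <- placed
    trace
  })
}

#' Simulate noisy Hill dose-response data
#'
#' Ground-truth generator for the dose-response fits:
#' `y = y_max * c^n / (K_D^n + c^n)` plus Gaussian noise, clipped to
#' `[0, 100]` (percent scale).
#'
#' @param K_D Half-saturation concentration (same units as `conc`).
#' @param n Hill coefficient.
#' @param y_max Plateau (percent).
#' @param conc Concentrations (> 0).
#' @param noise_sd Gaussian noise sd (percentage points).
#' @param replicates Replicates per concentration.
#' @param seed Optional integer seed.
#' @return data.frame with `conc`, `replicate`, `response`.
#' @export
simulate_dose_response <- function(K_D, n, y_max = 100, conc,
                                   noise_sd = 0, replicates = 1L,
                                   seed = NULL) {
  if (any(conc <= 0)) stop("concentrations must be positive")
  mu <- y_max * conc^n / (K_D^n + conc^n)
  out <- expand.grid(replicate = seq_len(replicates), conc = conc)
  out <- out[, c("conc", "replicate")]
  out$response <- with_seed(seed, {
    y <- rep(mu, each = replicates) + rnorm(nrow(out), 0, noise_sd)
    pmin(100, pmax(0, y))
  })
  rownames(out) <- NULL
  out
}
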