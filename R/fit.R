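#' Fit configuration
#'
#' Optimizer and parameterization settings for maximum-likelihood
#' estimation. Rates are optimized in log10 space (the default bounds
#' 1e-1..1e6 s^-1 map to -1..6), multi-started from random log-uniform
#' initial points; emission level means may float within a short interval
#' around their defaults and the shared emission sd within its plausible
#' range (7-10 pA).
#'
#' @param lower,upper Default rate bounds (s^-1).
#' @param bound_overrides Named list of `c(lo, hi)` native-scale bounds for
#'   individual rate parameters (the hook for data-informed bound
#'   adjustments).
#' @param step_tol Convergence tolerance passed to the optimizer.
#' @param max_iter Maximum optimizer iterations per start.
#' @param n_starts Number of multistarts (>= 1).
#' @param seed Master seed; per-start seeds derive deterministically.
#' @param fit_emission Float group means and the shared sd?
#' @param mean_halfwidth Half-width (pA) of the box around default group
#'   means.
#' @param sigma_bounds Bounds (pA) for the shared emission sd.
#' @param per_trace_offset Add one bounded baseline offset per trace?
#' @param offset_halfwidth Half-width (pA) for per-trace offsets.
#' @return List of class `ak_fit_config`.
#' @export
fit_config <- function(lower = 1e-1, upper = 1e6, bound_overrides = list(),
                       step_tol = 1e-3, max_iter = 200, n_starts = 6,
                       seed = 1, fit_emission = TRUE, mean_halfwidth = 3,
                       sigma_bounds = c(7, 10), per_trace_offset = FALSE,
                       offset_halfwidth = 3) {
  stopifnot(lower > 0, lower < upper, n_starts >= 1)
  structure(list(lower = lower, upper = upper,
                 bound_overrides = bound_overrides, step_tol = step_tol,
                 max_iter = max_iter, n_starts = n_starts, seed = seed,
                 fit_emission = fit_emission,
                 mean_halfwidth = mean_halfwidth,
                 sigma_bounds = sigma_bounds,
                 per_trace_offset = per_trace_offset,
                 offset_halfwidth = offset_halfwidth),
            class = "ak_fit_config")
}

# parameter packing: theta = [log10 rates | group means | sigma | offsets]
.fit_param_spec <- function(model, em, traces, config) {
  free <- model$free
  lo <- rep(log10(config$lower), length(free))
  hi <- rep(log10(config$upper), length(free))
  names(lo) <- names(hi) <- free
  for (p in intersect(names(config$bound_overrides), free)) {
    lo[p] <- log10(config$bound_overrides[[p]][1])
    hi[p] <- log10(config$bound_overrides[[p]][2])
  }
  spec <- list(free = free, rate_lo = lo, rate_hi = hi,
               mu0 = em$mu, sigma0 = mean(config$sigma_bounds))
  n_extra <- 0L
  if (config$fit_emission) n_extra <- n_extra + length(em$mu) + 1L
  if (config$per_trace_offset) n_extra <- n_extra + length(traces)
  spec$n_extra <- n_extra
  spec
}

.unpack_theta <- function(theta, spec, em, traces, config) {
  nf <- length(spec$free)
  rates <- setNames(10^theta[seq_len(nf)], spec$free)
  i <- nf
  mu <- em$mu
  sigma <- em$sigma
  if (config$fit_emission) {
    mu[] <- theta[i + seq_along(mu)]
    i <- i + length(mu)
    sigma[] <- theta[i + 1L]
    i <- i + 1L
  }
  offsets <- rep(0, length(traces))
  if (config$per_trace_offset) {
    offsets <- theta[i + seq_along(traces)]
    i <- i + length(traces)
  }
  list(rates = rates,
       em = emission_model(mu = mu, sigma = sigma, group = em$group),
       offsets = offsets)
}

.theta_bounds <- function(spec, em, traces, config) {
  lo <- spec$rate_lo
  hi <- spec$rate_hi
  if (config$fit_emission) {
    lo <- c(lo, em$mu - config$mean_halfwidth, config$sigma_bounds[1])
    hi <- c(hi, em$mu + config$mean_halfwidth, config$sigma_bounds[2])
  }
  if (config$per_trace_offset) {
    lo <- c(lo, rep(-config$offset_halfwidth, length(traces)))
    hi <- c(hi, rep(config$offset_halfwidth, length(traces)))
  }
  list(lo = unname(lo), hi = unname(hi))
}

.start_theta <- function(spec, em, traces, config, start_seed) {
  with_seed(start_seed, {
    th <- runif(length(spec$free), spec$rate_lo, spec$rate_hi)
    if (config$fit_emission) th <- c(th, em$mu, spec$sigma0)
    if (config$per_trace_offset) th <- c(th, rep(0, length(traces)))
    th
  })
}

#' Maximum-likelihood fit of a kinetic model to current traces
#'
#' Maximizes the joint scaled-forward log-likelihood over the variant's
#' free rate constants (log10 scale, bounded) and, optionally, the emission
#' level means / shared sd / per-trace baseline offsets, using bounded
#' quasi-Newton iterations (finite-difference gradients) multi-started from
#' random log-uniform initial points. The best start is reported; the run
#' is deterministic given `config$seed`.
#'
#' @param traces List of [ak_trace()] objects (each carries its own
#'   concentrations).
#' @param variant Variant id or [ak_model].
#' @param config [fit_config()].
#' @param em Emission model defining groups and default means.
#' @param extra_starts Optional list of warm starts, each a list with
#'   `rates` (named, native scale) and optionally `mu`/`sigma`; appended
#'   to the random multistarts (used by [compare_variants()] to seed each
#'   variant from the others' optima).
#' @return Object of class `ak_fit`: `rates` (full tied vector), `em`,
#'   `offsets`, `loglik`, `starts` (per-start table), `model`, `config`.
#' @export
fit_model <- function(traces, variant = "V3", config = fit_config(),
                      em = emission_model(), extra_starts = NULL) {
  if (length(traces) == 0L) stop("at least one trace is required")
  model <- ak_model_of(variant)
  em <- emission_model(mu = em$mu, sigma = em$sigma,
                       group = em$group[model$states])
  spec <- .fit_param_spec(model, em, traces, config)
  bounds <- .theta_bounds(spec, em, traces, config)

  negll <- function(theta) {
    p <- .unpack_theta(theta, spec, em, traces, config)
    ll <- tryCatch(
      joint_loglik(p$rates, p$em, traces, model, offsets = p$offsets),
      error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  # forward-difference gradient with the objective value at theta cached
  # from the optimizer's own fn call (halves the evals per iteration)
  last <- new.env(parent = emptyenv())
  fn <- function(theta) {
    v <- negll(theta)
    last$theta <- theta
    last$f <- v
    v
  }
  gr <- function(theta) {
    f0 <- if (!is.null(last$theta) && identical(last$theta, theta))
      last$f else negll(theta)
    g <- numeric(length(theta))
    for (i in seq_along(theta)) {
      h <- 1e-6 * max(1, abs(theta[i]))
      ti <- theta
      if (theta[i] + h <= bounds$hi[i]) {
        ti[i] <- theta[i] + h
        g[i] <- (negll(ti) - f0) / h
      } else {
        ti[i] <- theta[i] - h
        g[i] <- (f0 - negll(ti)) / h
      }
    }
    g
  }

  # random starts plus any supplied warm starts
  theta_of_start <- function(ws) {
    th <- log10(pmin(pmax(ws$rates[spec$free], 10^spec$rate_lo),
                     10^spec$rate_hi))
    if (config$fit_emission) {
      mu <- if (is.null(ws$mu)) em$mu else ws$mu[names(em$mu)]
      sg <- if (is.null(ws$sigma)) spec$sigma0 else ws$sigma[[1L]]
      th <- c(th, pmin(pmax(mu, em$mu - config$mean_halfwidth),
                       em$mu + config$mean_halfwidth),
              min(max(sg, config$sigma_bounds[1]), config$sigma_bounds[2]))
    }
    if (config$per_trace_offset) th <- c(th, rep(0, length(traces)))
    unname(th)
  }
  n_all <- config$n_starts + length(extra_starts)
  starts <- data.frame(start = seq_len(n_all),
                       loglik0 = NA_real_, loglik = NA_real_,
                       convergence = NA_integer_)
  best <- NULL
  for (s in seq_len(n_all)) {
    th0 <- if (s <= config$n_starts)
      .start_theta(spec, em, traces, config,
                   start_seed = as.integer(
                     (as.numeric(config$seed) * 101 + s) %%
                       .Machine$integer.max))
    else theta_of_start(extra_starts[[s - config$n_starts]])
    starts$loglik0[s] <- -negll(th0)
    run_opt <- function(par) tryCatch(
      optim(par, fn, gr, method = "L-BFGS-B",
            lower = bounds$lo, upper = bounds$hi,
            control = list(maxit = config$max_iter,
                           factr = config$step_tol * 1e12)),
      error = function(e) NULL)
    fit <- run_opt(th0)
    # line searches on finite-difference gradients occasionally abort
    # (convergence 52); a restart from the stopped point with a fresh
    # Hessian approximation usually recovers
    for (retry in 1:2) {
      if (is.null(fit) || fit$convergence == 0) break
      fit2 <- run_opt(fit$par)
      if (is.null(fit2) || fit2$value >= fit$value - 1e-8) break
      fit <- fit2
    }
    if (is.null(fit)) next
    starts$loglik[s] <- -fit$value
    starts$convergence[s] <- fit$convergence
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || best$value >= 1e10)
    stop("no multistart produced a finite likelihood")

  p <- .unpack_theta(best$par, spec, em, traces, config)
  full <- p$rates
  if (!is.null(model$variant_id) && model$variant_id %in% .AK_VARIANTS) {
    full <- rate_vector()
    full[names(p$rates)] <- p$rates
    full <- apply_variant(full, model$variant_id)
  }
  structure(list(rates = full, em = p$em, offsets = p$offsets,
                 loglik = -best$value, starts = starts,
                 model = model, config = config, seed = config$seed),
            class = "ak_fit")
}

#' @export
print.ak_fit <- function(x, ...) {
  cat(sprintf("<ak_fit %s: logL = %.2f over %d start(s)>\n",
              x$model$variant_id, x$loglik, nrow(x$starts)))
  invisible(x)
}

#' Compare endosteric model variants by maximal likelihood
#'
#' Fits each variant independently to the same trace set and tabulates the
#' maximized log-likelihoods; the comparison is between raw maxima (no
#' information criterion), as the variants encode structural hypotheses
#' rather than nested penalty classes. `delta_loglik` is relative to the
#' best variant (<= 0). Also reports AIC as a clearly-separate extra.
#'
#' @inheritParams fit_model
#' @param variants Character vector (or list of [ak_model]) of variants.
#' @return Object of class `ak_comparison`: `table` (data.frame) and
#'   `fits` (named list of [fit_model()] results).
#' @export
compare_variants <- function(traces, variants = c("V1", "V2", "V3"),
                             config = fit_config(), em = emission_model()) {
  fits <- lapply(variants, function(v)
    fit_model(traces, v, config = config, em = em))
  # second pass: re-polish each variant from the other variants' optima
  # (the shared rate naming makes every optimum a valid start everywhere,
  # and V1's optimum is exactly expressible in V3, so the richer model can
  # never be reported below its special case for lack of a good start)
  if (length(fits) > 1L) {
    warm_of <- function(f) list(rates = f$rates, mu = f$em$mu,
                                sigma = f$em$sigma)
    for (i in seq_along(fits)) {
      ws <- lapply(fits[-i], warm_of)
      ok <- vapply(ws, function(w)
        all(ak_model_of(variants[[i]])$free %in% names(w$rates)),
        logical(1))
      if (!any(ok)) next
      cfg1 <- config
      cfg1$n_starts <- 1L  # one random start + the warm starts
      refit <- fit_model(traces, variants[[i]], config = cfg1, em = em,
                         extra_starts = ws[ok])
      if (refit$loglik > fits[[i]]$loglik) fits[[i]] <- refit
    }
  }
  ids <- vapply(fits, function(f) f$model$variant_id, character(1))
  names(fits) <- make.unique(ids)
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  k <- vapply(fits, function(f) length(f$model$free), numeric(1))
  tab <- data.frame(variant = ids, n_free_rates = k, loglik = ll,
                    delta_loglik = ll - max(ll),
                    AIC = 2 * k - 2 * ll, row.names = NULL)
  structure(list(table = tab[order(-tab$loglik), ], fits = fits),
            class = "ak_comparison")
}

#' @export
print.ak_comparison <- function(x, ...) {
  cat("<ak_comparison>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Aggregate domain closing/opening rates by path simulation
#'
#' Simulates one CTMC sample path from the model at the given
#' concentrations, merges consecutive sojourns into dwells in the LID-open
#' versus LID-closed state groups, and reports the inverse mean completed
#' dwell: the inverse dwell in the open group is the aggregate LID closing
#' rate, in the closed group the LID opening rate. The first and last
#' group dwells are censored (they do not terminate in an observed
#' transition) and excluded. NMP rates are computed the same way over the
#' NMP groups when the model defines them.
#'
#' @param rates Named rate vector (s^-1).
#' @param variant Variant id or [ak_model].
#' @param conc [ligand_conc()].
#' @param duration_ms Path duration (default 20000 ms).
#' @param seed Optional integer seed.
#' @return List of class `ak_aggregate` with `lid_closing_s`,
#'   `lid_opening_s` (s^-1; `NA` + flag when no completed dwell),
#'   `nmp_closing_s`, `nmp_opening_s`, dwell counts, `duration_ms`, `seed`.
#' @export
predict_aggregate_rates <- function(rates, variant = "V3",
                                    conc = ligand_conc(atp_mM = 1),
                                    duration_ms = 20000, seed = NULL) {
  model <- ak_model_of(variant)
  Q <- model$build_Q(rates, .as_conc(conc))
  p0 <- stationary_distribution(discretize(Q, 0.2))
  lid <- model$states %in% model$lid_closed
  nmp <- model$states %in% model$nmp_closed
  # simulate once, merged over the 4-way (LID x NMP) partition; memory and
  # post-processing then scale with observable switches, not microscopic
  # jumps (robust to fast intra-group equilibria in fitted rates)
  gid <- 1L + as.integer(lid) + 2L * as.integer(nmp)
  raw <- with_seed(seed,
                   .sample_ctmc_grouped(Q * 1e-3, duration_ms,
                                        as.numeric(p0), gid))
  lid_stats <- .binary_dwell_rates(raw, c(FALSE, TRUE, FALSE, TRUE))
  out <- list(lid_closing_s = lid_stats$entry_rate,
              lid_opening_s = lid_stats$exit_rate,
              n_dwells_lid_open = lid_stats$n_open,
              n_dwells_lid_closed = lid_stats$n_closed,
              duration_ms = duration_ms, seed = seed)
  if (length(model$nmp_closed)) {
    nmp_stats <- .binary_dwell_rates(raw, c(FALSE, FALSE, TRUE, TRUE))
    out$nmp_closing_s <- nmp_stats$entry_rate
    out$nmp_opening_s <- nmp_stats$exit_rate
    out$n_dwells_nmp_open <- nmp_stats$n_open
    out$n_dwells_nmp_closed <- nmp_stats$n_closed
  }
  structure(out, class = "ak_aggregate")
}

# dwell statistics for a binary partition defined over the 4-way group ids:
# entry rate = 1 / mean completed dwell in the "open" (FALSE) side,
# exit rate  = 1 / mean completed dwell in the "closed" (TRUE) side;
# the first and last dwells are censored (no observed terminating jump)
.binary_dwell_rates <- function(raw, closed_of_gid) {
  v <- closed_of_gid[raw$group]
  r <- rle(v)
  ends <- cumsum(r$lengths)
  cs <- cumsum(raw$dwell_ms)
  dwell <- cs[ends] - c(0, cs[head(ends, -1L)])
  keep <- seq_along(dwell)
  keep <- keep[keep > 1L & keep < length(dwell)]
  open_d <- dwell[keep][!r$values[keep]]
  closed_d <- dwell[keep][r$values[keep]]
  list(entry_rate = if (length(open_d)) 1000 / mean(open_d) else NA_real_,
       exit_rate = if (length(closed_d)) 1000 / mean(closed_d) else NA_real_,
       n_open = length(open_d), n_closed = length(closed_d))
}

#' Case-resampling bootstrap intervals for fitted rates
#'
#' Resamples traces with replacement, refits each replicate, and reports
#' percentile intervals over the replicate estimates (the point estimate is
#' included among the replicates, so intervals always contain it). This is
#' generic resampling plumbing, not a reproduction of any specific
#' interval method.
#'
#' @inheritParams fit_model
#' @param n_boot Number of bootstrap replicates (>= 2).
#' @param level Interval coverage (default 0.9).
#' @param seed Seed for the resampling (and, derived, each refit).
#' @return List of class `ak_boot`: `intervals` data.frame (`param`,
#'   `point`, `lower`, `upper`), `replicates` matrix, `point_fit`.
#' @export
bootstrap_confidence <- function(traces, variant = "V3",
                                 config = fit_config(), n_boot = 20,
                                 level = 0.9, seed = 1,
                                 em = emission_model()) {
  if (n_boot < 2) stop("n_boot must be >= 2")
  model <- ak_model_of(variant)
  point <- fit_model(traces, model, config = config, em = em)
  est <- function(f) f$rates[model$free]
  reps <- matrix(NA_real_, nrow = n_boot, ncol = length(model$free),
                 dimnames = list(NULL, model$free))
  idx_list <- with_seed(seed, lapply(seq_len(n_boot), function(b)
    sample.int(length(traces), replace = TRUE)))
  for (b in seq_len(n_boot)) {
    # same optimizer seed for every replicate: identical resampled data
    # must refit identically, so interval width reflects resampling only
    fb <- tryCatch(
      fit_model(traces[idx_list[[b]]], model, config = config, em = em),
      error = function(e) NULL)
    if (!is.null(fb)) reps[b, ] <- est(fb)
  }
  a <- (1 - level) / 2
  pool <- rbind(reps[stats::complete.cases(reps), , drop = FALSE],
                est(point))
  ci <- t(apply(pool, 2, quantile, probs = c(a, 1 - a), names = FALSE))
  # percentile interpolation can clip the extreme pooled value; widen so
  # the observed point estimate is always contained
  ci[, 1] <- pmin(ci[, 1], est(point))
  ci[, 2] <- pmax(ci[, 2], est(point))
  structure(list(
    intervals = data.frame(param = model$free, point = unname(est(point)),
                           lower = ci[, 1], upper = ci[, 2],
                           row.names = NULL),
    replicates = reps, point_fit = point, level = level, seed = seed),
    class = "ak_boot")
}
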