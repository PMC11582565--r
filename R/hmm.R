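#' Discretize a CTMC generator
#'
#' Transition probability matrix of the sampled chain,
#' `Gamma = exp(dt * Q)`, computed by scaling-and-squaring. `Q` is in s^-1
#' and `dt` in ms (the unit conversion happens here and nowhere else). The
#' default step equals the 0.2 ms recording interval so that no transition
#' faster than the sampling is lost to coarser discretization.
#'
#' @param Q Square generator matrix (s^-1), rows summing to zero.
#' @param dt_ms Time step in ms (> 0).
#' @return Stochastic matrix with the same dimnames as `Q`.
#' @export
discretize <- function(Q, dt_ms = 0.2) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) stop("Q must be a square matrix")
  if (!is.numeric(dt_ms) || length(dt_ms) != 1L || dt_ms <= 0)
    stop("dt_ms must be a positive scalar")
  G <- .expm_generator(Q * 1e-3, dt_ms)
  dimnames(G) <- dimnames(Q)
  G
}

# Reachability closure over the positive entries of a rate/probability
# matrix; TRUE iff every state reaches every other.
.is_irreducible <- function(M, tol = 0) {
  all(.reachability(M, tol))
}

.reachability <- function(M, tol = 0) {
  R <- (M > tol) | diag(nrow(M)) > 0
  for (i in seq_len(ceiling(log2(nrow(M))) + 1L)) R <- (R %*% R) > 0
  R
}

# A finite chain has a unique stationary law iff it has exactly one
# recurrent communicating class (transient states then carry zero mass).
.has_unique_stationary <- function(M, tol = 0) {
  R <- .reachability(M, tol)
  recurrent <- vapply(seq_len(nrow(R)),
                      function(i) all(R[R[i, ], i]), logical(1))
  if (!any(recurrent)) return(FALSE)
  rec <- which(recurrent)
  all(R[rec, rec])
}

#' Stationary distribution of a discrete-time chain
#'
#' Solves `delta' Gamma = delta'` for the unique invariant probability
#' vector of an irreducible transition matrix (left eigenvector of
#' eigenvalue 1, normalized to sum one).
#'
#' @param G Stochastic matrix.
#' @return Probability vector named by states.
#' @export
stationary_distribution <- function(G) {
  n <- nrow(G)
  if (n == 1L) return(setNames(1, rownames(G)))
  if (!.has_unique_stationary(G, tol = 1e-14))
    stop("transition matrix is reducible: stationary distribution not unique")
  # solve (t(G) - I) x = 0 with sum(x) = 1 as a bordered linear system;
  # for ill-conditioned chains fall back to repeated squaring of G, whose
  # rows converge to the stationary law for any aperiodic unichain
  x <- tryCatch({
    A <- rbind(t(G) - diag(n), rep(1, n))
    v <- qr.solve(A, c(rep(0, n), 1))
    if (any(v < -1e-9)) stop("negative mass")
    v
  }, error = function(e) {
    P <- G
    for (i in 1:60) {
      P <- P %*% P
      P <- P / rowSums(P)
    }
    colMeans(P)
  })
  x[x < 0] <- 0
  setNames(x / sum(x), rownames(G))
}

#' Grouped Gaussian emission model
#'
#' One normal emission distribution per observable current level; hidden
#' states with the same LID/NMP arrangement share the level exactly, since
#' ligand binding itself is invisible in the current. Default level means
#' derive from the measured residual-current fractions of the M, M1, M2 and
#' M3 levels against an open-pore current of -433.3 pA, with the anomalous
#' shallow M0 level near -180 pA.
#'
#' @param mu Named numeric vector of group means (pA).
#' @param sigma Group standard deviations (pA); a scalar is recycled.
#' @param group Named character vector mapping state -> group (defaults to
#'   the enzyme chain's grouping).
#' @return Object of class `ak_emission`.
#' @export
emission_model <- function(mu = c(M0 = -180, M = -199.3, M1 = -211.0,
                                  M2 = -221.0, M3 = -233.1),
                           sigma = 8, group = .AK_GROUP) {
  if (length(sigma) == 1L) sigma <- setNames(rep(sigma, length(mu)), names(mu))
  sigma <- sigma[names(mu)]
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("all emission standard deviations must be positive")
  if (!all(group %in% names(mu)))
    stop("every emission group must have a mean")
  structure(list(mu = mu, sigma = sigma, group = group),
            class = "ak_emission")
}

#' Per-state emission density vector
#'
#' Gaussian density of one current sample under every hidden state; states
#' in the same emission group receive identical entries.
#'
#' @param y Current sample (pA), scalar or vector.
#' @param em [emission_model()].
#' @param states States to evaluate (default: all mapped states).
#' @return For scalar `y` a named vector; otherwise a `states x T` matrix.
#' @export
emission_density_vector <- function(y, em, states = names(em$group)) {
  g <- em$group[states]
  groups <- unique(g)
  # densities per group, expanded to states (states sharing a group get
  # identical rows)
  Dg <- matrix(0, length(groups), length(y),
               dimnames = list(groups, NULL))
  for (gr in groups) {
    z <- (y - em$mu[[gr]]) / em$sigma[[gr]]
    Dg[gr, ] <- exp(-0.5 * z * z) / (em$sigma[[gr]] * sqrt(2 * pi))
  }
  D <- Dg[match(g, groups), , drop = FALSE]
  if (length(y) == 1L) return(setNames(D[, 1L], states))
  rownames(D) <- states
  D  # states x T
}

# density matrix (states x T) for a trace, with optional additive mean
# offset applied to every non-M0 group (per-segment baseline shift)
.density_matrix <- function(trace, em, states, offset = 0) {
  if (offset != 0) {
    mu <- em$mu
    shift <- names(mu) != "M0"
    mu[shift] <- mu[shift] + offset
    em <- emission_model(mu = mu, sigma = em$sigma, group = em$group)
  }
  emission_density_vector(trace$current_pA, em, states)
}

#' Scaled forward log-likelihood of a current trace
#'
#' Evaluates `L = delta' (prod_t B_t) 1` with `B_t = Gamma diag(phi(y_t))`,
#' where `delta'` is the stationary distribution of `Gamma`. The stationary
#' prior is propagated through `Gamma` before every emission *including the
#' first* (the model's stated ordering). Per-step normalization of the
#' forward vector avoids underflow; the log-normalizers sum to the exact
#' log-likelihood.
#'
#' @param G Transition matrix over the model's states.
#' @param em [emission_model()].
#' @param trace [ak_trace()] (or any list with `current_pA`).
#' @param delta Optional initial row distribution; defaults to the
#'   stationary distribution of `G`.
#' @param filtered Keep per-step filtered state probabilities?
#' @param offset Additive segment mean offset (pA) applied to all non-M0
#'   level means.
#' @return List with `loglik`, `logscale` (per-step log normalizers),
#'   `delta`, and optionally `filtered` (states x T).
#' @export
forward_loglik <- function(G, em, trace, delta = NULL, filtered = FALSE,
                           offset = 0) {
  y <- trace$current_pA
  if (length(y) < 1L) stop("trace must contain at least one sample")
  if (any(!is.finite(y))) stop("trace contains non-finite samples")
  states <- rownames(G)
  if (is.null(states)) states <- names(em$group)[seq_len(nrow(G))]
  if (is.null(delta)) delta <- stationary_distribution(G)
  dens <- .density_matrix(trace, em, states, offset)
  if (length(y) == 1L) dens <- matrix(dens, ncol = 1L)
  res <- .forward_filter(G, dens, rbind(delta), filtered)
  res$delta <- delta
  if (!is.null(res$filtered)) rownames(res$filtered) <- states
  res
}

#' Joint log-likelihood over independent traces
#'
#' Traces are independent recordings, so the joint likelihood is the
#' product of per-trace likelihoods; each trace's transition matrix is
#' rebuilt from the shared rates at that trace's own ligand concentrations,
#' and its stationary distribution serves as the initial law.
#'
#' @param rates Named rate vector (s^-1).
#' @param em [emission_model()].
#' @param traces List of [ak_trace()] objects carrying concentrations.
#' @param variant Variant id or [ak_model].
#' @param dt_ms Sampling interval override; defaults to each trace's own.
#' @param offsets Optional numeric vector of per-trace mean offsets (pA).
#' @return Total log-likelihood (scalar).
#' @export
joint_loglik <- function(rates, em, traces, variant = "V3", dt_ms = NULL,
                         offsets = NULL) {
  if (length(traces) == 0L) stop("empty trace list")
  model <- ak_model_of(variant)
  if (is.null(offsets)) offsets <- rep(0, length(traces))
  total <- 0
  cache <- new.env(parent = emptyenv())
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    key <- paste(tr$conc$atp_mM, tr$conc$amp_mM, tr$conc$adp_mM,
                 if (is.null(dt_ms)) tr$dt_ms else dt_ms)
    if (is.null(cache[[key]])) {
      Q <- model$build_Q(rates, tr$conc)
      G <- discretize(Q, if (is.null(dt_ms)) tr$dt_ms else dt_ms)
      cache[[key]] <- list(G = G, delta = stationary_distribution(G))
    }
    cc <- cache[[key]]
    total <- total +
      forward_loglik(cc$G, em, tr, delta = cc$delta,
                     offset = offsets[i])$loglik
    if (!is.finite(total)) return(-Inf)
  }
  total
}
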