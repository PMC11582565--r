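#' Hill equation fit
#'
#' Least-squares fit of the Hill dose-response. Increasing form:
#' `y = y_max * c^n / (K_D^n + c^n)`; decreasing form (used for opening
#' frequencies that plateau at a nonzero floor):
#' `y = y_max - (y_max - y_min) * c^n / (K_D^n + c^n)`.
#' Starts are deterministic: `K_D` at the geometric mean of the
#' concentrations and `n = 1`, so fits are reproducible without a global
#' search. `K_D` is reported in the units of `conc` (this module works in
#' uM by convention; see [um_to_mM()]).
#'
#' @param conc Concentrations (> 0; >= 3 distinct values).
#' @param response Responses (same length).
#' @param increasing Increasing (binding/closing) or decreasing (opening
#'   frequency) form.
#' @return List of class `ak_hill`: `K_D`, `n`, `y_max`, `y_min`,
#'   standard errors, `resid_norm`, `converged`, `fit`.
#' @export
hill_fit <- function(conc, response, increasing = TRUE) {
  if (length(unique(conc)) < 3L)
    stop("at least 3 distinct concentrations are required")
  if (any(conc <= 0)) stop("concentrations must be positive")
  df <- data.frame(conc = conc, response = response)
  K0 <- exp(mean(log(unique(conc))))
  fit <- tryCatch({
    if (increasing) {
      minpack.lm::nlsLM(
        response ~ ymax * conc^n / (K^n + conc^n), data = df,
        start = list(ymax = max(response), K = K0, n = 1),
        lower = c(1e-12, 1e-12, 0.05), upper = c(Inf, Inf, 20),
        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      minpack.lm::nlsLM(
        response ~ ymax - (ymax - ymin) * conc^n / (K^n + conc^n), data = df,
        start = list(ymax = max(response), ymin = min(response),
                     K = K0, n = 1),
        lower = c(-Inf, -Inf, 1e-12, 0.05), upper = c(Inf, Inf, Inf, 20),
        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }, error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(K_D = NA_real_, n = NA_real_, y_max = NA_real_,
                          y_min = if (increasing) 0 else NA_real_,
                          se = NULL, resid_norm = NA_real_,
                          converged = FALSE, message = conditionMessage(fit)),
                     class = "ak_hill"))
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) cf * NA)
  structure(list(
    K_D = cf[["K"]], n = cf[["n"]], y_max = cf[["ymax"]],
    y_min = if (increasing) 0 else cf[["ymin"]],
    se = c(K_D = unname(se["K"]), n = unname(se["n"])),
    resid_norm = sqrt(sum(stats::residuals(fit)^2)),
    converged = TRUE, fit = fit), class = "ak_hill")
}

#' Linear fit of closing frequency against ligand concentration
#'
#' Ordinary least squares; the slope is the apparent association rate
#' constant `k_on` in the units of `1/(conc unit x s)`.
#'
#' @param conc Concentrations (>= 2 distinct).
#' @param closing_frequency Frequencies (s^-1).
#' @return List of class `ak_linear`: `slope`, `intercept`, `se`, `fit`.
#' @export
linear_fit <- function(conc, closing_frequency) {
  if (length(unique(conc)) < 2L)
    stop("degenerate design: at least 2 distinct concentrations required")
  fit <- lm(closing_frequency ~ conc)
  cf <- coef(fit)
  se <- suppressWarnings(sqrt(diag(vcov(fit))))
  structure(list(slope = unname(cf["conc"]),
                 intercept = unname(cf["(Intercept)"]),
                 se = c(slope = unname(se["conc"]),
                        intercept = unname(se["(Intercept)"])),
                 fit = fit), class = "ak_linear")
}

#' One-site specific binding fit
#'
#' Least-squares fit of `y = B_max * x / (K_d + x)` (used for the
#' Mg2+-dependence of the M2 to M3 transition fraction).
#'
#' @param x Concentrations (>= 3 points).
#' @param y Responses.
#' @return List of class `ak_binding`: `B_max`, `K_d`, `se`, `converged`.
#' @export
one_site_binding_fit <- function(x, y) {
  if (length(x) < 3L) stop("at least 3 points are required")
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ Bmax * x / (Kd + x),
                      data = data.frame(x = x, y = y),
                      start = list(Bmax = max(y), Kd = stats::median(x)),
                      lower = c(1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(structure(list(B_max = NA_real_, K_d = NA_real_, se = NULL,
                          converged = FALSE,
                          message = conditionMessage(fit)),
                     class = "ak_binding"))
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) cf * NA)
  structure(list(B_max = cf[["Bmax"]], K_d = cf[["Kd"]],
                 se = c(B_max = unname(se["Bmax"]), K_d = unname(se["Kd"])),
                 converged = TRUE, fit = fit), class = "ak_binding")
}

#' Steady-state closed fraction of a two-state binding-closure scheme
#'
#' `100 * k_on * c / (k_on * c + k_off)`: the percentage of time spent
#' closed when closure follows first-order association at `k_on * c` and
#' reopening at `k_off`. Consistency check relating the measured
#' association / opening rate constants to the measured percent-closed.
#'
#' @param k_on Association rate constant (uM^-1 s^-1).
#' @param conc Ligand concentration (uM).
#' @param k_off Opening rate (s^-1).
#' @return Percent closed.
#' @export
two_state_closed_fraction <- function(k_on, conc, k_off) {
  if (any(k_on <= 0) || any(k_off <= 0)) stop("k_on and k_off must be > 0")
  100 * k_on * conc / (k_on * conc + k_off)
}

#' Concentration unit converters
#'
#' The dose-response interface works in uM (dissociation constants are
#' reported in uM) while the kinetic generator takes mM.
#'
#' @param x Concentration value(s).
#' @export
um_to_mM <- function(x) x / 1000

#' @rdname um_to_mM
#' @export
mM_to_um <- function(x) x * 1000
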