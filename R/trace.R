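#' Nanopore current trace
#'
#' A sampled current series (pA, sign-preserving: blockade currents are
#' negative at -90 mV) with its sampling interval and ligand-concentration
#' metadata.
#'
#' @param current_pA Numeric vector of current samples (>= 1 sample).
#' @param dt_ms Constant sampling interval in ms.
#' @param conc [ligand_conc()] for the recording condition.
#' @param label Provenance label.
#' @return Object of class `ak_trace`.
#' @export
ak_trace <- function(current_pA, dt_ms = 0.2, conc = ligand_conc(),
                     label = "trace") {
  if (length(current_pA) < 1L) stop("trace must contain at least one sample")
  if (!is.numeric(dt_ms) || length(dt_ms) != 1L || dt_ms <= 0)
    stop("dt_ms must be a positive scalar")
  structure(list(current_pA = as.numeric(current_pA), dt_ms = dt_ms,
                 conc = .as_conc(conc), label = label),
            class = "ak_trace")
}

#' @export
print.ak_trace <- function(x, ...) {
  cat(sprintf(
    "<ak_trace '%s': %d samples @ %g ms (%.1f ms), ATP %g / AMP %g / ADP %g mM>\n",
    x$label, length(x$current_pA), x$dt_ms, length(x$current_pA) * x$dt_ms,
    x$conc$atp_mM, x$conc$amp_mM, x$conc$adp_mM))
  invisible(x)
}

#' Trace duration in ms
#' @param trace [ak_trace()].
#' @export
trace_duration_ms <- function(trace) length(trace$current_pA) * trace$dt_ms

# evaluate `code` under a temporary RNG state seeded with `seed`;
# NULL seed leaves the RNG alone
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
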