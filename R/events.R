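#' Select usable trace segments
#'
#' Screens a trace with a sliding-window mean and keeps the contiguous runs
#' whose local mean lies strictly between the open-pore exclusion cutoff
#' (default -350 pA; open-pore excursions sit around -400 pA and below) and
#' the shallow cutoff (default -160 pA and above excluded). All thresholds
#' are on the signed (negative) current scale.
#'
#' @param trace [ak_trace()].
#' @param open_pore_cutoff Exclude windows with mean below this (pA).
#' @param shallow_cutoff Exclude windows with mean at/above this (pA).
#' @param window_ms Sliding-window length (ms; >= one sample).
#' @return List of `ak_segment` objects: `samples`, `start` / `end`
#'   (0-based half-open sample indices into the parent), `dt_ms`, `conc`,
#'   `label`.
#' @export
select_segments <- function(trace, open_pore_cutoff = -350,
                            shallow_cutoff = -160, window_ms = 50) {
  y <- trace$current_pA
  w <- max(1L, round(window_ms / trace$dt_ms))
  if (w > length(y)) w <- length(y)
  # centered running mean via cumulative sums; edges use the available span
  cs <- cumsum(c(0, y))
  half <- w %/% 2L
  i <- seq_along(y)
  lo <- pmax(1L, i - half)
  hi <- pmin(length(y), lo + w - 1L)
  lo <- pmax(1L, hi - w + 1L)
  m <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  ok <- m > open_pore_cutoff & m < shallow_cutoff
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  segs <- list()
  for (j in which(runs$values)) {
    idx <- starts[j]:ends[j]
    segs[[length(segs) + 1L]] <- structure(list(
      samples = y[idx], start = starts[j] - 1L, end = ends[j],
      dt_ms = trace$dt_ms, conc = trace$conc,
      label = sprintf("%s[%d,%d)", trace$label, starts[j] - 1L, ends[j])),
      class = "ak_segment")
  }
  segs
}

#' Pick one random segment per condition and right-truncate
#'
#' Selects a uniformly random segment for each experimental condition and
#' truncates every selection on the right to the least of the shortest
#' selected segment's length and `max_len_ms`.
#'
#' @param segments_by_condition Named list: condition -> list of
#'   `ak_segment`.
#' @param max_len_ms Truncation cap (default 1000 ms).
#' @param seed Optional integer seed.
#' @return Named list of truncated `ak_segment`s, one per condition.
#' @export
pick_fit_segments <- function(segments_by_condition, max_len_ms = 1000,
                              seed = NULL) {
  if (any(vapply(segments_by_condition, length, integer(1)) == 0L))
    stop("every condition must contribute at least one segment")
  picked <- with_seed(seed, lapply(segments_by_condition, function(segs)
    segs[[sample.int(length(segs), 1L)]]))
  len_ms <- vapply(picked, function(s) length(s$samples) * s$dt_ms,
                   numeric(1))
  cap <- min(min(len_ms), max_len_ms)
  lapply(picked, function(s) {
    n <- floor(cap / s$dt_ms + 1e-9)
    s$samples <- s$samples[seq_len(n)]
    s$end <- s$start + n
    s
  })
}

#' All-point amplitude histogram
#'
#' Uniform-width histogram of every sample in a segment, with bin edges
#' anchored at 0 pA so that binning is reproducible across runs.
#'
#' @param x `ak_segment`, [ak_trace()] or numeric vector of currents (pA).
#' @param bin_width Bin width in pA (default 0.1).
#' @return List of class `ak_histogram`: `edges`, `mids`, `counts`.
#' @export
all_point_histogram <- function(x, bin_width = 0.1) {
  if (!is.numeric(x)) x <- if (!is.null(x$samples)) x$samples else x$current_pA
  if (bin_width <= 0) stop("bin_width must be positive")
  b0 <- floor(min(x) / bin_width)
  b1 <- floor(max(x) / bin_width)
  idx <- pmin(floor(x / bin_width) - b0 + 1L, b1 - b0 + 1L)
  counts <- tabulate(idx, nbins = b1 - b0 + 1L)
  edges <- (b0:(b1 + 1L)) * bin_width
  structure(list(edges = edges, mids = head(edges, -1L) + bin_width / 2,
                 counts = counts),
            class = "ak_histogram")
}

#' Multi-Gaussian fit to an all-point histogram
#'
#' Least-squares fit of a sum of `n_peaks` Gaussians to the histogram
#' counts (Levenberg-Marquardt). Peaks are returned ordered by mean.
#'
#' @param hist [all_point_histogram()] result.
#' @param n_peaks Number of peaks (>= 1).
#' @param means Initial peak means (pA); required for `n_peaks > 1`.
#' @param sd0 Initial common sd (pA).
#' @return data.frame of class `ak_peaks` (`mean`, `sd`, `height`) with
#'   attribute `converged`.
#' @export
fit_gaussian_peaks <- function(hist, n_peaks = 1, means = NULL, sd0 = 8) {
  stopifnot(n_peaks >= 1)
  x <- hist$mids
  y <- hist$counts
  if (is.null(means)) {
    if (n_peaks > 1) stop("initial means required for n_peaks > 1")
    means <- sum(x * y) / sum(y)
  }
  if (length(means) != n_peaks) stop("need one initial mean per peak")
  h0 <- rep(max(y), n_peaks)
  par0 <- c(means, rep(sd0, n_peaks), h0)
  model_fn <- function(p) {
    mu <- p[seq_len(n_peaks)]
    sg <- p[n_peaks + seq_len(n_peaks)]
    hh <- p[2 * n_peaks + seq_len(n_peaks)]
    rowSums(vapply(seq_len(n_peaks),
                   function(k) hh[k] * exp(-(x - mu[k])^2 / (2 * sg[k]^2)),
                   numeric(length(x))))
  }
  lo <- c(rep(min(x), n_peaks), rep(0.2, n_peaks), rep(0, n_peaks))
  hi <- c(rep(max(x), n_peaks), rep(diff(range(x)) + 1, n_peaks),
          rep(max(y) * 10 + 1, n_peaks))
  fit <- tryCatch(
    minpack.lm::nls.lm(par0, lower = lo, upper = hi,
                       fn = function(p) y - model_fn(p),
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  converged <- !is.null(fit) && fit$info %in% 1:4
  p <- if (is.null(fit)) par0 else fit$par
  out <- data.frame(mean = p[seq_len(n_peaks)],
                    sd = p[n_peaks + seq_len(n_peaks)],
                    height = p[2 * n_peaks + seq_len(n_peaks)])
  out <- out[order(out$mean), ]
  rownames(out) <- NULL
  at_bound <- any(abs(out$sd - 0.2) < 1e-8)
  structure(out, class = c("ak_peaks", "data.frame"),
            converged = converged && !at_bound)
}

#' Per-level occurrence from peak heights
#'
#' Percent occupancy of each current level computed from the heights
#' (counts at the peak maxima, not areas) of the fitted histogram peaks;
#' percentages sum to 100.
#'
#' @param peaks [fit_gaussian_peaks()] result or numeric vector of heights.
#' @return Numeric vector of percentages.
#' @export
occurrence_percent <- function(peaks) {
  h <- if (is.data.frame(peaks)) peaks$height else as.numeric(peaks)
  if (length(h) < 1L) stop("at least one peak is required")
  100 * h / sum(h)
}

#' Residual current percentage
#'
#' `I_RES = (I_B / I_O) * 100`, the percent ratio of the blocked-pore to
#' the open-pore current. Same-sign inputs give a positive percentage.
#'
#' @param i_b Blocked-pore current (pA).
#' @param i_o Open-pore current (pA, non-zero).
#' @return Percentage.
#' @export
residual_current <- function(i_b, i_o) {
  if (any(i_o == 0)) stop("open-pore current must be non-zero")
  (i_b / i_o) * 100
}

#' Idealize a segment into discrete level events
#'
#' Half-amplitude threshold idealization: each sample is assigned to the
#' configured level whose band it falls in (thresholds at the midpoints
#' between adjacent level means), the assignment is run-length encoded, and
#' events shorter than `min_dwell_ms` are merged into the preceding event
#' (the first event merges forward) until all events meet the minimum.
#'
#' @param x `ak_segment`, [ak_trace()] or numeric sample vector.
#' @param levels Named numeric vector of level means (pA), e.g.
#'   `c(M = -199.3, M2 = -221)`; at least two for transition analysis.
#' @param min_dwell_ms Minimum reportable event duration (default 0.1 ms).
#' @param dt_ms Sampling interval (taken from `x` when available).
#' @return data.frame of class `ak_events`: `level`, `start_ms`,
#'   `dwell_ms`, `mean_pA`.
#' @export
idealize <- function(x, levels, min_dwell_ms = 0.1, dt_ms = NULL) {
  if (!is.numeric(x)) {
    if (is.null(dt_ms)) dt_ms <- x$dt_ms
    x <- if (!is.null(x$samples)) x$samples else x$current_pA
  }
  if (is.null(dt_ms)) dt_ms <- 0.2
  if (length(levels) < 1L) stop("at least one level definition is required")
  if (anyDuplicated(unname(levels)))
    stop("overlapping level definitions: means must be distinct")
  lv <- sort(levels)
  # band assignment = nearest level (uniform half-amplitude thresholds)
  cuts <- head(lv, -1L) + diff(lv) / 2
  assign_idx <- findInterval(x, cuts) + 1L
  lab <- names(lv)[assign_idx]
  repeat {
    r <- rle(lab)
    short <- which(r$lengths * dt_ms < min_dwell_ms - 1e-12)
    if (length(short) == 0L || length(r$lengths) == 1L) break
    # merge each short run into its predecessor (first run merges forward)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    j <- short[1L]
    donor <- if (j == 1L) r$values[2L] else r$values[j - 1L]
    lab[starts[j]:ends[j]] <- donor
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(
    level = r$values,
    start_ms = (starts - 1L) * dt_ms,
    dwell_ms = r$lengths * dt_ms,
    mean_pA = vapply(seq_along(starts),
                     function(i) mean(x[starts[i]:ends[i]]), numeric(1)),
    stringsAsFactors = FALSE)
  class(out) <- c("ak_events", "data.frame")
  out
}

#' Exponential dwell-time fit
#'
#' `histogram` mode bins the dwell times (bin width close to the expected
#' dwell, i.e. the sample mean, unless given) and least-squares fits a
#' single exponential `A * exp(-t / tau)` to the counts; `direct` mode uses
#' the maximum-likelihood estimate for exponential data, the sample mean.
#'
#' @param dwells_ms Numeric vector of dwell times (ms).
#' @param mode `"histogram"` or `"direct"`.
#' @param bin_width Histogram bin width (ms); default = mean dwell.
#' @return List of class `ak_dwell`: `tau_ms`, `rate_s` (= 1000/tau),
#'   `mode`, `n`.
#' @export
dwell_exponential_fit <- function(dwells_ms, mode = c("histogram", "direct"),
                                  bin_width = NULL) {
  mode <- match.arg(mode)
  dwells_ms <- dwells_ms[is.finite(dwells_ms) & dwells_ms > 0]
  n <- length(dwells_ms)
  if (mode == "direct") {
    if (n < 1L) stop("no usable dwell times")
    tau <- mean(dwells_ms)
  } else {
    if (n < 10L) stop("histogram mode requires at least 10 dwells")
    if (is.null(bin_width)) bin_width <- mean(dwells_ms)
    edges <- seq(0, max(dwells_ms) + bin_width, by = bin_width)
    counts <- tabulate(findInterval(dwells_ms, edges,
                                    rightmost.closed = TRUE),
                       nbins = length(edges) - 1L)
    mids <- head(edges, -1L) + bin_width / 2
    keep <- seq_len(max(which(counts > 0)))
    fit <- minpack.lm::nlsLM(
      counts ~ A * exp(-mids / tau),
      data = data.frame(counts = counts[keep], mids = mids[keep]),
      start = list(A = max(counts), tau = mean(dwells_ms)),
      lower = c(0, 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    tau <- coef(fit)[["tau"]]
  }
  structure(list(tau_ms = tau, rate_s = 1000 / tau, mode = mode, n = n),
            class = "ak_dwell")
}

#' Count ordered level-to-level transitions
#'
#' Tabulates the six ordered transitions among the observable levels
#' (default M, M2, M3) from consecutive events, and the per-origin
#' percentages (each origin's outgoing counts normalized to 100).
#'
#' @param events [idealize()] result (or data.frame with a `level` column).
#' @param levels Levels to include.
#' @return List of class `ak_transitions`: `counts` (from x to matrix) and
#'   `percent` (row-normalized, `NaN` rows when an origin has no outgoing
#'   transition).
#' @export
count_transitions <- function(events, levels = c("M", "M2", "M3")) {
  if (nrow(events) < 2L) {
    z <- matrix(0L, length(levels), length(levels),
                dimnames = list(from = levels, to = levels))
    return(structure(list(counts = z, percent = z * NaN),
                     class = "ak_transitions"))
  }
  seq_lv <- events$level[events$level %in% levels]
  counts <- matrix(0L, length(levels), length(levels),
                   dimnames = list(from = levels, to = levels))
  if (length(seq_lv) >= 2L) {
    from <- seq_lv[-length(seq_lv)]
    to <- seq_lv[-1L]
    keep <- from != to
    for (i in which(keep)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1L
  }
  rs <- rowSums(counts)
  percent <- sweep(counts, 1, rs, "/") * 100
  structure(list(counts = counts, percent = percent),
            class = "ak_transitions")
}
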