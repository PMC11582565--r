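#' Write a current trace to disk
#'
#' Two-column tab-delimited text (`time_ms`, `current_pA`, full double
#' precision) plus a JSON sidecar (`<path>.json`) holding the sampling
#' interval, ligand concentrations (mM), Mg flag, variant hint and
#' provenance label. Byte output is deterministic for identical inputs.
#'
#' @param trace [ak_trace()] (non-empty).
#' @param path Output path for the sample table.
#' @param variant_hint Optional variant id recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, variant_hint = NULL) {
  if (!inherits(trace, "ak_trace")) stop("'trace' must be an ak_trace")
  if (length(trace$current_pA) < 1L) stop("refusing to write an empty trace")
  t_ms <- seq_along(trace$current_pA) * trace$dt_ms
  lines <- c("time_ms\tcurrent_pA",
             sprintf("%.17g\t%.17g", t_ms, trace$current_pA))
  writeLines(lines, path)
  meta <- list(sampling_interval_ms = trace$dt_ms,
               concentrations_mM = list(atp = trace$conc$atp_mM,
                                        amp = trace$conc$amp_mM,
                                        adp = trace$conc$adp_mM),
               mg_present = trace$conc$mg,
               label = trace$label)
  if (!is.null(variant_hint)) meta$variant_hint <- variant_hint
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a current trace from disk
#'
#' Counterpart of [write_trace()]: loads the sample table and its JSON
#' sidecar, validates required metadata and the constant sampling interval.
#'
#' @param path Path written by [write_trace()].
#' @return [ak_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such trace file: ", path)
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stop("missing metadata sidecar: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in c("sampling_interval_ms", "concentrations_mM"))
    if (is.null(meta[[f]]))
      stop("trace metadata is missing required field '", f, "'")
  for (f in c("atp", "amp", "adp"))
    if (is.null(meta$concentrations_mM[[f]]))
      stop("trace metadata is missing required field 'concentrations_mM$",
           f, "'")
  tab <- utils::read.delim(path, header = TRUE)
  if (!all(c("time_ms", "current_pA") %in% names(tab)))
    stop("malformed trace file: expected columns time_ms, current_pA")
  if (nrow(tab) >= 2L) {
    dts <- diff(tab$time_ms)
    if (max(abs(dts - meta$sampling_interval_ms)) > 1e-6)
      stop("inconsistent sampling interval in ", path)
  }
  ak_trace(tab$current_pA, dt_ms = meta$sampling_interval_ms,
           conc = ligand_conc(atp_mM = meta$concentrations_mM$atp,
                              amp_mM = meta$concentrations_mM$amp,
                              adp_mM = meta$concentrations_mM$adp,
                              mg = !isFALSE(meta$mg_present)),
           label = if (is.null(meta$label)) basename(path) else meta$label)
}

# polynomial rolling hash of a deparsed object; stable fingerprint for
# configs (not cryptographic)
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the simulate -> select -> fit -> predict pipeline
#'
#' End-to-end driver: simulates an experiment from reference (or supplied)
#' rates, screens the traces for usable segments, picks one random segment
#' per condition (right-truncated), fits the requested variants, and
#' predicts aggregate LID rates from the best fit. All stage outputs are
#' written under `out_dir` as JSON/TSV artifacts stamped with the master
#' seed and a config hash; reruns with the same config are reproducible.
#'
#' @param config List with elements `seed` (integer), `variants`
#'   (character), `design` ([experiment_design()] or `NULL` for default),
#'   `rates` (generating truth; `NULL` for [rate_vector()] defaults),
#'   `fit` ([fit_config()] or `NULL`), `max_len_ms` (segment cap),
#'   `aggregate_conc` (list for [ligand_conc()] or `NULL`).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the comparison, aggregate rates and
#'   artifact paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(is.list(config))
  seed <- config$seed
  if (is.null(seed)) stop("config$seed is required")
  variants <- config$variants
  if (is.null(variants)) variants <- "V3"
  bad <- setdiff(variants, .AK_VARIANTS)
  if (length(bad))
    stop("configuration error: unknown variant(s) ", paste(bad, collapse = ", "))
  design <- if (is.null(config$design)) experiment_design() else config$design
  rates <- if (is.null(config$rates)) rate_vector() else config$rates
  fitcfg <- if (is.null(config$fit)) fit_config(seed = seed) else config$fit
  max_len <- if (is.null(config$max_len_ms)) 1000 else config$max_len_ms
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config)
  stamp <- list(seed = seed, config_hash = hash)

  message("[simulate] ", nrow(design$conditions), " condition(s)")
  traces <- simulate_experiment(rates, variants[[length(variants)]],
                                design, seed = seed)

  message("[prep] segment selection and per-condition picks")
  cond_key <- vapply(traces, function(tr)
    paste(tr$conc$atp_mM, tr$conc$amp_mM, tr$conc$adp_mM, sep = "/"),
    character(1))
  segs_by_cond <- lapply(split(traces, cond_key), function(trs)
    do.call(c, lapply(trs, select_segments)))
  picked <- pick_fit_segments(segs_by_cond, max_len_ms = max_len,
                              seed = seed + 1L)
  fit_traces <- lapply(names(picked), function(k) {
    s <- picked[[k]]
    ak_trace(s$samples, dt_ms = s$dt_ms, conc = s$conc, label = s$label)
  })

  message("[fit] variants: ", paste(variants, collapse = ", "))
  comparison <- compare_variants(fit_traces, variants, config = fitcfg,
                                 em = design$em)
  best <- comparison$fits[[comparison$table$variant[1L]]]

  agg_conc <- if (is.null(config$aggregate_conc)) list(atp_mM = 1)
              else config$aggregate_conc
  agg <- predict_aggregate_rates(best$rates, best$model,
                                 conc = do.call(ligand_conc, agg_conc),
                                 seed = seed + 2L)

  cmp_path <- file.path(out_dir, "model_comparison.json")
  jsonlite::write_json(c(stamp, list(
    table = comparison$table,
    best_variant = comparison$table$variant[1L],
    best_rates_per_s = as.list(best$rates),
    aggregate_rates = unclass(agg))),
    cmp_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(comparison = comparison, aggregate = agg,
                 artifacts = cmp_path, seed = seed, config_hash = hash))
}
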