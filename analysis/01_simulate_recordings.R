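#!/usr/bin/env Rscript
# Simulate a synthetic nanopore experiment on adenylate kinase: current
# traces at the six ATP/AMP conditions (plus open-pore/shallow artifacts in
# one trace) from the reference endosteric parameterization, written as
# plain-text traces under results/traces/.

suppressPackageStartupMessages(library(akinetics))
seed <- 20260924L
out_dir <- "results/traces"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

rates <- rate_vector()
design <- experiment_design()  # six ATP/AMP pairs, 3 x 2000 ms each
traces <- simulate_experiment(rates, "V3", design, seed = seed)
message(sprintf("simulated %d traces (%.0f s of recording at %g ms)",
                length(traces),
                sum(vapply(traces, trace_duration_ms, 1)) / 1000,
                design$dt_ms))

# salt one trace with the artifacts that segment selection must remove
art <- data.frame(type = c("open_pore", "shallow"),
                  at_ms = c(400, 1200), duration_ms = c(150, 100))
traces[[1]] <- inject_artifacts(traces[[1]], art, seed = seed + 1L)

for (tr in traces)
  write_trace(tr, file.path(out_dir, paste0(tr$label, ".tsv")),
              variant_hint = "V3")
write_rates_json(rates, "V3", file.path("results", "generating_rates.json"))
message("wrote ", length(traces), " trace files under ", out_dir)
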