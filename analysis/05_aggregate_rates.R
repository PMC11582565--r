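#!/usr/bin/env Rscript
# Aggregate domain-motion rates predicted from the fitted model: simulate a
# 20,000 ms sample path per condition and report the inverse mean dwell in
# the LID-open (closing rate) and LID-closed (opening rate) state groups,
# plus the NMP analogues.

suppressPackageStartupMessages(library(akinetics))
seed <- 626L
fitted <- read_rates_json("results/fitted_rates.json")
message("using fitted ", fitted$variant_id, " rates")

conds <- data.frame(atp_mM = c(0.01, 0.1, 1, 1, 1, 1),
                    amp_mM = c(0, 0, 0, 0.01, 0.1, 1))
rows <- lapply(seq_len(nrow(conds)), function(i) {
  agg <- predict_aggregate_rates(
    fitted$rates, fitted$variant_id,
    conc = ligand_conc(atp_mM = conds$atp_mM[i], amp_mM = conds$amp_mM[i]),
    duration_ms = 20000, seed = seed + i)
  data.frame(atp_mM = conds$atp_mM[i], amp_mM = conds$amp_mM[i],
             lid_closing_s = agg$lid_closing_s,
             lid_opening_s = agg$lid_opening_s,
             nmp_closing_s = agg$nmp_closing_s,
             nmp_opening_s = agg$nmp_opening_s,
             n_open_dwells = agg$n_dwells_lid_open)
})
tab <- do.call(rbind, rows)
print(round(tab, 2))
write.table(format(tab, digits = 6), "results/aggregate_rates.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("LID closing at 1 mM ATP: ",
        round(tab$lid_closing_s[tab$atp_mM == 1 & tab$amp_mM == 0]),
        " s^-1; NMP closing at 1/1 mM: ",
        round(tab$nmp_closing_s[tab$atp_mM == 1 & tab$amp_mM == 1]),
        " s^-1")
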