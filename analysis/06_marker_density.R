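#!/usr/bin/env Rscript
# Predictive ability as a function of marker density (random subsets,
# five-fold CV, RR-BLUP). Block LD makes the curve plateau well before the
# full marker set.

source("analysis/helpers.R")

G <- get_clean_geno()
blups <- get_blups()
p <- ncol(G$values)
counts <- c(250, 500, 1000, 2500, p)
rows <- list()
for (tr in names(blups)) {
  cur <- marker_density_curve("RRBLUP", G, blups[[tr]], counts = counts,
                              reps = 10, seed = panel_seed + 6)
  for (ct in names(cur)) {
    rows[[paste(tr, ct)]] <- data.frame(
      trait = tr, n_markers = as.integer(ct),
      mean_ability = cur[[ct]]$mean_ability,
      ci_lo = cur[[ct]]$ci95[1], ci_hi = cur[[ct]]$ci95[2])
  }
  plateau_gap <- cur[[as.character(p)]]$mean_ability -
    cur[["1000"]]$mean_ability
  say("%-15s ability %.3f @1000 vs %.3f @%d markers (gap %.3f)", tr,
      cur[["1000"]]$mean_ability, cur[[as.character(p)]]$mean_ability, p,
      plateau_gap)
}
tab <- do.call(rbind, rows)
write.table(tab, file.path(res_dir, "06_marker_density.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
gap2500 <- tapply(tab$mean_ability, tab$trait, function(a) a[5] - a[4])
say("remaining gain from 2500 to all %d markers: %s", p,
    paste(names(gap2500), sprintf("%.3f", gap2500), collapse = ", "))
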