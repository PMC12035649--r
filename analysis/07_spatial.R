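#!/usr/bin/env Rscript
# Tumour-neighbourhood analysis on the simulated slide: sum each cell
# type's deconvolution weights over the eight spots adjacent to every
# tumour spot, then correlate MP scores with those neighbourhood scores.
# Run from the repository root after 01_simulate.R.
source("analysis/00_config.R")

grid <- read_spot_grid(file.path(RESULTS, "spot_grid.tsv"))

nb <- neighbourhood_score_table(grid)
write.table(data.frame(spot_id = rownames(nb), nb),
            file.path(RESULTS, "neighbourhood_scores.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

res <- mp_tme_correlation(grid)
write.table(data.frame(mp = rownames(res$pooled), res$pooled),
            file.path(RESULTS, "mp_tme_correlation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("pooled over %d tumour spots:\n", res$n_spots))
print(round(res$pooled, 3))
r <- res$pooled["MP_planted", "fibroblast"]
t <- r * sqrt((res$n_spots - 2) / (1 - r^2))
cat(sprintf("planted pair (MP_planted, fibroblast): r = %.3f, p = %.2g\n",
            r, 2 * pt(-abs(t), res$n_spots - 2)))
cat(sprintf("null pair (MP_null, T_cell): r = %.3f\n",
            res$pooled["MP_null", "T_cell"]))
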