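#!/usr/bin/env Rscript
# Stage 4: cross-modal coupling and the multimodal feature set.
#
# Each significant structural edge is correlated (over its present
# subjects) with the mean functional connectivity of both endpoints; the
# edge survives when either side is significant at p < 0.05 (uncorrected by
# design -- the edge set was already family-wise screened). Features: one
# fiber-density column per retained edge, one mean-FC column per distinct
# significantly-coupled region.

library(bmiconn)

data <- read_cohort("scratch/cohort")
nets <- readRDS("scratch/networks.rds")
et <- readRDS("scratch/edge_tests.rds")

coupling <- couple_edges(et$sig, et$samples, nets$mean_fc, data$atlas,
                         alpha = 0.05)
cat(sprintf("%d of %d significant edges retained after coupling\n",
            sum(coupling$retained), nrow(coupling)))
write.table(format(coupling[, c("name_u", "name_v", "r1", "p1", "r2", "p2",
                                "retained")], digits = 4),
            "results/04_coupling.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

fset <- assemble_features(coupling, et$samples, nets$mean_fc, data$atlas,
                          alpha = 0.05)
print(fset)
write_matrix_csv(fset$X, "results/04_features.csv")
saveRDS(fset, "scratch/features.rds")
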