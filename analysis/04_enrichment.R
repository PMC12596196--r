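#!/usr/bin/env Rscript
# Stage 4: TRN enrichment and expansion.
#
# Scores every iModulon against every regulator of the known TRN (one-sided
# Fisher test, joint BH adjustment), classifies each into the four recall
# quadrants at the 0.7 cut, and counts the regulator-target associations
# the regulatory iModulons imply beyond the known network.

library(rmodulon)

run_pipeline("results/config.yaml", stages = "enrich")

enr <- read.delim("results/run/enrichment.tsv")
expansion <- jsonlite::read_json("results/run/trn_expansion.json")

cat(sprintf("regulatory iModulons (FDR < 1e-4): %d of %d\n",
            sum(enr$is_regulatory), nrow(enr)))
cat("quadrant counts:\n")
print(table(enr$quadrant[enr$is_regulatory]))
cat(sprintf("TRN expansion: %d associations from regulatory iModulons, %d novel (%.1f%% of the known TRN)\n",
            expansion$total_associations, expansion$novel_associations,
            100 * expansion$expansion_fraction))
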