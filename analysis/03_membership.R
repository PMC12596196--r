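#!/usr/bin/env Rscript
# Stage 3: gene membership.
#
# Optimizes the D'Agostino K-squared cutoff against the known TRN (the
# workflow's optimize-cutoff behaviour), peels each component's heavy tail
# into its iModulon member set, and writes imodulons.json.

library(rmodulon)

run_pipeline("results/config.yaml", stages = "threshold")

dec <- read_decomposition("results/run")
imods <- read_imodulons_json("results/run/imodulons.json", dec)
man <- jsonlite::read_json("results/run/membership_manifest.json")

sizes <- lengths(lapply(imods, `[[`, "members"))
cat(sprintf("K-squared cutoff used: %s\n", man$k2_cutoff))
cat(sprintf("iModulon sizes: median %d genes (range %d-%d); %d of %d flagged degenerate\n",
            as.integer(median(sizes)), min(sizes), max(sizes),
            sum(vapply(imods, `[[`, TRUE, "degenerate")), length(imods)))
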