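#!/usr/bin/env Rscript
# Stage 5: activity analysis.
#
# Ward-clusters the rows of the activity matrix (modules with similar
# condition profiles form stimulon-like groups), tests one module for
# differential activity between its active conditions and the reference,
# and checks that a member gene's expression tracks its module's activity.

library(rmodulon)

run_pipeline("results/config.yaml", stages = "activities")

dec <- read_decomposition("results/run")
xc <- read_expression("results/run/X_centered.tsv", is_centered = TRUE)
imods <- read_imodulons_json("results/run/imodulons.json", dec)
meta <- read_sample_metadata("results/data/metadata.csv")
labels <- read.delim("results/run/activity_clusters.tsv")
cat(sprintf("activity rows cut into %d Ward clusters (sizes: %s)\n",
            length(unique(labels$cluster)),
            paste(sort(table(labels$cluster), decreasing = TRUE), collapse = ", ")))

# differential activity of the strongest component between its most active
# condition and the reference conditions of the same project
act <- dec$A[1, ]
top_cond <- names(sort(tapply(act, meta$condition[match(names(act), meta$sample_id)],
                              mean), decreasing = TRUE))[1]
grp_a <- meta$sample_id[meta$condition == top_cond]
grp_b <- meta$sample_id[meta$is_reference &
                          meta$project_id == meta$project_id[meta$condition == top_cond][1]]
da <- differential_activity(act, grp_a, grp_b)
cat(sprintf("%s in '%s' vs reference: delta = %.2f, Welch p = %.2g\n",
            rownames(dec$A)[1], top_cond, da$delta, da$p_value))

# a member gene's expression should track its module's activity
gene <- imods[[1]]$members[1]
r <- activity_expression_correlation(act, xc, gene)
cat(sprintf("correlation of %s activity with member gene %s expression: r = %.2f\n",
            rownames(dec$A)[1], gene, r))

diff_tab <- differential_activity_all(dec$A, grp_a, grp_b)
write.table(diff_tab, file.path("results", "differential_activity.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("differential-activity table for all %d components written to results/differential_activity.tsv\n",
            nrow(diff_tab)))
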