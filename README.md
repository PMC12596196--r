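# rmodulon

Robust independent component analysis of bacterial RNA-seq compendia.

Bulk transcriptomes are shaped by a limited set of transcriptional
regulators, each switching a sparse set of target genes together.
`rmodulon` recovers these *independently modulated gene sets* (iModulons)
from a genes x samples log-TPM compendium by decomposing it as

    X = M A

where columns of `M` (genes x K) are sparse, heavy-tailed gene-weight
vectors — one per module — and rows of `A` (K x samples) are the modules'
condition-dependent activities. Because FastICA is non-convex, the
decomposition is made *robust*: an ensemble of randomized restarts is
consensus-clustered with DBSCAN under the distance `d = 1 − |ρ|` (absolute
Pearson correlation between gene-weight vectors), and only components that
recur across runs survive. Member genes are then split from background by
iterative D'Agostino K² outlier thresholding, member sets are scored
against a curated transcriptional regulatory network (TRN) with one-sided
Fisher's exact tests under Benjamini–Hochberg FDR, and activities are
clustered and compared across conditions. The package is aimed at
microbial systems biologists who have a processed expression compendium
and a partial TRN, and want a reproducible module-level map of it.

A first-class synthetic-compendium generator (planted sparse modules,
condition-block activities, per-project reference conditions, and a
planted TRN with exact/subset/superset/unrelated regulon classes) makes
every stage testable end to end with no external data.

## Worked example

The `analysis/` directory is a numbered workflow over the package; running
its five scripts in order simulates a compendium, decomposes it, assigns
membership, scores the TRN, and analyzes activities:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_decompose.R
Rscript analysis/03_membership.R
Rscript analysis/04_enrichment.R
Rscript analysis/05_activities.R
```

Output from a complete run (2000 genes x 160 samples, 12 planted modules
at SNR 20, 20-restart ensemble at dimension 12):

```
wrote 2000-gene x 160-sample synthetic compendium (12 modules) to results/data
planted TRN: 310 associations over 12 regulators (classes: exact, subset, superset, unrelated)
robust components: K = 12 (cluster support 20-20)
explained variance: 90.5% of the centered compendium
planted-module recovery: 100% matched at |rho| >= 0.8 (median |rho| = 0.983)
K-squared cutoff used: 100
iModulon sizes: median 26 genes (range 11-40); 0 of 12 flagged degenerate
regulatory iModulons (FDR < 1e-4): 9 of 12
quadrant counts:
    regulon subset unknown-containing       well-matched
                 3                  3                  3
TRN expansion: 219 associations from regulatory iModulons, 49 novel (15.8% of the known TRN)
activity rows cut into 4 Ward clusters (sizes: 9, 1, 1, 1)
IC01 in 'cond20' vs reference: delta = 29.12, Welch p = 2e-08
correlation of IC01 activity with member gene g0871 expression: r = 1.00
```

Reading the numbers: all 12 planted modules were recovered as robust
components (every one supported by all 20 restarts) and together they
explain 90.5% of the centered compendium's variance — the rest is the
planted measurement noise. Membership thresholding recovers the planted
member sets exactly (the optimized K² cutoff maximizes F1 against the known
regulons). Of the 12 components, the 9 whose planted regulons overlap their
members are flagged regulatory and fall, three apiece, into the three
designed recall quadrants; the 49 novel regulator–target pairs are exactly
the member genes the superset-class regulons omit, a 15.8% expansion of the
planted TRN. The activity dendrogram groups the nine co-designed modules,
and the strongest module is sharply differentially active in its planted
condition block while its members' expression tracks its activity (r = 1.00).

Equivalent results come from the single entry point
`run_pipeline("results/config.yaml")`, which runs the same four stages
(decompose, threshold, enrich, activities) off one YAML config and writes
`M.tsv`, `A.tsv`, `imodulons.json`, `enrichment.tsv`, the activity tree,
and a manifest recording seeds, parameters, and input checksums. Stages
re-run separately on saved intermediates reproduce the single-call outputs
byte for byte.

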