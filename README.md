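# netmet

Predicting cancer recurrence from whole-exome sequencing by propagating
founding-clone mutations over a signaling network.

## The problem

Tumors with the same clinical outcome rarely share mutated genes, so
mutation tables are too sparse to train a classifier on directly. `netmet`
implements a network-based alternative for ER+ breast cancer-style
cohorts: the functional mutations of each tumor's *founding clone* (the
mutations present in every cancer cell, identified from tumor/normal
variant allele frequencies) are treated as heat sources on a
recurrence-specific signaling network. A random walk with restart,

    F = (1 - r) F0 + r W F,

with `W` the column-degree-normalized adjacency and uniform seed mass
`F0`, diffuses each sample's mutations into a "heating score" profile
(netProfile); z-scored profiles form the netMatrix. A modified Multiple
Survival Screening (MSS) then discovers 30-gene **network operational gene
(NOG) signatures** per cancer hallmark: random 30-gene sets from
hallmark-restricted pools are retained when fuzzy 2-means clustering of
their mean heating score separates disease-free survival (log-rank
P < 0.05) on more than 80% of 200 random sample subsets, and gene
frequency across retained sets ranks the signature. Each signature's
per-class mean heating profiles define a "recurring" and a "non-recurring"
cellular state; new samples are classified by correlating their profile
with the two state centroids (nearest shrunken centroids), and a
combinatory signature set (NOG_CSS) votes the final low/high/unclassified
risk call under LN/HN cutoffs. The 21-gene Oncotype DX recurrence score is
included as the standard comparator.

Because the original inputs are controlled-access consortium data, the
package ships a synthetic-data generator with planted network modules,
two-state survival and matching expression/copy-number evidence, so the
whole pipeline is testable end to end.

## Worked example

```r
library(netmet)

# a fully synthetic study: 200 samples, 2000-gene network,
# two planted 30-gene modules
ds      <- simulate_dataset(sim_config(), seed = 101)
genes   <- merge_functional_genes(ds$cohort$annotations)
clones  <- build_founding_clones(ds$cohort$mutations, genes)
nm      <- build_netmatrix(propagate_cohort(ds$network$edges, clones))

disc <- discover_signatures(nm, ds$cohort$clinical,
                            ds$evidence$hallmarks, seed = 1)
length(disc$signatures)
#> [1] 3
disc$signatures[[1]]
#> NOG signature 'apoptosis': 30 genes from 10000 retained sets
#>   top genes: g1570, g0378, g0284, g1132, g1419, g0621, g0423, g1304 ...

css <- select_n_signatures(unname(disc$signatures), nm, ds$cohort$clinical)
css
#> NOG_CSS: 2 signature(s), LN = 2, HN = 1

res <- loocv(css, nm, ds$cohort$clinical)
res$evaluation$low
#> $precision 0.977   $recall 0.744   $n_predicted 128
```

Read: of the 128 samples the leave-one-out classifier calls low risk,
97.7% are recurrence-free (precision), and those calls cover 74.4% of all
recurrence-free samples (recall) — the clinically relevant direction,
since confidently-low-risk patients are candidates to be spared adjuvant
chemotherapy. The three emitted signatures (the recurrence-module
hallmarks; the protective module's pools fall below the 30-gene set size
at this event rate) recover their planted module at 87–90% in this run,
and label-permuted runs emit no signature at all.

A thin command line covers the same steps
(`Rscript inst/cli/netmet.R simulate --seed 9 --out fixtures/`, then
`filter-variants`, `propagate`, `discover-signatures`, `predict`, or `run`
with a YAML config; see `?netmet_cli`).

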