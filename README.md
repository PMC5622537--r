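# ndprio

Network-diffusion prioritization of disease genes and detection of
significantly connected gene modules.

## The problem

Large genetic studies of a heterogeneous disease rarely agree on a gene
list: screens for de novo variants, rare copy-number variants and curated
evidence databases each nominate largely non-overlapping genes. When the
products of those genes interact, the disagreement at the gene level can
hide agreement at the network level — the variation clusters in a
*disease module*, a connected region of the gene interaction network.
`ndprio` is for analysts who have one or more weighted disease-gene lists
and a confidence-scored gene network (STRING-like edge list) and want to

1. score **every** gene for network proximity to the input lists,
2. test whether the top-ranked genes form a significantly connected
   module, and extract it, and
3. characterize the results with pathway over-representation and
   overlap statistics.

## The method

Input lists are encoded as a seed vector `X0` (a gene's value is the
largest weight over the lists containing it) and diffused over the
symmetrically normalized adjacency matrix
`W[i,j] = A[i,j] / sqrt(d_i d_j)`:

```
X_{t+1} = alpha W X_t + (1 - alpha) X0,     X* = lim X_t
```

with retention parameter `alpha = 0.7`. Each gene `g` is scored with the
network smoothing index and its permutation-adjusted form

```
S(g)  = X*(g) / (X0(g) + eps)
Sp(g) = -log10(pS(g)) * S(g),   pS(g) = (1 + #{S^k(g) >= S(g)}) / (K + 1)
```

where the null scores `S^k` come from `K = 999` random reassignments of
the seed values over all node labels — hub genes that collect diffused
mass under any seeding are down-weighted. The regularizer `eps` is either
fixed or calibrated so that input and predicted genes appear 1:1 among
the top `2n` ranks.

Whether the top-`m` genes form a significantly connected module is
tested by network resampling: the objective `Omega(m) = Sp' A_m Sp` on
their induced subnetwork is compared with `q = 200` degree-preserving
edge rewirings, giving an empirical `p_NR(m)` along the ranking;
`extract_module()` maps the `p_NR` profile to a module cutoff. Pathway
characterization uses exact hypergeometric over-representation with
Benjamini–Hochberg correction (gene sets of 10–200 genes) and
overlap-coefficient enrichment maps.

A synthetic generator (`generate_scenario()`) produces heavy-tailed
networks with a planted connected module, noisy low-overlap seed lists
and partially enriched pathway sets, so the whole pipeline is testable
against a known ground truth.

## Worked example

```r
library(ndprio)

sc  <- synthetic_scenario(n_nodes = 500L, module_size = 40L,
                          module_density = 0.25, n_lists = 3L, rng_seed = 7L)
sim <- generate_scenario(sc)
sim$network
#> gene_network: 500 nodes, 1330 edges (score >= 700, binary adjacency)
#>   degree: median 3, max 91; isolated nodes: 0

run <- run_joint(sim$network, sim$lists,
                 config = pipeline_config(K = 199L, q = 99L, rng_seed = 1L))
run$scores
#> smoothing_result: 500 genes, 29 input; alpha = 0.7, epsilon = 1, K = 199, seed = 1
#>   genes with pS <= 0.05: 41
#>      gene         S    pS        Sp rank is_input
#> 1 G000121 0.3165899 0.005 0.7284828    1     TRUE
#> 2 G000463 0.3114824 0.005 0.7167304    2    FALSE
#> ...
run$module
#> gene_module: 46 genes (m* = 46), 202 induced edges, 3 component(s)
#>   (predicted): 17
#>   list01: 7
#>   ...
```

The 29 input genes (union of three noisy lists) pull in 17 predicted
genes; the extracted 46-gene module recovers the planted 40-gene module
with precision 0.85 and recall 0.97. Rank 2 (`G000463`) is a predicted
gene: it was in no input list but sits at the minimal permutation
p-value, i.e. in exceptional network proximity to the seeds. ORA on the
module then ranks the module-enriched pathway sets first:

```r
head(as.data.frame(ora(run$module$genes, sim$pathways, sim$network$nodes)), 2)
#>   pathway size overlap            p        p_adj
#> 1  PW0002   83      41 2.856536e-31 1.713922e-29
#> 2  PW0005   81      39 2.886892e-28 8.660676e-27
```

Real data enter the same way through `load_edge_list()` (three-column
TSV with confidence scores, threshold 700 by default, optional ID
mapping), `read_gene_list()` and `read_gmt()`.

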