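# agnet — prioritizing biological processes in associative gene networks

`agnet` is an R toolkit for network-based prioritization of Gene Ontology
biological processes. Starting from a typed knowledge graph — a heterogeneous
graph whose vertices are molecular entities (genes, proteins, metabolites,
microRNAs) and higher-level factors (biological processes, traits, diseases),
with relation-labelled, provenance-tagged edges — it:

1. **reconstructs** the associative gene network of a seed biological
   process: the gene/protein vertices directly linked to the seed (the `M`
   members) and the knowledge-graph edges running among them;
2. **prioritizes** every candidate process by its *cross-talk centrality*

   ```
   CTC_i = N_i / M
   ```

   where `N_i` is the number of distinct network members adjacent to
   candidate `i` (its degree centrality restricted to the network). CTC
   ranges from 0 (the candidate touches no member) to 1 (linked to all of
   them). Significance is an upper-tail hypergeometric over-representation
   test — `P(X >= N_i)` for `X ~ Hypergeom(N_U, K, M)` with `K` the
   candidate's annotated genes in the whole graph and `N_U` the annotated
   universe — corrected by the Benjamini–Yekutieli FDR procedure, which is
   valid under the arbitrary dependence that shared network genes induce;
3. **clusters** the significant processes by semantic proximity: Wang
   graph-based similarity over the ontology (weighted ancestor
   contributions, `w_is_a = 0.8`, `w_part_of = 0.6`) fed to the Markov
   Cluster algorithm (expansion/inflation on the column-stochastic
   similarity matrix);
4. **compares** significant-process sets across several seed networks,
   reporting the common core and the condition-specific remainders.

Because the knowledge bases such pipelines run on are typically proprietary,
the package ships a synthetic fixture generator (`fixture_spec()`,
`make_knowledge_graph()`, `make_ontology()`, `make_comparison_fixture()`)
that plants known high-CTC processes and known common/specific structure, so
every stage is testable offline with a known ground truth.

## Worked example

```r
library(agnet)

spec <- fixture_spec(n_genes = 100, n_processes = 32,
                     planted_ctc = c("GO:0000003" = 0.8), rng_seed = 7)
kg <- make_knowledge_graph(spec)
kg
#> Knowledge graph: 332 vertices, 699 edges
#>   kinds: gene=300, process=32

seed_id <- fixture_process_ids(spec)[1]   # "GO:0000002"
net <- reconstruct(kg, seed_id)
net
#> Associative gene network for seed process GO:0000002
#>   M = 89 member vertices, 81 internal edges

scores <- prioritize(kg, net,
                     candidates = setdiff(fixture_process_ids(spec), seed_id))
head(scores, 3)
#>   process_id process_name Ni  M        ctc      p_value      q_value rank
#> 1 GO:0000003   GO:0000003 71 89 0.79775281 1.243231e-45 1.552107e-43    1
#> 2 GO:0000009   GO:0000009  8 89 0.08988764 1.679039e-01 1.000000e+00    2
#> 3 GO:0000012   GO:0000012  8 89 0.08988764 1.679039e-01 1.000000e+00    3
```

The process planted at a link fraction of 0.8 comes out with `CTC = 71/89 ≈
0.80` at rank 1, and its q-value (~1.6e-43) says 71 links is far more than a
random process with 71 annotated genes would achieve against an 89-member
network drawn from a 300-gene annotated universe; the 30 decoy processes
(5 % background link rate) stay around CTC ≈ 0.08 with q = 1. Clustering the
significant set and comparing several seed networks continue from here:

```r
sig <- significant(scores, alpha = 0.05)
sim <- similarity_matrix(make_ontology(spec), sig$process_id)
mcl_cluster(sim)
#> MCL clustering: 1 processes in 1 clusters ( converged after 1 iterations )
```

The same pipeline is scriptable from a shell via `inst/cli/agnet.R`
(subcommands `simulate`, `reconstruct`, `prioritize`, `cluster`, `compare`;
see `Rscript inst/cli/agnet.R` for usage).

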