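---
title: "Methods: NOD-based prioritization of miRNA biomarkers in bipartite regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NOD-based prioritization of miRNA biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pomanet)
```

## The problem

Patients with locally advanced colorectal cancer receive preoperative
(neoadjuvant) chemoradiotherapy, but only a fraction respond. miRNAs are
attractive predictive biomarkers: they are stable, measurable in tissue,
and each regulates a battery of mRNA targets. `pomanet` implements a
network-based prioritization pipeline (in the field often called POMA, a
pipeline of outlier miRNA analysis): rather than ranking miRNAs by
differential expression alone, it asks which differentially expressed
miRNAs also hold *independent regulatory power* in the bipartite
miRNA–mRNA regulatory network, on the premise that a miRNA whose targets
are regulated by it alone is a frail point of the system whose
deregulation propagates unbuffered.

## The NOD statistic

Let \(G = (M \cup V, E)\) be a directed bipartite graph with miRNA nodes
\(M\), gene nodes \(V\), and edges \(m \to v\) meaning "miRNA \(m\)
targets gene \(v\)". For a gene \(v\), write \(\deg^{-}(v)\) for its
regulatory in-degree. The **NOD** ("novel out-degree") of a miRNA is its
count of exclusively-regulated targets:

\[
\mathrm{NOD}(m) \;=\; \bigl|\{\, v : (m \to v) \in E,\ \deg^{-}(v) = 1 \,\}\bigr|.
\]

Two conservation identities pin the implementation down and are enforced
as tests: \(\sum_m \mathrm{NOD}(m)\) equals the number of genes with
in-degree exactly 1, and \(\sum_m \deg^{+}(m) = |E|\). NOD is computed in
one pass over the gene in-degree distribution (`compute_nod_all()`), and
always against the **full** network: uniqueness is judged among all
regulators, not just the differentially expressed subset, because
literature miRNAs outside any DE set still carry meaningful NOD values.

## Pipeline

1. **Network construction** (`read_edge_list()`, `merge_networks()`).
   Target databases are merged as edge lists with per-edge provenance.
   miRNA names are reconciled by lowercasing, stripping the `hsa-`
   species prefix, and an explicit, auditable alias table
   (`mirna_alias_table()`) mapping reported to official names; we chose
   an explicit table over a heuristic because no rewriting rule recovers
   official arm suffixes (e.g. `miR-196b` → `mir-196b-5p`). Gene symbols
   are uppercased only — full symbol-alias resolution would silently
   change edge counts and is deliberately out of scope.
2. **Differential expression** (`select_de()`). Per miRNA, a classical
   two-sample Student's *t* (pooled variance, two-sided) between
   responders and non-responders, with selection at raw
   \(p < 0.05\) and \(|\log_2 \mathrm{FC}| > 1\) (i.e. fold change > 2).
   Raw-p selection is the screen's convention; Benjamini–Hochberg FDR is
   reported alongside for modern reuse but not used to select. Input is
   assumed log2-scale (normalized arrays); a `scale = "linear"` switch
   computes fold change as a ratio of means instead. A moderated
   (limma-style) *t* is intentionally not offered: the method is defined
   on the classical statistic, and mixing the two changes the DE set.
3. **Mapping and NOD scoring** (`map_de_to_network()`,
   `compute_nod_all()`). Selected DE miRNAs are partitioned by network
   membership; unmapped ones are reported, never silently dropped.
4. **NOD significance and selection** (`nod_null_pvalues()`,
   `run_poma()`). Each mapped miRNA receives a NOD p-value under a null
   model (below); candidates are those with
   \(p_{\mathrm{NOD}} < \alpha\) (default 0.05) and NOD ≥ 1, ordered by
   NOD descending, then p ascending, then ID — a stable, diff-able
   ordering.

## Null models for NOD

The reference analyses in this literature report a significance value per
NOD but do not define the null construction, so `pomanet` ships two
explicit ones:

* **Empirical tail** (default; deterministic). The network-wide NOD
  distribution is itself the null:
  \(p(m) = \bigl(1 + \#\{m' \in M : \mathrm{NOD}(m') \ge
  \mathrm{NOD}(m)\}\bigr) / (1 + |M|)\), the focal miRNA included. This
  reproduces the characteristic monotone NOD→p pattern of published
  candidate tables and needs no simulation, but it is a *rank* test: its
  resolution is bounded below by \(2/(|M|+1)\), and a cohort of \(k\)
  high-NOD miRNAs can never all beat \(\alpha\) when
  \((k+1)/(|M|+1) > \alpha\) — the weakest cohort member carries all the
  others in its tail count.
* **Degree-preserving rewiring** (`rewire_permutation`). Bipartite
  checkerboard swaps \((m_1,g_1),(m_2,g_2) \to (m_1,g_2),(m_2,g_1)\),
  rejected when they would duplicate an edge, leave every miRNA
  out-degree and gene in-degree intact while randomizing who shares
  targets with whom; \(p(m) = (1 + \#\{\mathrm{NOD}^*(m) \ge
  \mathrm{NOD}(m)\}) / (1 + n_{\mathrm{perm}})\). This tests exclusivity
  *beyond what degree alone implies*. The swap kernel is compiled (Rcpp)
  and draws from R's RNG, so runs are reproducible under a seed. Each
  permutation applies \(10 \times |E|\) swap attempts starting from the
  observed graph — a standard mixing heuristic for edge-swap samplers;
  doubling it does not change the p-values beyond Monte-Carlo noise on
  the shipped problem sizes.

Both estimators use +1 smoothing (the permutation-p convention), so no
reported p is exactly 0. Published NOD p-values attached to the packaged
candidate table are consumed as a fixture — their generating network is
not reconstructable from public database snapshots — and are never
claimed to be reproduced numerically.

## The synthetic benchmark

`poma_benchmark()` fixes the validation conditions; they mirror the
two-group design the pipeline is meant for and are not tuning knobs:

| parameter | default | why |
|---|---|---|
| samples | 9 responders vs 29 non-responders | the archetypal unbalanced response-profiling design this screen targets |
| miRNAs × genes | 100 × 1000 | desk-scale network with a realistic 10:1 gene:miRNA ratio |
| background mean degree | 20 | ~2% of the gene universe per miRNA, consistent with per-miRNA target breadths seen in merged target databases |
| planted biomarkers | 5, each with 8 reserved exclusive targets | clear high-NOD signal while staying within the NOD range of real candidate tables |
| decoys | 3 DE-only (NOD forced to 0), 3 high-NOD-only (not DE) | probe each selection axis separately |
| effect, noise | 2.0 log2 shift, σ = 0.5 | a 4-fold biomarker-grade change against typical normalized-array residual spread |

Construction guarantees: reserved genes are never touched by background
edges, so a planted miRNA's NOD is at least its reservation; each
DE-only decoy target that would be unique receives a second regulator,
so those decoys have NOD exactly 0 and are excluded by the NOD ≥ 1 rule
regardless of the null. Expression is i.i.d. Gaussian on the log2 scale
around a per-miRNA baseline drawn from Uniform(4, 12).

The benchmark runs the NOD stage with the **rewiring null**. The choice
is forced by arithmetic, not preference: with \(|M| = 100\) and five
planted biomarkers, the empirical tail gives the weakest of them
\(p \ge 6/101 \approx 0.059 > 0.05\) — a relative-rank test cannot
certify five simultaneous outliers among one hundred. The rewiring null
scores each miRNA against its own degree-conditional expectation and
separates the planted cohort cleanly. A back-of-envelope power check:
with ~2100 edges on 1000 genes, a random target is exclusive with
probability \(q \approx e^{-2.1} \approx 0.13\), so a planted miRNA
(degree ≈ 28) has null mean \(28q \approx 3.5\) against an observed
\(\mathrm{NOD} \ge 8\) — several null SDs away — while a background
miRNA sits at its null mean by construction.

What the generator does **not** emulate: probe- and batch effects,
heavy-tailed or correlated noise, miRNA–target expression coupling, or
database-specific edge biases. Passing the benchmark therefore shows the
selection logic discriminates DE-and-exclusive miRNAs from both decoy
classes under clean Gaussian conditions; it does not certify performance
on raw array data.

## Numerical conventions and edge cases

* Degenerate *t* inputs: both groups constant and equal → p = 1; both
  constant but different → the p = 0 limit, flagged in the
  `qc_degenerate` column rather than thrown.
* Rows with missing values are dropped (complete-case, counted warning);
  duplicate probe IDs collapse to the per-sample mean. No imputation.
* Subnetwork uniqueness is judged against the **parent** network by
  default (the strictest reading of "exclusively regulated", and the one
  wet-lab follow-up of unique targets relies on); a
  `uniqueness = "subnetwork"` flag gives the candidate-local reading.
* Enrichment (`hypergeom_ora()`) is a generic hypergeometric
  over-representation test; the default universe is the union of the
  GMT's genes, overridable — results are only as meaningful as the
  collection and universe supplied, and no attempt is made to mimic any
  specific annotation service's backgrounds.
* Candidate ordering ties break lexicographically by miRNA ID, so
  outputs are byte-stable across runs with the same seed.

## Validation problem sizes

The shipped test suite validates NOD against a brute-force per-gene
oracle on 100 random bipartite graphs (up to 50 miRNAs × 500 genes, edge
probability 0.02–0.2), the pooled *t* against the closed-form textbook
formula at 1e-12 and its type-I error on 1000 null draws, the
hypergeometric tail against exhaustive enumeration on universes of ≤ 12
genes, and end-to-end recovery over 20 benchmark seeds (exact recovery of
all five planted biomarkers with both decoy classes rejected in ≥ 90% of
seeds). `scripts/acceptance.R` recomputes the same headline quantities
from a fresh seed.

## Known limitations

* The packaged catalog network is a *constructed realization* of the
  literature catalog's NOD values (reservation scheme plus shared hubs),
  not the original integrated seven-database network, which is not
  reconstructable without versioned snapshots.
* NOD treats all edges equally; predicted and validated interactions are
  distinguished only in provenance, not weighted.
* The empirical-tail null is informative for single outliers but
  rank-limited for cohorts (see above); users screening many candidates
  at once should prefer the rewiring null.
* GEO series parsing is deliberately minimal (plain TSV matrix + group
  file); no download client is included.
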