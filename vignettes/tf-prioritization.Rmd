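---
title: "Methods: prioritizing IMiD-degraded transcription factors"
author: "imidtf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prioritizing IMiD-degraded transcription factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imidtf)
```

## The problem and the model

Immunomodulatory drugs (IMiDs — thalidomide, lenalidomide, pomalidomide)
bind cereblon (CRBN), redirecting the CRL4-CRBN ubiquitin ligase toward
neosubstrate proteins, with C2H2 zinc-finger transcription factors (TFs)
the class most implicated. Degradation of a TF removes its regulon from
transcriptional control, so drug exposure should leave a detectable
footprint: the TF's targets become differentially expressed across many
independent datasets, even when the TF transcript itself does not move.

`imidtf` formalizes that reasoning as a pipeline of filters and tests:

1. **Per-dataset significance.** A gene is significant in a dataset iff
   $|\log_2 FC| > 1$ and BH-adjusted $p < 0.05$, both strict. The threshold
   is read symmetrically (up- and down-regulation), since degradation of an
   activator depresses its targets while degradation of a repressor
   de-represses them.
2. **Vote counting.** The frequency score $s_g$ is the number of datasets
   in which gene $g$ is significant. Vote counting, rather than effect-size
   meta-analysis, is deliberate: the ingested DE tables come from
   heterogeneous platforms and designs whose fold changes are not directly
   poolable, while "how often does this gene recur" is.
3. **Dual-evidence query.** Keep $s_g \ge 2$, or $s_g = 1$ with
   gene-level literature evidence of an IMiD effect. A single significant
   dataset alone is treated as noise; literature genes never significant
   are likewise ruled out.
4. **Regulon enrichment.** For each TF with regulon $R$ (size $K$ after
   intersection with the universe of $N$ genes) and query $Q$ (size $n$),
   $k = |R \cap Q|$ is tested with the upper-tail hypergeometric
   $P(X \ge k)$. TFs with raw $p < 0.05$ are retained and ranked by $k$
   descending (ties by $p$). The screen uses the *raw* p-value; a
   BH-adjusted column is emitted alongside so users can apply the stricter
   rule. Both counts are reported by `run_pipeline()`'s log.
5. **Classification.** Enriched TFs are crossed with the literature
   protein set $L$ (protein-level evidence entries only — gene-level
   evidence feeds the dual-evidence filter, not the classification) and
   the C2H2 list $Z$. The class of interest is $T \cap Z \setminus L$:
   C2H2 TFs regulating many affected genes but never themselves reported
   as drug-affected.
6. **Development filter.** The novel candidates are screened by
   hypergeometric ORA against user-supplied development gene sets (GMT);
   a candidate is kept iff it belongs to at least one set with BH $< 0.05$.
7. **Network essentiality.** The literature proteins form an interaction
   graph (edges with score $> 0.400$, strict); on its main connected
   component we compute degree, harmonic closeness, ordered-pair
   betweenness and maximal clique centrality (MCC), and call a node
   *essential* iff it is dense-rank 1 on all four. The graph is then
   augmented with the prioritized novel TFs and re-ranked, showing how the
   candidates embed among the known drug-affected proteins.

## Network conventions

Three conventions are fixed by what the surrounding tooling
(Cytoscape/cytoHubba) computes, and are worth stating precisely:

- **Closeness is harmonic**: $C(v) = \sum_{u \ne v,\ u \text{ reachable}}
  1/d(v,u)$, so values exceed 1 on graphs of a few dozen nodes and
  unreachable pairs contribute 0. Normalized closeness (bounded by 1) is
  *not* what hub-ranking tools report on such graphs.
- **Betweenness counts ordered pairs**: every ordered $(s, t)$, $s \ne t
  \ne v$, contributes $\sigma_{st}(v)/\sigma_{st}$; on an undirected graph
  this is exactly twice the unordered-pair value. The ordered convention is
  required to match the magnitudes hub-ranking tools print (values above
  $\binom{n-1}{2}$ are impossible under the unordered convention).
- **MCC** is $\sum_{C \ni v} (|C|-1)!$ over *maximal* cliques $C$. For a
  node whose neighborhood contains no edge this equals its degree. Cliques
  are enumerated exactly (Bron–Kerbosch with pivoting, via igraph); when
  the count exceeds `clique_budget` (default $10^5$) the package raises an
  explicit resource error rather than truncating silently.

The whole-graph clustering coefficient defaults to the mean of local
coefficients with degree-<2 nodes contributing 0 (the NetworkAnalyzer
convention); global transitivity is available via
`topology_stats(g, clustering = "global")`. Both are implemented because
reported values in the literature rarely state which convention was used.

Tie handling: all ranks are dense ranks (1, 2, 2, 3), so exact ties —
common on small symmetric graphs — share rank 1 and a split first place
yields an empty essential set rather than an arbitrary winner. The main
component of a disconnected graph is the largest component, with exact size
ties broken by the lexicographically smallest node-name set.

## Enrichment details

`hypergeom_upper()` is the exact upper tail (via `phyper`); the test suite
checks it against exhaustive enumeration of all $\binom{N}{n}$ draws for
every parameter combination with $N \le 12$, and BH against the step-up
definition on grid-enumerated p-vectors.

The frequency-ranked GSEA ranks the full universe (score-0 genes included)
by $s_g$ descending; the running score increments at set members
proportionally to $s_g^{w}$ (default $w = 1$; $w = 0$ reduces the statistic
to the classical two-sample Kolmogorov–Smirnov $D$, which the tests verify
against `ks.test`) and decrements uniformly at non-members. The enrichment
score is the signed extremum; the profile ends at 0 by mass balance. The
null is a *gene-label* permutation with a mandatory seed — phenotype
permutation is impossible because no sample-level data survive to this
stage — with $p = (1 + \#\{|ES^\pi| \ge |ES|\})/(n_{perm}+1)$ and NES the
ES divided by the mean same-sign permutation |ES|. Ties in the ranked list
(many genes share small integer scores) are broken by symbol by default,
documented and stable; a seeded within-tie shuffle is available. GSEA is
exposed as its own stage rather than inside `run_pipeline()`: it is the
only stochastic computation, and the prioritization report does not depend
on it.

The ORA universe must be supplied explicitly in the pipeline (the TF list
for the development filter); when omitted in direct calls it defaults to
the union of set members and the query, which is the weakest defensible
background.

## Percentages and rounding

All percentages are reported to one decimal under round-half-even, with the
raw fraction retained alongside. Published tables rounded inconsistently;
recomputing (e.g. $100 \times 253/407 = 62.16\ldots \to 62.2$;
$100 \times 2947/28395 = 10.38 \to 10.4$) and keeping the fraction makes
the arithmetic reproducible rather than typographic.

## The synthetic scenario generator

`generate_scenario()` produces a fully self-contained study with known
ground truth. Defaults (the standard conditions used across the test
suite): 2000 genes, 60 TFs with 3 planted degraded C2H2 TFs, 8 datasets of
6 cases vs 6 controls, mean shift $|\log_2 FC| = 2$ on responding targets,
per-dataset response probability 0.6, residual SD 0.5 on the log2 scale.
These are sized like small GEO exposure studies: a shift of 2 with SD 0.5
gives per-gene Welch $t \approx 7$ at $n = 6 + 6$, detectable but not
trivial once BH correction across 2000 genes and the 0.6 response rate are
applied.

Structure: regulon sizes follow a truncated power law (exponent 2, range
10–150), with the first planted TF forced to the strictly largest regulon
(an SP1-like TF); target shift direction follows regulation mode (activated
targets drop when the TF is degraded, repressed targets rise). The
interaction network is an Erdős–Rényi graph over the literature proteins
(edge probability 0.08, scores uniform in [0.45, 0.95]) with a planted hub
attached to (max other degree + 2) neighbors, a small side component, three
isolated proteins, and a handful of sub-threshold edges the score filter
must drop. The evidence table covers the hub and proteins at protein level
(1–3 entries each, thalidomide-weighted drugs) and a `lit_coverage = 0.3`
fraction of true targets at gene level, plus decoy genes with no real
signal. Development gene sets contain the planted TFs plus a few other
C2H2 TFs, alongside decoy sets.

One global seed fans out to per-component substreams
(regulons, each dataset, evidence, network, annotations, gene sets), so
every component is individually reproducible and the whole bundle is
bit-identical for a fixed seed.

What the generator does **not** emulate: count-based RNA-seq noise
(negative binomial overdispersion), batch effects and normalization
artifacts, correlated co-expression structure, alias/version drift in gene
symbols, and the literature-screening process itself. Passing tests
therefore demonstrate that the pipeline's logic recovers planted signal
under idealized Gaussian noise — not that real GEO/STRING/TRRUST snapshots
would yield any particular candidate list.

## Degenerate inputs and edge behavior

Zero-variance genes get $p = 1$ with a flag (rather than $p = 0$ from a
degenerate $t$). Empty DE result sets, empty candidate tables and empty
reports are valid values, not errors. An empty development-set collection
skips the filter with a warning. A genome size smaller than the number of
scored genes, duplicate dataset ids, inconsistent hypergeometric counts and
query symbols outside the universe are hard errors. Each `run_pipeline()`
stage failure aborts naming the stage and the offending input.

## Testing strategy and problem sizes

Centralities are verified against brute-force oracles written without
igraph (matrix-power shortest-path counts, subset-testing clique
enumeration): exhaustively over every connected labeled graph with up to 5
nodes, plus fixed-seed random samples of 6- and 7-node graphs. The sampled
tier keeps the suite's runtime proportionate while exercising the same
property on larger graphs. Statistics oracles run exhaustively
($N \le 12$ hypergeometric enumeration; BH step-up on grid vectors).
Recovery tests run the default scenario at seed 1 plus a 4-point effect-
size grid averaged over 10 seeds; the full suite completes in well under
five minutes on one CPU.

## Known limitations

- Vote counting ignores effect direction across datasets; a gene flipping
  sign between studies counts the same as a consistent one.
- The regulon screen inherits TRRUST-style curation bias: TFs with large,
  well-studied regulons are easier to enrich (the raw-p rule follows the
  established practice for this screen; the BH column is the conservative
  alternative).
- Symbol matching is plain canonicalization (uppercase, trimmed) with an
  optional alias hook; no identifier mapping is attempted.
- Network essentiality depends on the input edge snapshot and score
  threshold; centrality ranks on graphs of a few dozen nodes are sensitive
  to single edges, which is why the unique-essential-node claim is only
  made when one node leads all four metrics simultaneously.
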