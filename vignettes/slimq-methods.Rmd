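---
title: "Query-restricted discovery of short linear motifs: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Query-restricted discovery of short linear motifs: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slimq)
```

## The problem

Short linear motifs (SLiMs) are 2–15 residue protein interaction modules
with as few as two functionally constrained positions, typically embedded
in intrinsically disordered regions. Because the sequence signal is so
small, *de novo* discovery from a set of proteins sharing an interaction
partner relies on over-representation: a motif recurring in many unrelated
proteins of the dataset is unlikely by chance. `slimq` implements such a
search — dataset-wide, and in a query-restricted mode in which prior
knowledge of one interacting protein (or a region of it) is used to shrink
the space of candidate motifs and thereby the multiple-testing burden.

## The significance model

Motifs are patterns of `L` defined positions (a fixed residue or a small
ambiguity set) separated by wildcard spacers of at most `W` residues, e.g.
`Q.[IL].FF`. The model evaluates each candidate with three cycles of the
cumulative binomial tail $f(k{+};n;p) = 1-\sum_{i<k}\binom{n}{i}p^i(1-p)^{n-i}$:

1. **Occurrence per cluster.** Proteins are first grouped into *unrelated
   protein clusters* (UPC): connected components of a relatedness graph in
   which two proteins are joined when a local alignment reaches E < 1e-4,
   so homologues are counted once. For a motif with per-site probability
   $p$ (the product over defined positions of the summed residue
   frequencies, computed from the unmasked residues of the dataset), the
   probability it occurs at least once in a cluster with $s$ candidate
   sites is $p_1 = 1-(1-p)^s$.
2. **Support in the dataset.** The probability of seeing the observed
   support $k$ (clusters containing the motif) or more among $n$ clusters
   is $\mathrm{Prob} = f(k{+}; n; \bar{p_1})$, with $\bar{p_1}$ the
   arithmetic mean of the per-cluster values.
3. **Motif-space correction.** The chance that *any* of the $M$ patterns
   searched does this well is $\mathrm{Sig} = 1-(1-\mathrm{Prob})^M$, with
   $M = 20^L (W+1)^{L-1}$ evaluated independently for each defined length
   `L` (`motif_space_size()`).

In query mode the candidate space is instead enumerated empirically from
the query region (`enumerate_query_motifs()`), which typically reduces $M$
by several orders of magnitude; e.g. a 15-residue peptide yields only tens
of candidate patterns against 4,320,000 four-position patterns at
`L = 4, W = 2`. The price is that the query's cluster is removed from the
search data, so a motif supported by $k$ of $n$ clusters is assessed as
$k-1$ of $n-1$ (`query_adjust()`): the trade-off pays off whenever the
space reduction outweighs the lost occurrence, which our simulations
reproduce (see the package acceptance checks).

## Tunable parameters

* `L = 5`, `W = 2` — maximum defined positions and wildcard spacer. These
  are the conventional defaults of this tool family; the motif space grows
  as $20^L(W+1)^{L-1}$, so larger values mainly cost sensitivity.
* `min_support = 3` (UPCs) — matches the benchmarking convention of
  requiring three or more unrelated instances. In query mode the query's
  cluster counts towards this threshold.
* `sig_cutoff = 0.1` — the model is slightly conservative, hence the
  customary cutoff of 0.1 rather than 0.05.
* Disorder masking: residues with an IUPred-style score below 0.2 are
  masked, with a minimum (dis)ordered region size of 5 residues. Masked
  residues are written as `X`; defined positions may never sit on one,
  wildcards may span them.
* Ambiguity (`ambiguity = TRUE`) merges fixed patterns differing at one
  position within the permitted equivalence groups `[ILMVF] [FYW] [FYH]
  [KRH] [DE] [ST]`, only when the merged pattern's support strictly
  exceeds every contributing variant's. In query mode this inflates the
  false-positive rate (variants found outside the query violate the
  space-restriction logic), so it is off by default; `cloudfix = TRUE`
  additionally drops clouds whose significant members are all ambiguous.

## Numerical and algorithmic choices

* The binomial tail is evaluated through `pbinom(..., lower.tail = FALSE)`
  so very small `Prob` values remain accurate; $1-(1-p)^n$ terms use
  `expm1`/`log1p`.
* Candidate enumeration is levelwise: length-`l + 1` patterns extend
  surviving length-`l` patterns. Support pruning at each level is exact
  because support is non-increasing under extension.
* Mask smoothing processes runs left to right, flipping the first run
  shorter than the minimum and recomputing until a fixpoint; the rule is
  deterministic, idempotent, and applies to ordered and disordered runs
  alike (the spec of the original masking procedure names only the
  minimum region size).
* Sites per cluster for a motif of span $s$: within each member sequence,
  every window of $s$ consecutive residues inside a maximal unmasked
  segment; the cluster's count is the **maximum** over members, since
  homologous members largely duplicate content and summing would inflate
  $n$. This rule is isolated in one internal function for easy
  replacement.
* Query-mode residue frequencies are computed after removing the query's
  cluster, keeping the null model independent of the candidate source.
* The built-in relatedness scorer is a Smith–Waterman local alignment
  (BLOSUM62, gap open 11 / extend 1) with a Karlin–Altschul-form
  significance estimate ($\lambda = 0.18$, $K = 0.041$, calibrated for
  this scorer rather than taken from BLAST) and a shared 5-mer prefilter;
  its contract is behavioural: identical or 10%-mutated length-100
  sequences are related, independent random pairs are not (>= 99%). A
  precomputed edge list from an external homology search can be supplied
  instead.
* Tie-breaks in ranking are: significance, then support, defined length,
  span, and finally pattern text — fully deterministic.
* Clouds connect motifs whose rendered patterns contain one another or
  whose occurrence sets share at least two overlapping instances; the
  representative is the top-ranked member. The original tools name the
  concept without the rule, so this reconstruction is a package decision.

## What the synthetic benchmark emulates

`generate_proteome()` stands in for the real human proteome used in the
original benchmark design, which cannot be bundled or downloaded here. Its
defaults are fixed study conditions: 100 proteins of 150–400 residues with
Swiss-Prot-like composition; disorder generated as alternating ordered
(20–60 aa, scores < 0.2) and disordered (15–50 aa, scores >= 0.2) blocks;
optional homologous families created by 5% point mutation of a parent.
Positive proteins are created by implanting a concrete realisation of the
motif wholly inside a disordered block (`implant_instance()`), rather than
by scanning for natural occurrences. `build_simbench()` then assembles
datasets of 5 or 10 mutually unrelated signal proteins (query included) at
signal-to-noise ratios 1:0 to 1:19, each paired with a same-size,
same-query random negative dataset.

What passing these simulations shows — and does not show: the synthetic
proteome is compositionally homogeneous and free of the local sequence
biases, repeats and compositional clusters of real proteomes, so the
specificity measured here (a few percent of random datasets at
Sig <= 0.1) reflects the statistical model, not the harder real-data
setting where biased patterns can be enriched by chance. Sensitivity
numbers likewise assume the implanted motif truly sits in every signal
protein's disordered region.

Problem sizes for the packaged checks were chosen at desk scale: 50
simulated positive datasets (signal 10, ratio 1:0, site query) for the
sensitivity property and 200 random 20-protein datasets for the
specificity property, against an 80–120 protein proteome.

## Motif induction and rating

`slimmaker()` re-derives a motif definition purely from aligned instances:
per column, residues occurring in >= 3 instances are accepted; the column
becomes that set only if the accepted residues cover >= 75% of instances
and number <= 5, else a wildcard; leading/trailing wildcards are trimmed
(terminal anchors retained when all instances are terminal); instances no
longer matching are dropped and the process iterates to a fixpoint.

Predictions are rated against a motif library by information content.
Positional IC is $1-\ln(a)/\ln(20)$ for an $a$-residue set (fixed = 1,
wildcard = 0). `compare_motifs()` scores every ungapped relative alignment
by the summed IC of position-pair intersections (MatchIC), normalised by
the smaller motif's IC (NormIC, capped at 1 — the "entirely matched"
case). A hit with >= 2 matched positions, MatchIC >= 1.5 and
NormIC >= 0.5 is a motif match; matches to the dataset's own motif are
true positives, stricter matches (MatchIC >= 2.5 or NormIC >= 1.0) to
other library motifs — or patterns already validated elsewhere — are
off-target, and the rest are false positives. Off-target calls are
excluded from both the sensitivity (SN) and false-positive (FPX)
numerators in `compute_metrics()`.

## Known limitations

* The cluster site-count rule (max over members) and the cloud edge rule
  are reconstructions of under-specified steps; both are isolated and
  documented above.
* Negated character classes (`[^P]`) and variable-length quantifiers are
  outside the pattern language; complex curated definitions reach the
  search only via `slimmaker()` reduction.
* Conservation masking is accepted only as a user-supplied mask; the
  package computes disorder masking alone.
* The built-in relatedness scorer approximates, but does not reproduce,
  BLAST statistics; for published analyses supply an external edge list.

## A worked example

```{r example, eval = FALSE}
proteome <- generate_proteome(n_proteins = 60, seed = 42)
ds <- build_simbench("DWFCT", proteome, signal = 8, ratio = "1:1",
                     seed = 43)
q <- ds$positive[ds$positive$role == "query", ]
fit <- slim_search(ds$positive,
                   query = sprintf("%s:%d-%d", q$id, q$instance_start,
                                   q$instance_end))
tidy(fit)
glance(fit)
autoplot(fit)
```
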