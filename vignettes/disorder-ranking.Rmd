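---
title: "Ranking genetic disorders from phenotypes and variants: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking genetic disorders from phenotypes and variants: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenovar)
```

## The problem

A clinician evaluating a child with a suspected rare genetic disorder
typically holds two kinds of evidence: a set of observed phenotypes, coded
as Human Phenotype Ontology (HPO) terms, and a list of sequence variants
from exome or genome sequencing, annotated with population frequencies,
predicted consequences and in-silico scores. Neither stream alone is
decisive — thousands of diseases share overlapping phenotypes, and every
exome carries tens of thousands of variants — so the practical question is
one of *ranking*: which candidate disorders best explain this patient?

`phenovar` analyzes the two streams independently and fuses them. Variants
are screened, scored per gene through an ACMG-AMP evidence engine and a
Bayesian combiner; phenotypes are scored against every disease's annotation
profile with a blend of two ontology similarities; and the final per-disease
score is a convex combination of the two. Because real diagnostic cohorts
are access-restricted, the package also ships a deterministic synthetic
generator that emulates the structure of such data, so every component is
testable offline.

## Phenotype model

### Ontology structure

HPO is distributed as `hp.obo`. Although it is often drawn as a tree, it is
a DAG: terms may have several `is_a` parents. `parse_obo()` therefore keeps
every `is_a` edge and defines a term's *depth* as the shortest path to the
root; all other relationship types are ignored, which matches the structure
of the phenotypic-abnormality subontology. Obsolete identifiers are resolved
through `replaced_by` (and `alt_id`) chains rather than silently dropped, so
patient term lists coded against older HPO releases still resolve.

### Information content

The semantic weight of a term comes from the annotation corpus supplied at
run time (an HPOA-style file), not from a frozen table: a term annotated to
few diseases is informative, one near the root is not. We use
disease-frequency counting,

$$\mathrm{IC}(t) = -\ln \frac{|\{d : d \text{ annotated to } t \text{ or a descendant}\}|}{N},$$

with natural logarithms (the convention of the Resnik/Lin literature; the
similarity below is a ratio, so the base cancels). IC is 0 at the root and
non-decreasing along every child edge. A term with no annotated descendant
has no defined semantic weight; it receives an infinite-IC sentinel, is
excluded as a MICA candidate, and contributes no semantic signal — the
topological component carries such terms.

### Term-level similarities

Two complementary term similarities are used, each isolated behind one
function so an alternative formula is a local swap:

* **Topological** (`top_similarity()`), a Wu–Palmer-style depth ratio
  $2\,\mathrm{depth}(\mathrm{lca}) / (\mathrm{depth}(t_1) + \mathrm{depth}(t_2))$
  over the deepest common ancestor. Because depth is the *shortest* path to
  the root, a multi-parent DAG can place a common ancestor deeper than one
  of the terms and push the ratio above 1; the value is clamped to 1, which
  preserves the similarity axioms (range, symmetry, self-maximality) without
  affecting tree-shaped regions of the ontology.
* **Semantic** (`meic_similarity()`), Lin similarity over the most
  informative common ancestor:
  $2\,\mathrm{IC}(\mathrm{MICA}) / (\mathrm{IC}(t_1) + \mathrm{IC}(t_2))$.
  MICA ties are broken by greater depth and then term id, so results are
  deterministic.

### Set aggregation, blend and normalization

Patient and disease term sets are compared with the symmetric best-match
average — each term is matched to its best counterpart, means are taken in
both directions and averaged. This is the standard aggregation for HPO
patient–disease comparison and is robust to redundant patient terms, so no
ancestor-pruning is applied to the input.

The two set-level scores are blended as $\beta \cdot \mathrm{top} +
(1-\beta) \cdot \mathrm{meic}$ with $\beta = 0.9$ by default: most of the
weight on the topological signal, the semantic term refining among
topologically similar candidates. Blends are then min-max normalized across
the candidate list, which makes the phenotype score commensurate with the
$[0,1]$ gene score before fusion. When every blend is equal (including a
single-candidate list) the normalization is degenerate; all scores are set
to 1 — the phenotype then carries no discriminating information and should
impose no penalty.

## Variant model

### Screening

Two screens run before any scoring. The allele-frequency screen removes
variants with population AF above a threshold `alpha` (default 0.1). The
boundary is inclusive and *missing* AF is kept: absence from population
databases is evidence of rarity, and is deliberately distinct from AF 0.
The inheritance screen then checks each gene's disease-linked modes against
single-sample genotypes: dominant modes accept any genotype; autosomal
recessive requires a homozygote or at least two distinct heterozygous
variants (a putative compound heterozygote — without phase data this
over-calls, which we accept and document); X-linked recessive requires
hemizygous or homozygous genotypes, relaxed to heterozygotes when the
patient's sex is unknown. Genes without mode data pass through.

### Evidence engine

Evidence assignment is a transparent rule table over fields already present
on the annotated input (consequence, AF, in-silico score, assertion,
hotspot/control flags, gene-level mechanism flags), covering the 18 codes
an automated annotator can support without segregation or functional data:
PVS1; PS1, PS4; PM1, PM2, PM4, PM5; PP2, PP3, PP5; BA1; BS1, BS2; BP1, BP3,
BP4, BP6, BP7. Every rule can be disabled in a YAML config, thresholds are
exposed (`pm2_af_max` 1e-4, `ba1_af_min` 0.05, `pp3_threshold` 0.8,
`bp4_threshold` 0.2 on a [0,1] in-silico scale), and a rule whose inputs
are missing stays silent rather than erroring mid-case. Users running an
external ACMG interpreter can bypass the table entirely: precomputed codes
in an `ACMG` INFO key or column are ingested verbatim.

### Bayesian combination and the gene score

Evidence combines through exponentially tiered odds. Each item contributes
an exponent of 1 (very strong), 1/2 (strong), 1/4 (moderate) or 1/8
(supporting), negated for benign items; with prior $\pi = 0.1$ and
very-strong odds $O = 350$,

$$\mathrm{odds} = O^{\,\mathrm{pvs} + \mathrm{ps}/2 + \mathrm{pm}/4 + \mathrm{pp}/8 - \mathrm{bs}/2 - \mathrm{bp}/8},
\qquad
P = \frac{\mathrm{odds}\cdot\pi}{(\mathrm{odds}-1)\pi + 1}.$$

Classification bands are pathogenic $\ge 0.99$, likely pathogenic
$\ge 0.90$, likely benign $\le 0.10$, benign $< 0.001$. BA1 is stand-alone:
a common-frequency variant is classified benign with posterior forced to 0
regardless of other evidence, because an exponent treatment would let
strong pathogenic evidence outvote a stand-alone benign criterion.

A gene's score is the **maximum** posterior over its surviving variants:
the conservative single-dominant-variant reading appropriate to monogenic
diagnosis. The aggregation is one isolated function, so a zygosity-aware
alternative (e.g. summing compound-heterozygote contributions) is a local
change.

## Fusion, ranking and evaluation

The final disease score is $\gamma \cdot \mathrm{gene} + (1-\gamma) \cdot
\mathrm{phenotype}$ with $\gamma = 0.5$ — the equal-weight sum of two
commensurate $[0,1]$ scores; $\gamma$ reads as the genotype-vs-phenotype
trust dial. A disease's gene score is the maximum over its linked genes
(0 when none survives), so diseases supported by only one stream still
rank: the streams are genuinely independent and either may be absent.
Ties break on higher phenotype score (the patient-specific signal), then
lexicographic disease id, making the ranking a reproducible total order.
`gene_ranking()` projects the disease ranking onto genes by best disease
rank, which is how benchmark truth (known causal genes) is scored.

Case collections are summarized as TOP-1/5/10/20/50 and >50 proportions
(cumulative through TOP-50; an unranked causal gene counts beyond 50), and
two methods are compared with a one-sided paired Wilcoxon signed-rank test
(`stats::wilcox.test`, normal approximation with continuity correction;
zero differences are dropped by the routine and their count reported; an
all-zero comparison degenerates to p = 1; fewer than five pairs warns but
still reports).

## The synthetic generator

`synth_config()` / `make_corpus_and_cases()` emulate the *structure* of a
diagnostic cohort: a rooted multi-parent ontology (breadth-first primary
parents bounded by `branching`, a random second parent with probability
0.25), diseases annotated with distinct random term sets, one causal gene
and inheritance mode per disease, and patient cases built by perturbing the
causal disease's terms and spiking one causal variant into a VCF among
benign-profile background variants.

Defaults describe a moderately noisy scenario: 150 terms, 60 diseases with
8 terms each, 80 genes, and phenotype noise `p_drop = 0.2`, `p_add = 0.2`,
`p_generalize = 0.1` — roughly, a clinician records most but not all true
phenotypes, adds some incidental ones, and sometimes codes a less specific
term. The causal variant template is a `stop_gained` change with absent
population AF in a loss-of-function-mechanism gene, i.e. exactly PVS1 +
PM2 (posterior 0.994). Each of the 30 background variants per case is
drawn either common (AF 0.12–0.6, removed by the alpha screen or hit by
BA1) or rare-but-benign (AF 0.001–0.09, low in-silico score, sometimes a
benign assertion), so the frequency screen and the benign rules are
genuinely exercised. All randomness flows from one master seed with
derived per-case substreams, so fixtures are byte-identical across runs
and platforms.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: realistic genome coordinates or sequence
context, linkage between phenotype noise and variant noise, phenotype
frequency/onset modifiers, multi-gene diseases, incomplete penetrance, and
the sheer scale of a real exome (tens of thousands of variants) and of the
full HPO (~19k terms). On these synthetic conditions a single spiked
very-strong variant is a giveaway, which is why causal recovery is near
perfect even under heavy phenotype noise; real cohorts, where many genes
carry ambiguous evidence, will sit far below that.

## Numerical and design choices

* Problem sizes: property tests sweep 50 ontologies of 20–200 terms;
  recovery and noise benchmarks use 500 cases at the default corpus size;
  the Bayes combiner is checked exhaustively on the full 2160-point
  evidence count lattice against an independent closed form, to 1e-12.
* Degenerate inputs: empty patient term sets and empty candidate lists are
  errors; a generated case whose phenotype vanishes under noise is flagged
  invalid and skipped with a warning; an empty variant table yields an
  empty gene-score map, not an error.
* Determinism: every tie-break (MICA, LCA, best gene, disease order,
  within-gene best variant) is specified down to lexicographic order;
  repeated CLI runs are byte-identical.
* Where the design was genuinely open we chose: disease-frequency IC (over
  term-frequency); min-max normalization of blended phenotype scores (the
  simplest scheme making them commensurate with posteriors); max-posterior
  gene aggregation; convex-combination fusion (the only reading that makes
  the default an equal-weight sum); keeping redundant patient terms.

## Limitations

The rule engine is intentionally simplified: it consumes precomputed
annotations and cannot itself establish PS2/PS3/PM3/PM6/PP1/PP4/BS3/BS4/
BP2/BP5, which need segregation, functional or phasing data. Inheritance
screening is mode-based only (no pedigree or de novo analysis), and the
compound-heterozygote heuristic is unphased. Phenotype scoring ignores
HPOA frequency and onset modifiers and negated phenotypes. The min-max
normalization makes phenotype scores relative to the candidate list: a
score of 1 means "best among these candidates", not an absolute match
quality.
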