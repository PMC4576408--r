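---
title: "Inferring a transcription factor's regulon from a single genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring a transcription factor's regulon from a single genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A bacterial transcription factor (TF) binds short, degenerate sites —
typically 12–24 bp, often with internal symmetry — in the promoters of the
genes it regulates.  The set of regulated genes and sites is the TF's
*regulon*.  Comparative-genomics reconstructions require orthologs in
related species and therefore miss organism-specific interactions.
`motifregulon` instead reconstructs a regulon from a *single* genome plus
data that are routinely available for one organism: a gene-expression
compendium and, optionally, genome-wide knockout-fitness measurements and
an operon prediction table.

The pipeline has five stages, each exposed as an ordinary function and
chained by `run_pipeline()`:

1. **TF-seeded biclustering** (`estimate_bicluster`) — find genes whose
   expression is linearly coherent with the TF's coding gene over a
   *subset* of conditions;
2. **operon-head filtering** (`filter_operon_heads`) — keep only the genes
   whose promoters can actually carry a binding site;
3. **motif discovery** (`discover_motif`) — a sequential Monte Carlo (SMC)
   sampler infers a two-block PWM of unknown width from the 300-bp
   upstream sequences;
4. **genome scanning** (`scan_genome`) — log-likelihood-ratio scores with
   exact p-values over both strands;
5. **regulon assembly** (`assign_sites_to_genes`, `extend_operons`,
   `evaluate_regulon`) — bidirectional site-to-gene pairing, operon
   extension, intragenic sites, and comparison against a reference.

# Models and procedures

## Linear-coherency biclustering

The model for a co-regulated gene $g$ is affine in the TF's log-expression
over an unknown condition subset $C$:

$$x_{gc} = a_g\, x_{\mathrm{tf},c} + b_g + \varepsilon_{gc},
  \qquad c \in C,$$

with sign of $a_g$ free (repression gives negative correlation; the sign
is recorded per gene and the absolute correlation is used throughout).
The optimizer alternates:

* **gene step** — keep genes with $|\mathrm{cor}(x_g, x_{\mathrm{tf}})|
  \ge r_\mathrm{init}$ (default 0.7) over the current conditions, computed
  pairwise over shared non-missing entries (at least `min_obs = 10`);
* **condition step** — fit each member's least-squares line, standardize
  residuals per gene, and drop conditions whose mean squared standardized
  residual exceeds the `q = 0.9` quantile, keeping at least
  `min_cond_frac = 0.5` of all conditions;

until a fixed point (at most `max_iter = 20` rounds).  One seeding rule is
ours: over the *full* condition set the planted correlations are diluted,
and at `r_init = 0.7` the first gene step can collapse to the TF alone.
When fewer than `min_genes = 5` genes pass, the top-5 genes by absolute
correlation are admitted instead; after one condition step the threshold
rule takes over.  Raising `r_init` never adds genes (tested property).

Knockout-fitness data act as a **veto**: a candidate gene is removed when
the absolute correlation of its fitness profile with the TF's falls below
`r_fit_min = 0.5`.  A veto (rather than a weighted score) keeps the
expression evidence primary and the fitness evidence falsifying; genes
without fitness measurements are kept, and the TF is exempt.

## Operon-head filtering

Adjacent co-transcribed genes share one promoter, so operon-interior
genes rarely carry their own site and their upstream windows only dilute
motif discovery.  Genes are grouped into maximal runs of genomically
adjacent (no annotated gene in between, intergenic gap at most
`max_gap = 200` bp — a standard bacterial operon heuristic), same-strand
genes with consecutive pairwise expression correlation at least
`r_adj = 0.8`; each run contributes only its 5'-most gene.  The filter is
idempotent and its output is always a subset of its input.

## Two-block SMC motif discovery

Each of the $n$ upstream sequences carries at most one motif instance
(present with prior probability $\pi = 0.8$, uniformly placed on either
strand).  Aligned site positions follow a product-Dirichlet PWM
$\theta$ ($w \times 4$, Dirichlet pseudocount $\alpha = 0.5$ per base);
non-site positions follow the genome background.  Integrating $\theta$
out gives a Polya-urn predictive, so a particle only needs its aligned
base counts.  A *particle* is a hypothesis about all placements processed
so far; sequences are fed in order of decreasing absolute TF correlation
(`feeding_order`), so the sampler sees the cleanest evidence first.  For
each particle and each candidate placement the weight is

$$\underbrace{\pi/2K \text{ or } 1-\pi}_{\text{placement prior}}
  \times
  \underbrace{\frac{\prod_j (\mathrm{cnt}_{j,b_j}+\alpha)/(N_j+4\alpha)}
       {\prod_j q_{b_j}}}_{\text{Polya predictive vs background}}
  \times
  \underbrace{e^{-\lambda_\mathrm{sym} D_{\min}(\hat\theta)}}_{\text{symmetry prior}}$$

where $\hat\theta$ is the posterior-mean PWM after the tentative update
and $D_{\min}$ is the minimum two-block dissimilarity (below) over the
three symmetry types.  One placement is sampled per particle; weights are
multiplied by the candidate normalizer; systematic resampling triggers at
ESS $< n_\mathrm{particles}/2$.  With $\lambda_\mathrm{sym} = 0$ the
weighted particle population targets the exact posterior — the test suite
verifies this against exhaustive enumeration (total-variation distance
below 0.05 at 50,000 particles on a 2-sequence problem).

**Blocks and symmetry.**  TF sites concentrate information in two core
blocks (half-sites) that are reverse complements (palindromic), identical
copies (direct repeat), or reversed copies (inverted repeat) of each
other.  The dissimilarity between blocks $p$ and (transformed) $q$ of
length $c$ is the averaged symmetrized Kullback–Leibler divergence in
bits,

$$D = \frac{1}{c}\sum_{j=1}^{c}
      \tfrac12\left[\mathrm{KL}(p_j\|q_j) + \mathrm{KL}(q_j\|p_j)\right],$$

which is zero exactly at perfect symmetry — a raw cross-entropy never
reaches zero and could not serve as a minimized dissimilarity.  During
the SMC the blocks are fixed to the motif halves ($[0,c)$ and $[w-c,w)$,
$c = \lfloor w/2\rfloor$): a per-candidate exhaustive block search would
multiply the inner-loop cost by the number of block pairs, and the halves
match the half-site structure the model targets.  The exhaustive search
(`find_blocks`, maximizing block information content minus $\lambda D$)
and the symmetry classification (`select_symmetry`, with a 1.0-bit
"none" threshold and the fixed tie order palindromic > direct repeat >
inverted repeat) run once on the final PWM.

**Width selection.**  One independent SMC family per candidate width
(default 12–24, seeds derived as `seed + w`); the score is the
accumulated log marginal-likelihood estimate minus a BIC-style penalty
$(3w/2)\log(\text{aligned sites})$ — three free parameters per PWM
column, site count taken from the maximum-weight particle.  Ties prefer
the smaller width.  If the best penalized score does not beat the
all-absent null ($n \log(1-\pi)$), or every placement of the best
particle is absent, the result is `"no motif found"` — on pure background
sequences this check is what rejects the spurious low-information
alignments any motif sampler can produce.

**Prior PWM.**  When a reference motif is available (e.g. when expanding
a known regulon) it enters as pseudo-counts $m\,\theta_\mathrm{prior}$
per column (`prior_m = 10` pseudo-sites) and fixes the width.

## Scanning and p-values

A window $s$ scores $\sum_j \log_2(\theta_{j,s_j}/q_{s_j})$ bits.  The
null distribution of scores under the background is computed by the
standard dynamic program: per-position score contributions are rounded to
an $\varepsilon$ lattice (default: score range / 10,000) and convolved
column by column as sparse integer-indexed mass vectors.  The p-value
lookup applies a $w/2$-index tolerance absorbing the rounding drift
between a directly computed score and its lattice image, so
$p(\text{minimum achievable score}) = 1$ exactly and p-values are
monotone.  At $\varepsilon = 10^{-9}$ the DP is exact to machine
precision against $4^w$ enumeration (tested for $w \le 6$); the default
lattice stays within $5\times10^{-3}$ in the tails used for thresholding.
Sites must pass **both** $p \le 0.001$ and a raw-score threshold; without
a user threshold, 60% of the maximum achievable score is used, or — given
reference sites — the largest threshold recovering 90% of them
(`choose_score_threshold`).  Reverse-complement hit pairs at one locus
(inevitable for palindromes) collapse to the higher-scoring strand, ties
to `+`.  Windows containing N are skipped and counted; a degenerate
background entry is floored at $10^{-3}$ and renormalized with a warning.

## Regulon assembly

Each accepted site searches bidirectionally: downstream on the `+` strand
and downstream of its complement on the `-` strand, pairing in each
direction the nearest gene whose translation start lies within
`max_upstream = 300` bp (mirroring the discovery window; a site between
divergently transcribed genes may pair with both).  Offsets are reported
as site start minus translation start in gene orientation (negative =
upstream).  Sites inside ORFs pair to that gene with
`intragenic = TRUE` (disable with `allow_intragenic = FALSE`; disabling
never increases the gene count).  With an operon table, genes downstream
of a paired gene within its operon are appended with `via_operon = TRUE`.
`evaluate_regulon` reports TPR $= TP/(TP+FN)$ and FPR $= FP/(FP+TN)$ over
gene ids; `roc_curve` sweeps the score threshold.

# The synthetic-data generators

All tests run on seeded generators (`make_pwm`, `make_genome`,
`make_expression`, `make_fitness`, `make_planted_sequences`,
`make_fixture_bundle`); every generator is a pure function of its
parameters and seed.

* `make_pwm` builds cores with exact requested symmetry; consensus draws
  are rejected until the three symmetry transforms are separated by at
  least 0.5 bits, because a half-site that happens to be its own reverse
  complement makes the palindromic and direct-repeat labels genuinely
  ambiguous — without this margin a "99% correct classification" bar is
  unattainable for any classifier.
* `make_genome` lays ~300-bp ORFs with 420-bp spacing (alternating
  strands; operon members consecutive, same strand, 50-bp gaps) on an
  i.i.d. background contig and plants one PWM sample per regulon gene
  uniformly inside its 300-bp upstream window.
* `make_expression` plants the affine bicluster
  ($|a_g| \in [0.8, 1.5]$, random sign, $\sigma = 0.3$ within the
  bicluster) in an otherwise standard-normal matrix; operon members copy
  their head's profile plus small noise.
* The default end-to-end bundle mirrors a small bacterial regulon study
  at desk scale: 50 genes, a TF with an 18-bp palindromic motif
  (core conservation 0.9, per-site identity 0.9), 12 planted-site genes
  (8 singletons including the autoregulated TF, 4 three-gene operon
  heads), 200 expression conditions with a 120-condition bicluster, and
  30 fitness conditions.  These sizes exercise every stage in seconds on
  one CPU while leaving enough signal-to-noise headroom that failures
  indicate implementation defects rather than sampling accidents.

What the generators do **not** emulate: codon structure, GC skew,
transcription-unit read-through, condition-dependent operon structure,
correlated noise across conditions, multiple sites per promoter, or
overlapping regulons of several TFs.  Passing tests therefore demonstrate
correctness of the algorithms under their stated model, not performance
on real compendia, where signal is weaker and the biclustering thresholds
typically need organism-specific tuning.

On the default bundle, reported false positives are dominated by the
bidirectional pairing rule itself: a genuine site upstream of a
minus-strand regulon gene can also fall within the upstream window of its
divergently transcribed neighbour.  This is a property of the assembly
rule (and of real divergent promoters), not a scanning error;
`--strand-restricted` removes it at the cost of genuine divergent
targets.

# Numerical choices and tie-breaking

* Internal coordinates are 0-based half-open everywhere; GFF3 converts at
  the I/O boundary, BED is native.
* All randomness flows from a single integer seed; sub-seeds are derived
  additively (per width: `seed + w`; per SMC step: a fixed multiple of
  the step index).  The C++ core uses a self-contained splitmix64
  generator, so identical seeds give byte-identical outputs on a given
  platform regardless of the standard library.
* Ties break deterministically: smaller width, smaller block length,
  leftmost block, lexicographic gene id, `+` strand.
* Zero-probability PWM entries are an error in dissimilarity
  computations (pseudocounts are applied upstream); `read_motif` floors
  zeros at $10^{-6}$ and renormalizes.
* Degenerate inputs: sequences shorter than the motif width force an
  absent placement; a presence prior of 0 yields "no motif found"; an
  empty reference set flags TPR as undefined rather than dividing by
  zero.

# Known limitations

* One motif instance per sequence and one motif per run; gapped or
  variable-length motifs are out of scope.
* The zero-order genome-wide background is the only null model
  (per-contig backgrounds are a flag away, higher-order models are not
  implemented).
* The width-selection penalty is BIC-styled, not derived; for very small
  sequence sets it can prefer widths one or two positions away from the
  planted width, which is why recovered consensus strings are compared by
  best-offset alignment.
* No genome-wide multiple-testing correction: the raw p-value threshold
  is combined with a score threshold instead, so the score threshold does
  the heavy lifting on large genomes.
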