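---
title: "Calling RNA-protein interaction sites from PAR-CLIP data with clipSiteR"
author: "clipSiteR maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling RNA-protein interaction sites from PAR-CLIP data with clipSiteR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clipSiteR)
```

## The problem

PAR-CLIP maps the binding sites of an RNA-binding protein (RBP)
transcriptome-wide. Cells incorporate a photoreactive ribonucleoside (4SU or
6SG) into nascent RNA, UV light crosslinks the protein to the RNA, and the
immunoprecipitated, protease-digested RNA fragments are sequenced. Reverse
transcription through the crosslinked base leaves a diagnostic transition in
the cDNA — T→C for 4SU, G→A for 6SG — so the aligned reads carry a
single-nucleotide imprint of where the protein touched the RNA.

Two complications make the inference non-trivial. First, not every observed
transition is crosslink-induced: SNPs of the cell line, reproducible
(systematic) sequencing errors, RNA editing and mismapped reads all generate
transitions, some at frequencies indistinguishable from genuine crosslinks.
Second, the coverage profile of CLIP libraries is volatile, so deciding
where one binding site ends and the next begins requires a boundary caller
that separates binding-driven coverage jumps from noise rather than applying
a fixed threshold or window.

clipSiteR addresses both with (i) a Bayesian mixture model over relative
substitution frequencies that scores every transition, (ii) the Mini-Rank
Norm (MRN) algorithm that resolves cluster boundaries around
high-confidence transitions, and (iii) experimentally based FDR estimates
obtained by integrating a matched total RNA-Seq library, which shares the
non-experimental transition sources but cannot contain crosslink-induced
transitions.

## The transition model

At a genomic position with strand-specific read coverage $z$ and $y$ reads
showing the expected transition, the relative substitution frequency (RSF)
is $x = y/z$. Observed transitions are modelled by a three-variable chain
$\Theta \to X \to Y$:

* $\Theta \in \{1, 2\}$ is the unobserved source — non-experimental
  ($\Theta = 1$, prior $p(\Theta = 1) = \lambda$) or crosslink-induced
  ($\Theta = 2$);
* $X \mid \Theta = \theta \sim f_\theta$ is the per-position substitution
  probability, with a source-specific density on $(0, 1]$;
* $Y \mid X = x \sim \mathrm{Binomial}(z, x)$ is the observed count.

The joint density factorizes as
$p(Y, X, \Theta) = p(Y \mid X)\, p(X \mid \Theta)\, p(\Theta)$, and the
posterior source probability marginalizes the unknown substitution
probability out:

$$
p(\Theta = \theta \mid Y) =
  \frac{p(\theta) \int_0^1 \mathrm{Bin}(Y; z, x) f_\theta(x)\, dx}{p(Y)} .
$$

Each transition is scored by the log-odds
$\log \left( p(\Theta = 2 \mid Y) / p(\Theta = 1 \mid Y) \right)$, and a
cluster by its *relative log-odds*: the sum of member log-odds divided by
the number of crosslinkable bases (T in transcript orientation) in the
cluster sequence, so that base composition does not bias the ranking.

### Non-parametric estimation

Neither component density is given a parametric form. Both are estimated on
a fixed RSF grid (step 0.001 on $(0, 1]$) by binned counting followed by
boundary-corrected Gaussian kernel smoothing (bandwidth 0.01 RSF units;
kernel weights are renormalized inside the domain so no mass leaks past 0
or 1):

* $\hat f$ — density of the RSFs of the *target* transition type (e.g.
  T→C), which is the mixture $\lambda f_1 + (1 - \lambda) f_2$;
* $f_1$ — density of the RSFs of all *other* substitution types pooled.
  These cannot be crosslink-induced, so they estimate the non-experimental
  component directly. SNPs, systematic errors and mismapping affect all
  substitution types; crosslinking affects only the target type.

The mixing weight is the standard identifiability choice for a two-component
decomposition with a known component: the largest $\lambda$ keeping
$f_2 = (\hat f - \lambda f_1)/(1 - \lambda)$ non-negative, i.e. the minimum
of $\hat f / f_1$. Two numerical safeguards matter in finite samples:

* the minimum is restricted to grid points where $f_1$ exceeds a small
  relative floor (default $0.01 \cdot \max f_1$), because the ratio is
  meaningless in undersampled density tails;
* both densities are smoothed a second time (bandwidth 0.04) *only* for the
  ratio minimization. The mixing weight is a mass ratio; without this the
  minimum locks onto single-bin downward fluctuations and is biased low.
  With it, recovery of a planted mixing weight on the default synthetic
  conditions is accurate to about $\pm 0.03$.

If the target density is explained by the background alone
($\lambda \to 1$), fitting aborts: the data contain no detectable
experimental signal.

### High-confidence transitions

The RSF-conditional posterior
$p(\Theta = 2 \mid x) = (1-\lambda) f_2(x) / (\lambda f_1(x) +
(1-\lambda) f_2(x))$ defines, for a cutoff $\delta$, the *support*
$[a, b]$: the smallest interval containing all grid points (with positive
mixture density) whose posterior reaches $\delta$. Transitions with RSF
inside the support and coverage $\ge c$ are the high-confidence transitions
(hcTs); each is scored with the count-marginalized posterior and log-odds.
Raising $\delta$ shrinks the support monotonically, which tunes the
stringency of the analysis without refitting.

Classification therefore uses the *conditional* posterior (an RSF interval,
which is interpretable and directly comparable across cutoffs), while
ranking uses the *marginalized* log-odds (which accounts for the counting
noise of finite coverage: $y/z = 5/20$ is weaker evidence than $50/200$).

Defaults: minimum coverage $c = 20$ for model fitting and for
classification, posterior cutoff $\delta = 0.9$. An exhaustive mode — fit
at $c = 20$, then classify at $c = 1$ — trades precision for sensitivity.
4SU chemistry (T→C) is the default; 6SG selects G→A.

## The Mini-Rank Norm boundary caller

The expected coverage of an RBP binding site is a sharply peaked rectangle:
reads piled on the site start together and end together. The MRN algorithm
exploits this geometry. Throughout, $S(i)$ and $E(i)$ denote the number of
alignments whose first/last covered base is position $i$ — the positive and
negative jumps of the coverage function $C(i)$.

1. **Noise model.** A random sample of up to $N = 1000$ hcTs (seeded,
   without replacement) is taken; around each, a window of half-width
   $n = 25$ contributes its $S$ and $E$ values, normalized by the largest
   fluctuation in that window. The pooled non-zero values $D^+$ are fitted
   with a two-component unequal-variance Gaussian mixture by EM (component
   1: noisy fluctuations; component 2: sharp jumps). The crossover
   coefficient is $c = \min\{x \in D^+ : p(k{=}2 \mid x) \ge
   p(k{=}1 \mid x)\}$.
2. **Local thresholds.** For the maximal non-zero coverage window $w$
   around an hcT, the side-specific thresholds are
   $\delta_s = \lceil c \cdot \max S(w) \rceil$ and
   $\delta_e = \lceil c \cdot \max E(w) \rceil$ (clamped to $\ge 1$); the
   coefficient scales to each side's dynamic range. Alternatively a single
   global threshold $\delta = \lfloor 0.1 \cdot \max(m_1, m_2) \rfloor$ may
   be used, where $m_1$ is the coverage requirement at hcTs and $m_2$ the
   mode of their coverage distribution.
3. **Candidates.** Candidate starts are window positions $\le$ the hcT with
   $S(i) \ge \delta_s$; candidate ends are positions $\ge$ the hcT with
   $E(i) \ge \delta_e$; their Cartesian product forms the candidate
   clusters. An empty side falls back to the window edge, so every hcT
   yields at least one candidate — the caller cannot drop an hcT.
4. **Rank vectors.** Each candidate $(k, l)$ becomes
   $(r_s, r_e, r_w)$: the 0-based rank of its start among distinct starts
   by decreasing $S$ (ties toward the 5' end), of its end among distinct
   ends by decreasing $E$ (ties toward the 3' end), and of its width in
   increasing order (ties share the minimum rank). The ideal rectangle is
   $O = (0, 0, 0)$.
5. **Selection.** The candidate minimizing $\lVert r \rVert_2$ wins;
   equal norms prefer the shorter cluster, equal widths the 5'-most start
   (a determinism tie-break). hcTs selecting the identical interval merge
   into one cluster; overlapping but distinct intervals are reported
   separately, which is what preserves the resolution of adjacent binding
   sites.

Numerical details of the EM: initialization at the 25th/75th percentiles of
$D^+$ (falling back to a range-based split when one value dominates both
quantiles), log-likelihood tolerance $10^{-8}$, at most 500 iterations,
variance floor $10^{-6}$. A fit whose components fail to separate (weight
below 1%, or means closer than $10^{-3}$) is rejected as degenerate rather
than silently used. Tie orientation of ranks is applied in genomic
coordinates on both strands; the choice only affects exact ties of integer
counts and keeps output deterministic.

## FDR estimation from matched RNA-Seq

Total RNA-Seq from the same cells shares the cell line's SNPs and the
library-independent systematic substitution processes, but no crosslinks.
A PAR-CLIP transition that is equally present in RNA-Seq is therefore
likely a false positive.

* **Site level.** Over positions covered $\ge 20\times$ in both libraries
  with at least one target transition in PAR-CLIP, the RSF interval
  $(0, 1]$ is split into ten equal bins. Within each bin, the *upper* FDR
  bound counts as false every position with any target transition in
  RNA-Seq, the *lower* bound only those whose RNA-Seq RSF falls in the same
  bin. Per construction lower $\le$ upper in every bin.
* **Cluster level.** Clusters are ranked by decreasing relative log-odds;
  for each top-$n$, the *conservative* FDR counts a cluster false when at
  least one member hcT has an RNA-Seq RSF inside the PAR-CLIP-specific
  support $[a, b]$, and the *relaxed* FDR only when every RNA-Seq-covered
  member does. A member without RNA-Seq coverage contributes no evidence —
  absence of data is not treated as contradiction.

The within-bin requirement for the lower bound, and the target-type
requirement for membership, follow the convention that a "transition" means
the expected transition type of the chemistry.

## Post-processing

Clusters and hcTs export as BED6 (0-based half-open; scores
$\min(1000, \mathrm{round}(100 \cdot \text{rel. log-odds}))$ and
$\min(1000, \mathrm{round}(1000 \cdot \text{posterior}))$ respectively) and
as TSV that round-trips coordinates exactly. Cluster sequences export as
transcript-oriented FASTA (minus-strand clusters reverse-complemented) for
motif discovery.

miRNA seed enrichment compares the per-kilobase count of the reverse
complement of a miRNA's seed (positions 2–8) in the cluster sequences with
the mean per-kilobase count over dinucleotide-shuffled copies of the miRNA
(default $10^4$ shuffles, each seed taken from positions 2–8 of the
shuffle). The shuffle is a randomized Eulerian walk on the dinucleotide
transition multigraph (Hierholzer's algorithm with permuted adjacency
lists), so the dinucleotide multiset is preserved exactly; sequences with
fewer than two distinct dinucleotide transitions are returned unchanged
with a warning. Per-kilobase normalization applies identically to observed
and background counts, so the enrichment ratio is normalization-invariant;
it is exposed as a parameter because "relative count" conventions vary.

## The synthetic-data generator

Because genuine PAR-CLIP/RNA-Seq pairs are external, every guarantee of the
package is exercised on seeded simulations with known truth
(`simulate_genome()`, `simulate_truth()`, `simulate_parclip()`,
`simulate_rnaseq()`). The generator emulates:

* strand-alternating transcribed regions (1 kb transcripts, 200 bp gaps) at
  uniform background coverage (default 25× PAR-CLIP, 30× RNA-Seq);
* rectangular binding-site pile-ups: 50 reads of length 36 whose offsets
  keep the whole 30 bp site inside the read, giving a coverage plateau with
  sharp shoulders;
* crosslink-induced transitions: every PAR-CLIP read overlapping a site
  converts its crosslinkable bases independently with the site's
  probability, drawn once per site from U(0.25, 0.6);
* homozygous SNPs (default 20): alternate allele in every read of both
  libraries, RSF ≈ 1;
* shared artifact positions (default 500): position-specific substitution
  rates reproduced in both libraries, 60% low-rate U(0.01, 0.12)
  (systematic sequencing errors) and 40% U(0.12, 0.95) (RNA-editing- and
  mismapping-like events), with a transition-biased alternate base
  (transitions 4× transversions, matching the substitution spectrum of
  these processes). Without a shared noise component spanning the whole RSF
  range, matched-control FDR estimation has nothing to detect outside the
  signal band — real CLIP data always contains such reproducible
  non-crosslink transitions;
* independent uniform sequencing errors (default rate 0.002 per base).

Reads are emitted pre-aligned (perfect placement, ungapped 36M records) as
coordinate-sorted, indexed BAM; alignment is upstream of this package, and
hermetic tests must not depend on an external aligner. The generator does
**not** model fragment-length distributions, RNA secondary structure,
PCR duplicates, paired ends, indels or mapping ambiguity — so passing tests
demonstrate the statistical machinery on idealized coverage geometry, not
robustness to alignment artifacts.

Default problem sizes (one 300 kb chromosome, 200 sites, ~180k reads per
library) were chosen so a full pipeline run completes in about half a
minute; they give ~2,900 target transition sites at the fitting coverage,
enough for stable density estimation.

## Design choices and limitations

* **Coordinates** are 1-based closed inside the package (the Bioconductor
  convention of GRanges/IRanges used throughout); BED output converts to
  0-based half-open at the boundary.
* **Identical-interval merging only.** Nearby hcTs whose optimal candidate
  intervals differ slightly produce distinct, overlapping clusters rather
  than one merged region. This is deliberate: merging would undo the
  resolution the MRN algorithm provides for adjacent binding sites. Users
  wanting broader regions can `GenomicRanges::reduce()` the output.
* **Log-odds capping.** Where the background likelihood underflows to zero
  the raw log-odds are infinite; they are capped at ±700 (configurable) to
  keep downstream arithmetic finite.
* **Quadrature** is the trapezoidal rule on the model grid; the
  count-marginalized and RSF-conditional posteriors agree to well under
  0.01 at coverage 10⁴, and results are stable under grid refinement.
* **Strandedness of the RNA-Seq library** is assumed by default; an
  unstranded flag pools both strands at each position, counting the
  complementary substitution code on the opposite strand.
* **What is not modelled:** multi-component (>2) mixtures, parametric
  (beta-binomial) alternatives, PCR-duplicate collapsing (exposed as an
  ingestion flag, default off, since upstream pipelines differ), and any
  transcriptome annotation of the called clusters.

## A minimal session

```{r example, eval = FALSE}
library(clipSiteR)

genome <- simulate_genome(1, 3e5, gc = 0.4, seed = 1)
truth <- simulate_truth(genome, seed = 2)
pc <- simulate_parclip(truth, "parclip.bam", seed = 3)
rn <- simulate_rnaseq(truth, "rnaseq.bam", seed = 4)

fit <- call_binding_sites(pc$bam, genome, cfg = mrn_config(seed = 5))
fit$model          # mixing weight lambda
head(fit$clusters) # GRanges of called binding sites

rprof <- substitution_profile(rn$bam, genome)
site_fdr(fit$profile, rprof)
cluster_fdr(fit$clusters, rprof, attr(fit$hcts, "support"),
            top_n = c(75, 250))
```

The same pipeline is scriptable through the CLI under
`system.file("cli", "clipSiteR", package = "clipSiteR")` with the
subcommands `simulate`, `fit`, `call`, `fdr`, `seeds` and `export`.
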