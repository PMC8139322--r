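---
title: "Methods: pan-genome analysis with panbac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome analysis with panbac}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panbac)
```

`panbac` analyses bacterial pan-genomes: it builds ortholog gene
families from proteomes, partitions them into core, dispensable and
strain-unique classes, fits rarefaction curves to decide whether the
pan-genome is open, delineates species from genome distances, and
screens for gene families associated with a habitat contrast (here
called *marine* versus *land*). This vignette explains the models
behind each step, the defaults and why they were chosen, and what the
bundled simulator does and does not emulate.

## The gene-family presence/absence matrix

Everything downstream consumes a `pa_matrix`: gene families as rows,
genomes as columns, integer copy numbers as entries, plus per-genome
metadata (niche, species). It can come from three places: the
package's own clustering (`build_families()`), a Roary-style
`gene_presence_absence.csv`, or a plain binary TSV.

## Ortholog clustering

Families are built in the classical bidirectional-best-hit (BBH)
fashion:

1. **All-against-all alignment.** Ends-free ("overlap") pairwise
   alignment with BLOSUM62 scores and affine gaps (open 11, extend 1).
   Identity is the fraction of matching aligned columns (end gaps are
   excluded by the alignment type); coverage is the aligned span
   divided by each sequence's full length, computed for both sequences
   separately.
2. **Thresholds.** A hit requires identity ≥ 0.5 *and* both coverages
   ≥ 0.5 — the 50%/50% regime common to OrthoMCL/PGAP-style pipelines.
   The usual E-value cut-off is replaced by a raw alignment-score floor
   (`score_min`): an E-value depends on the database size, so two runs
   over different genome sets would accept different pairs; a score
   floor is deterministic and portable.
3. **Graph.** Edges are inter-genome BBHs (ties kept: if two hits in a
   target genome share the best score, both survive) plus intra-genome
   hits passing the same thresholds (in-paralogs). Families are the
   connected components. MCL inflation is deliberately not
   re-implemented; on data with a clear identity gap between orthologs
   and non-orthologs the components are identical and fully
   deterministic.
4. **Determinism.** Family ids are assigned by the lexicographically
   smallest (genome, gene) member of each component, so repeated runs
   label families identically.

A shared-4-mer prefilter may skip alignment of hopeless pairs. It is a
pure speed device: the tests compare filtered and unfiltered runs and
require byte-identical matrices.

`single_copy_core()` extracts families with exactly one member in every
genome — the standard input for core-gene phylogenetics.
`concat_distance_tree()` then averages per-family p-distances (mean
per-site mismatch over non-gap columns of global pairwise alignments)
and applies neighbor joining. This is a distance-based stand-in for a
maximum-likelihood tree: fast, deterministic, and adequate for
clade-level structure, but it does not model rate heterogeneity and
should not be used for branch-support claims.

## Pan-genome partition and rarefaction

Occupancy drives the partition: a family present in all *N* genomes is
**core**, in exactly one genome **strain-unique**, otherwise
**dispensable**. For the degenerate *N* = 1 matrix both rules would
apply; core takes precedence ("shared by all strains" is vacuously
true), so a single-genome matrix is all core. The partition counts
occupancy, not copy number: a family with two copies in every genome is
still core.

`rarefaction()` adds genomes in random order and records the cumulative
union (pan), intersection (core) and increment (new genes). The curve
models are fitted to the **mean** trajectory across permutations (100
by default; the choice of mean over median is a package decision — at
these permutation counts the two are nearly indistinguishable on
simulated data, and the mean is the quantity the exhaustive-enumeration
oracle can check exactly).

Three models are fitted by Levenberg–Marquardt nonlinear least squares
(`minpack.lm`):

* pan: $y(n) = A\,n^{\gamma} + C$ (Heaps-style power law),
* core: $c(n) = A'\,e^{-kn} + \Omega$,
* new genes: the same decay form, fitted for $n \ge 2$.

Initial values are $A = \mathrm{range}(y)$, $\gamma = 0.5$ (or
$k = 0.1$), $C = \min(y)$, with up to five jittered restarts; the
best-RSS convergent fit wins. Bounds: $\gamma \in [0, 2]$,
$k \in [0, 5]$, and — beyond the conventional bounds — $A \ge 0$ and
$C \ge 0$ for the pan model. The non-negative offset matters: an
unconstrained fit of a saturating trajectory can drift into the
degenerate regime $A\,n^{\gamma} \approx A\gamma\ln n$ with a huge
amplitude and a large *negative* offset, reporting
$\gamma \approx 0$ for data whose new-gene influx is clearly positive.
Since the offset represents a baseline gene count, a negative value is
meaningless, and excluding it removes the degeneracy.

A pan-genome is called **open** when $\gamma > 0.01$; the small
tolerance keeps numeric noise on genuinely flat (closed) trajectories
from flipping the flag. $R^2 = 1 - SS_{res}/SS_{tot}$, with the
convention that a perfect fit of a constant trajectory
($SS_{tot} = 0$, $SS_{res} = 0$) has $R^2 = 1$; if $SS_{tot} = 0$ but
the fit is not perfect, $R^2$ is undefined and flagged. Constant input
trajectories short-circuit the optimiser entirely (amplitude 0, offset
= the constant). A fit that fails all restarts returns a flagged
failure object rather than raising.

One typographic note on the exponential core model: decay exponents are
sometimes printed with the minus sign lost (`e^0.058n`). The package
always treats the core model as a decay, $e^{-kn}$ with $k \ge 0$.

## Genome distances and species delineation

`sketch_genome()` is a bottom-$s$ MinHash over canonical
(strand-minimal) k-mers, hashed with a seeded 64-bit FNV-1a function.
Hash values are masked to 53 bits so they are exactly representable as
R doubles on every platform — sketches are bit-identical across
machines. Defaults $k = 21$, $s = 1000$ match Mash. The Mash distance
uses the merged-sketch estimator: Jaccard $j$ is estimated from the
$s$ smallest hashes of the union, then
$d = -\tfrac{1}{k}\ln\frac{2j}{1+j}$, capped at 1 when $j = 0$.

Species assignment consumes an ANI matrix (the package does not
re-implement BLAST/MUMmer ANI; `kmer_ani()` offers the labelled
approximation $ANI \approx 100(1-d)$). Genomes are joined at
ANI ≥ 95% and species are the connected components — so chains merge
transitively, which is documented behaviour, not an accident.
`ani_correlation()` computes the Pearson correlation between the
genomes' full ANI profiles with self-entries set to 100, matching
common correlation-heatmap practice (an assumption, recorded here).
`hierarchical_tree()` (UPGMA by default) and `nj_tree()` render either
kind of matrix as dendrograms/trees; negative NJ branch lengths are
clamped to zero with a warning.

## Niche-associated families and COG enrichment

Two screens are deliberately kept distinct:

* `shared_dispensable()`: families dispensable in the whole set *and*
  present in every genome of a group. Presence outside the group is
  **not** restricted — whether published "shared by all marine
  strains" counts required absence from land strains is ambiguous, so
  this function implements the weaker reading and the stricter rule
  lives in `niche_specific()`.
* `niche_specific()`: present in at least `ceiling(f · |focal|)` focal
  genomes (the "at least one-third" rule uses the ceiling, because
  "at least") and in at most `max_background_presence` background
  genomes (default 0: strict absence).

`cog_enrichment()` tests each COG category with a two-sided Fisher
exact test, summing all hypergeometric outcomes no more probable than
the observed table (the standard two-sided convention; exact-test
variants differ and the choice is recorded here). The default reports
raw p-values at α = 0.05; Benjamini–Hochberg correction is available
via `correction = "BH"`. `niche_report()` runs both screens per
species and reports species with fewer than two genomes in either
niche as "insufficient contrast" instead of testing them.

Because Fisher's test is conditionally exact, its attained level is
below α for small tables. The type-I-error check therefore restricts
itself to categories whose pooled count is at least 200, where the
discreteness is negligible; with smaller margins the flag rate is
conservative by construction, which is a property of the test, not a
bug.

## The synthetic pan-genome simulator

No generative model is published for the data this package targets, so
the simulator's choices are explicit stand-ins:

* **Tree**: a Kingman coalescent (`ape::rcoal`) or a balanced topology
  with uniform branch lengths.
* **Gene content**: a fixed core present everywhere; accessory
  families gained once (infinitely-many-genes style) at a uniform
  position on a Poisson-chosen branch, then lost along descendant
  branches at a constant rate — a loss removes the whole subtree below
  it. Single gain plus exponential loss yields open pan-genomes of the
  kind observed in real clades.
* **Niches**: contiguous blocks of the tree's tip order share a niche
  (marine isolates cluster together), with a shuffled mode as a null.
* **Planted signal**: niche-specific families inserted into a fixed
  fraction of one niche's genomes and absent from the other, with COG
  labels drawn from a 24-category distribution (23 bacterial COG
  letters plus "unknown"; the rare eukaryote-leaning categories A and
  B are omitted) and an optional category skew of known strength.
* **Proteomes**: per-family random ancestors (20 uniform residues,
  length uniform on 100–400 aa), members mutated so the expected
  *pairwise* identity matches the requested value (solving
  $(1-m)^2 + m^2/19 = p$ for the per-branch rate $m$); different
  families are independent random sequences, so inter-family identity
  sits far below 50%.
* **RNG**: one root seed; every stage hashes `"<stage>:<seed>"` to its
  own stream, so outputs are byte-identical given a seed and adding a
  stage never perturbs another.

**Calibration.** The defaults are fixed at a 52-genome clade with a
2,370-family core. The gain rate was calibrated once, by pilot
simulation and linear rescaling (`calibrate_gain_rate()`), so that
genomes carry ≈ 3,705 gene families on average; with the loss rate 0.3
this gives `gain_rate = 1045`. Two rates cannot simultaneously match a
target mean genome size, a target pan-genome size and a target
unique/dispensable split; the per-genome mean was prioritised as the
calibration target, and the resulting simulated pan-genome
(~10,700 families) is somewhat larger and less unique-heavy than real
clades of this size. Tests that depend on class composition therefore
assert invariants (conservation, monotonicity, truth recovery), not
absolute counts.

**What passing tests do and do not show.** The simulator produces
idealised data: families are cleanly separated in identity, there is no
annotation noise, no fragmented assemblies, no horizontal transfer of
partial genes, and no correlation between gene function and
phylogenetic position. Passing the recovery tests shows that the
algorithms are implemented correctly, not that real proteomes will
cluster as cleanly; on real data the 50%/50% thresholds and the BBH
graph inherit the usual failure modes (domain sharing, fission/fusion).

## Problem sizes used in the checks

The bundled checks run at deliberately small scale, chosen so each
suite completes comfortably on a single CPU: oracle-equivalence
clustering on ≤ 20 genes, exhaustive rarefaction at 5 genomes
(120 orderings), Fisher enumeration at margins ≤ 30, MinHash
unbiasedness with 100–200 seeded sketches of 2 kb sequences, and
openness discrimination over 20 seeds per regime with 20 rarefaction
permutations each. The curve-fit round trips regenerate noiseless
trajectories for n = 1..52 from published fitted models and require
the exponent back to three decimals and the asymptote to one decimal.

## Known limitations

* Connected components, not MCL: very permissive thresholds chain
  families together; the threshold-monotonicity property only
  guarantees that tightening thresholds never merges.
* The distance tree is not an ML phylogeny and carries no support
  values.
* `kmer_ani()` is an approximation; for species boundaries near 95%
  use an alignment-based ANI matrix.
* The simulator does not emulate nucleotide-level evolution,
  recombination or codon structure; `simulate_ani()` draws ANI values
  consistent with species labels rather than deriving them from
  sequence.
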