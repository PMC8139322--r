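# panbac

Comparative pan-genome analysis for bacterial clades, built around the
kind of question asked of closely related genome collections such as
the *Bacillus pumilus* species group: how large is the pan-genome, is
it open, where do the species boundaries lie, and which accessory gene
families track the habitat a strain was isolated from?

The package is aimed at microbial comparative genomicists who already
have per-genome protein FASTA files (or a Roary-style
`gene_presence_absence.csv`) and want a reproducible, scriptable path
from gene families to openness curves, species calls and
niche-association tables.

## What it computes

* **Ortholog families** — all-against-all ends-free BLOSUM62
  alignments, hits at ≥ 50% identity and ≥ 50% coverage of both
  sequences, inter-genome bidirectional best hits plus in-paralog
  edges, families as connected components
  (`build_families()`, `single_copy_core()`).
* **Pan-genome partition** — occupancy-based classes: core (all
  genomes), strain-unique (one genome), dispensable (in between)
  (`partition()`).
* **Rarefaction and openness** — permuted genome-addition curves and
  nonlinear least-squares fits of

  $$y(n) = A\,n^{\gamma} + C \qquad c(n) = A'e^{-kn} + \Omega$$

  for the pan and core trajectories (plus the same decay for new
  genes); the pan-genome is called open when γ > 0.01
  (`rarefaction()`, `fit_pan_curve()`, `fit_core_curve()`,
  `fit_new_gene_curve()`).
* **Genome distances and species** — canonical-k-mer MinHash sketches
  and Mash distances $d = -\tfrac1k \ln\frac{2j}{1+j}$, Pearson
  correlation of ANI profiles, UPGMA/NJ trees, and species as
  connected components at ANI ≥ 95%
  (`sketch_genome()`, `mash_distance()`, `ani_species()`).
* **Niche-associated families** — group-shared dispensable genes and
  the stricter "present in ≥ ⅓ of the focal niche, absent from the
  background" rule, with per-species reports and two-sided Fisher
  exact COG enrichment (`shared_dispensable()`, `niche_specific()`,
  `cog_enrichment()`, `niche_report()`).
* **A synthetic pan-genome simulator** — known tree, known gain/loss
  history, planted niche-specific families, COG labels and emitted
  proteomes, so every stage above can be validated against ground
  truth (`simulate_pangenome()`, `emit_proteomes()`).

## Worked example

```r
library(panbac)

cfg <- sim_config(n_genomes = 12, core_size = 1800,
                  gain_rate = 400, loss_rate = 0.3, seed = 42)
sim <- simulate_pangenome(cfg)
sim$matrix
#> pa_matrix: 4181 gene families x 12 genomes
#>   core (all 12 genomes): 1800;  single-genome: 775
#>   niches: land=7, marine=5

partition(sim$matrix)
#> pan_partition: 4181 families over 12 genomes
#>   core 1800 (43.1%), dispensable 1606 (38.4%), unique 775 (18.5%)

prof <- rarefaction(sim$matrix, 100, seed = 42)
fit_pan_curve(prof)
#> curve_fit [pan_power]: y = 2456.7 n^0.218 + 0.0  (R2 = 0.99768, open pan-genome)
fit_core_curve(prof)
#> curve_fit [core_expdecay]: y = 1779.4 exp(-1.055 n) + 1800.4  (R2 = 0.99913)

meta <- sim$matrix$metadata
length(niche_specific(sim$matrix,
                      meta$genome[meta$niche == "marine"],
                      meta$genome[meta$niche == "land"]))
#> [1] 49
```

Reading the output: the 12 simulated genomes share a 1,800-family
core (43.1% of the 4,181-family pan-genome); the positive fitted
exponent γ = 0.218 classifies the pan-genome as open (new genomes keep
contributing new families); the fitted core asymptote Ω ≈ 1,800
recovers the simulated core size; and 49 accessory families satisfy
the marine-specific rule (≥ ⅓ of marine genomes, absent from land).

A command-line interface wraps the same functions
(`inst/exec/panbac`, or `pan_cli()` from R):

```sh
panbac simulate --genomes 12 --core 1800 --gain 400 --seed 42 --out sim/
panbac profile  --matrix sim/matrix.tsv --permutations 100 --seed 42 --out profile.json
panbac fit      --profile profile.json --out fits.json
panbac species  --ani ani.tsv --threshold 95 --out species.tsv
```

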