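---
title: "A simulation bench for forensic SNP genotype imputation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A simulation bench for forensic SNP genotype imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the bench answers

Forensic applications that need dense SNP profiles — investigative genetic
genealogy, distant-kinship inference, phenotype prediction — routinely start
from partial data: a targeted panel of a few thousand to a few hundred
thousand markers, possibly contaminated by allelic drop-in and drop-out.
Genotype imputation can extend such a profile from a phased reference panel,
but every imputed genotype carries error risk, and the tolerable risk differs
sharply between applications.  This package measures, under controlled
synthetic conditions, how imputation **call rate** (assigned genotypes /
targeted genotypes) and **error rate** (wrong assigned genotypes / assigned
genotypes) respond to

* the number of observed genotypes (400–10,000 of a 20,000-site target set),
* the genotype-probability (GP) threshold used to accept imputed calls
  (0.5 / 0.9 / 0.95 / 0.99),
* allelic drop-in and drop-out in the observed data (rate 0.1 each),
* the ancestry composition of the reference panel (focal population present
  or absent, at a target F~st~ of 0.1), and
* WGS-like inputs where a fraction (10–75%) of all target sites is observed.

Both metrics are aggregated as median / minimum / maximum over 10 replicate
test individuals per design cell, and single-chromosome counts can be
extrapolated linearly to a genome-scale target set (1.3 million SNPs by
default) with `extrapolate_genome()`.

## The imputation model

The engine is a diploid Li–Stephens haplotype-copying hidden Markov model
applied directly to unphased genotypes.  The hidden state at target site
$m$ is the **ordered pair** $(i, j)$ of reference haplotypes the two
chromosomes are copying; each chain switches templates independently with
probability

$$\tau_m \;=\; 1 - \exp\!\big(-4 N_e\, d_m / (100\,k)\big)$$

across $d_m$ centiMorgans against $k$ reference haplotypes, landing on a
uniformly chosen template.  An observed genotype is emitted through a
per-allele miscopy probability $\varepsilon$: each of the two alleles copies
its template allele with probability $1-\varepsilon$.  Missing genotypes
emit probability 1, so they contribute no information.  The forward–backward
algorithm then yields, at every site, the exact posterior distribution over
the three diploid genotypes given *all* observed genotypes; the reported
per-site quantities are the posterior triple $(p_0, p_1, p_2)$, the dosage
$p_1 + 2p_2$, the GP score $\max(p_0,p_1,p_2)$, and the argmax genotype
(ties broken toward the lower genotype code for determinism).  A missing
site is accepted as *imputed* when its GP meets or exceeds the calling
threshold $Q_{gp}$ (inclusive rule).

Working on unphased genotypes with a paired-chain state removes the need
for a separate phasing stage and keeps the model small enough that a
brute-force path-enumeration oracle can verify the posteriors exactly on
tiny instances — the test suite checks forward–backward against literal
enumeration of all $(k^2)^L$ state paths to $10^{-9}$ on hundreds of random
instances.  Established imputation tools (e.g. Beagle) use a richer
haplotype-cluster machinery; this engine occupies the same input/output
contract (VCF in, `GT:DS:GP` out) with an exactly computable posterior.

### Numerical scheme

Forward messages are rescaled at every site, so there is no underflow at
any chromosome length.  The transition is applied in $O(k^2)$ per site via
its factorised form (row sums, column sums, total), giving $O(L k^2)$
overall.  Storing all forward messages for the backward sweep would need
$L k^2$ doubles (32 GB at $L = 10^5$, $k = 200$), so the implementation
checkpoints the forward matrix every $\lceil\sqrt{L}\rceil$ sites and
recomputes within blocks during the backward sweep — memory
$O(\sqrt{L}\,k^2)$ for a ~2× forward-cost overhead.  Sites at zero genetic
distance use $\tau = 0$ exactly; a zero-likelihood site (possible only at
$\varepsilon = 0$ with contradictory data) raises an informative error.

### Engine parameters

| parameter | default | meaning |
|---|---|---|
| `ne` | 10,000 (engine); 2,500 (benchmark default) | recombination-intensity scale; switch rate is $4 N_e / k$ per Morgan |
| `eps` | $10^{-3}$; `"auto"` = Watterson $\tilde\theta/(2(\tilde\theta + k))$ | per-allele miscopy probability |
| `q_gp` | 0.95 | GP calling threshold (inclusive) |

The engine-level default `ne = 10000` is the conventional human-scale
choice for a Li–Stephens model.  The *benchmark* overrides it with the
value matched to its own synthetic panels (below).  Settings of the order
of $10^6$, as used by some imputation tools, belong to differently
parameterised models and would make this HMM's chains nearly memoryless at
typical site spacings.

## The synthetic data generator

No external data are downloaded; the generator emulates the features of a
phased reference resource that imputation actually exploits.

1. **Founders** (`simulate_founders()`): sites are independent with
   alternate-allele frequencies drawn from Beta(0.8, 0.8) truncated to
   $[\text{maf}_{\min}, 1-\text{maf}_{\min}]$, $\text{maf}_{\min} = 0.05$ by
   default — a spectrum without a heavy rare tail, as appropriate for dense
   forensic target panels, and exposed as configuration.  Sites whose
   realised minor-allele count falls below the floor are redrawn, so every
   panel site is polymorphic.
2. **LD** (`recombine_panel()`): panel haplotypes are mosaics of the
   founders with switch points drawn as a Poisson process on the cM scale
   (rate `n_generations` per Morgan) — not a coalescent, but it creates the
   one feature imputation needs: tunable block-scale LD, deterministic
   under a seed.
3. **Population structure** (`split_populations()`): per population,
   founder frequencies are perturbed Balding–Nichols style with the
   `divergence` parameter playing the role of the target F~st~, a fresh
   founder set is drawn, and within-population mosaics are generated.  The
   Weir–Cockerham estimator on generated panels recovers the target within
   a few hundredths at 5,000 sites.  With `divergence = 0` the original
   founder set is reused, so the populations are statistically identical.
4. **Truth individuals** (`sample_truth_individual()`): two panel
   haplotypes drawn without replacement; the drawn rows are always removed
   from the reference before imputation (the leave-one-out contract the
   tests assert).
5. **Degradation** (`degrade()`): uniform random pruning to a count or
   fraction, then allelic drop-in (each observed *homozygote* becomes
   heterozygous with probability 0.1 — a single spurious opposite allele,
   never a hom→hom flip) and/or allelic drop-out (each observed
   *heterozygote* loses one allele with probability 0.1, surviving allele
   uniform).  Drop-out is interpreted per genotype by default, mirroring
   the genotype-level drop-in rule; an allele-level mode (rate applied
   independently to each allele) is available behind `mode = "allele"`.
   Errors are injected after pruning — they are properties of the typed
   data — and all provenance is tracked exactly.

### Why the default geometry looks the way it does

The default design matrix is a 1/65-scale model of a genome-wide study:
one synthetic chromosome of **20,000 target sites** (~35 Mb at 1,750 bp
spacing, 1.2 cM/Mb) stands in for chromosome 22's share of a 1.3M-SNP
target set, and the observed ladder {400, 1,000, 2,000, 5,000, 10,000}
preserves the observed-fraction ladder of panel sizes between 4k and 300k
genome-wide.

Two calibration choices matter and were fixed from first principles:

* **Founder redundancy.**  20 founders are expanded to 100 panel
  haplotypes, so each ancestral segment has ~5 carriers.  Haplotype
  sharing is *the* resource imputation consumes: in a panel where every
  segment has a single carrier, removing the test individual's rows
  removes its segments from the reference entirely, imputation becomes
  impossible in principle, and any confident call is an artifact.  Real
  panels are massively redundant in exactly this sense.
* **Model–generator consistency.**  With mosaic depth $g = 50$ per Morgan
  (~2 cM founder tracks, the LD-block scale at this density), the
  effective rate at which a copyable segment breaks is about $2g$ per
  Morgan — both the target's and the template's mosaics break.  The
  benchmark therefore sets the engine scale so the model's switch
  intensity matches: $4 N_e / k = 2g$, i.e. `ne = 2500` at $k \approx 100$.
  With this pairing the GP score is honest: among imputed sites with GP in
  [0.90, 0.95), empirical accuracy tracks the mean GP of the bin to within
  a few thousandths (asserted in the tests at ±0.05).  A mismatched pair
  is visibly miscalibrated in either direction.

### What the generator does **not** emulate

Mutation, gene conversion, indels and multiallelic sites; realistic
site-frequency spectra with heavy rare tails; recombination hotspots (the
map is constant-rate); genuine coalescent genealogies (relatedness
structure between panel members is only what mosaic sharing induces); and
sequencing-pipeline error models (no read depths or genotype likelihoods —
the error model is the forensic drop-in/drop-out abstraction).  The
two-population scenario is also *harsher* than, say, a EUR/EAS contrast:
the synthetic populations share no haplotype segments at all, only
correlated frequencies, so excluding the focal population degrades
accuracy more dramatically than in real panels.  Passing tests therefore
demonstrate correctness of the machinery and the direction and rough
magnitude of the design effects — not forensic error rates transferable to
casework, which must be estimated against real reference resources.

## Design decisions worth recording

* **Error-rate numerator**: injected observed errors count as erroneous
  assigned genotypes (they are assigned and wrong); a flag
  (`include_observed_errors = FALSE`) restricts the numerator to imputed
  sites for sensitivity analysis.  0/0 is defined as 0 with a warning.
* **Determinism**: every stochastic stage takes a seed; benchmark stages
  derive child seeds from the master seed by a counter-based splitter
  keyed on *cell content* (observed count), so any design cell can be
  re-run in isolation and removing one cell never changes another's
  numbers.  Identical configurations produce byte-identical reports.
* **Extrapolation** is linear in counts and leaves rates untouched; real
  chromosome-to-genome extrapolation carries model error of the order of
  10%, so extrapolated records are labelled as such.
* **Unimputable sites**: target sites absent from the panel are returned
  missing and flagged — alleles not represented in the reference are never
  predicted.  REF/ALT disagreements between target and panel are hard
  errors; allele harmonisation belongs to dedicated tooling upstream.
* **Problem sizes**: the default matrix (5 cells × 10 replicates × 4
  thresholds on 20,000 sites against ~98 reference haplotypes) runs in a
  couple of minutes on one core; the engine itself handles $L = 10^5$,
  $k = 200$ in well under a minute, which the tests exercise.

## A minimal session

```{r example}
library(forensimpute)

cfg <- benchmark_config(seed = 1)
report <- run_benchmark(cfg)
tidy(report)      # median/min/max per design cell x threshold
glance(report)    # one-row run summary
autoplot(report)  # figure-style medians with min-max bars

# error-mode and panel-composition comparisons with matched seeds
run_error_mode_comparison(cfg)
run_panel_comparison(benchmark_config(
  seed = 1, observed_counts = c(1000, 5000), thresholds = 0.95,
  populations = list(n_pops = 2, divergence = 0.1)
))
```

## Known limitations

* The copying model is not the generator: calibration holds at the matched
  default but is not guaranteed for arbitrary user configurations.
* Single-chromosome, biallelic-SNP scope; no windowed processing, so very
  long chromosomes trade memory at $O(\sqrt{L} k^2)$.
* The CLI (`inst/cli/forensimpute`) is a thin convenience wrapper; the R
  API is the primary interface.
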