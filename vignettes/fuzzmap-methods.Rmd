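---
title: "Methods: mapping a recessive multilocus seed-fuzz trait with fuzzmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping a recessive multilocus seed-fuzz trait with fuzzmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzmap)
```

## The problem

Cotton seeds carry two kinds of single-celled seed-coat fibres: long lint,
initiating around the day of anthesis (0 dpa), and short fuzz, initiating
at roughly 3--4 dpa. Some cottons set no fuzz at all ("fuzzless" or naked
seeds), a trait of direct value in ginning. In an interspecific cross
between a fuzzless donor and a normal-fuzz recurrent parent, fuzzlessness
behaves as a *recessive, multilocus* trait: a plant is fuzzless only when
it is homozygous for the donor allele at every required locus, while other
loci modify the quantitative amount of fuzz without gating the trait.

`fuzzmap` implements the full dissection workflow for such a trait:

1. **Segregation analysis** -- which k-recessive-gene Mendelian model fits
   the observed fraction of mutant F2 plants (or F2:F3 families)?
2. **Bulk segregant scanning** -- where in the genome does the
   donor-allele frequency of pooled mutant material depart from
   segregation expectation?
3. **Marker--trait association** -- at a candidate marker, how does mean
   fuzz percentage differ between the three genotype classes, and is the
   donor allele a suppressor, an enhancer, or an additive major factor?
4. **Expression dosage** -- given expression of a duplicated regulator
   (two homoeologs, At and Dt, in an allotetraploid), which seed phenotype
   does a two-threshold dosage model predict?
5. **Simulation** -- a seeded generator of all of the above, so the whole
   chain is testable end to end without any external data.

## Quantitative phenotype and classes

The fuzz phenotype is the *fuzz percentage*,

$$\mathrm{fuzz\%} = 100\cdot\frac{W_\text{ginned} - W_\text{delinted}}{W_\text{ginned}},$$

the weight fraction removed by acid delinting (`fuzz_percentage()`).
Normal-fuzz upland cultivars sit near 10--12%; fuzzless donor-type seeds
are near zero. Visual classes (fuzzless / intermediate / normal) have no
published quantitative boundary, so `classify_fuzz()` uses configurable
cut-offs defaulting to 1.5% and 6%: the lower value separates the
near-zero residual fuzz of true mutants from everything else, the upper
one splits clearly reduced from normal seeds. These are working
conventions, not measured facts, and both are exposed as configuration.

Genotypes are coded as donor-allele dosage halved: donor homozygote 1,
heterozygote 0.5, recurrent homozygote 0 (`encode_genotype()`). The mean
code of a pool is then exactly its donor-allele frequency, which is what
both the array-pool and the sequencing-bulk scans consume. Missing codes
are excluded from every mean, never imputed, and each operation reports
the count actually used.

## Segregation models

Under selfing of a multiply heterozygous F1, a trait requiring donor
homozygosity at $k$ unlinked loci appears in $(1/4)^k$ of F2 plants --
ratios 3:1, 15:1, 63:1 for $k = 1, 2, 3$. `ratio_chisq()` tests observed
mutant counts with the uncorrected two-class Pearson statistic on 1
degree of freedom; no Yates correction is applied, which is what makes
the statistic reproduce published worked examples exactly
(`ratio_chisq(3, 169, 3)` gives $\chi^2 = 0.0497$, $p = 0.8236$;
`ratio_chisq(5, 60, 2)` gives $\chi^2 = 0.4444$, $p = 0.5050$).
`select_model()` sweeps $k$ and reports the best-fitting model, breaking
ties toward the more parsimonious (smaller) $k$. Only the two-class test
is implemented; multi-class ratios are out of scope.

## The sliding-window scan

Pooled variant counts are filtered before scanning
(`filter_pooled_variants()`): a marker survives iff coverage $\ge 10$,
donor-allele reads $\ge 3$ and donor-allele frequency $\ge 35\%$ (all
configurable; indel records are dropped by default). Frequencies are then
smoothed per chromosome with 1 Mb windows advanced by 500 kb
(`sliding_window_frequency()`), each window carrying the *unweighted mean
of per-marker frequencies* -- not a read-pooled ratio -- so deep and
shallow markers contribute equally, matching how array-coded pools are
averaged.

Numerical conventions, chosen once and applied everywhere:

* Windows are anchored at offset 0 of every chromosome and the trailing
  partial window is emitted. Anchoring is a convention (anchoring at the
  first marker would be equally defensible); it is applied identically to
  both bulks, which is what the dual-bulk criterion needs.
* Intervals are 0-based half-open internally and in BED/bedGraph output;
  marker and variant positions are 1-based on input. Conversion happens
  only at the I/O boundary, and a boundary marker test pins the
  half-open membership end to end.
* Windows with no (or too few) markers carry an undefined mean; undefined
  windows never qualify as candidates and break runs of qualifying
  windows.

Candidate regions (`call_candidate_regions()`) need *both* bulks to
behave: the recessive bulk (progeny of fuzzless lines) at or above
`high_threshold = 0.9` -- "fixed or nearly fixed" -- while the
segregating bulk sits inside `segregating_band = [0.35, 0.65]`, the
neighbourhood of the 0.5 expected from selfed progeny of a heterozygous
parent. The band is the package's quantification of "about one half"; it
is deliberately wide enough to absorb binomial sampling at 30x coverage
on window means of a handful of markers, and narrow enough to reject
regions where donor alleles merely drifted to fixation during inbreeding
(those show high frequency in *both* bulks). At least
`min_consecutive = 2` adjacent qualifying windows are required, and
qualifying runs merge into one region. The array-pool analogue
(`call_array_candidates()`) asks the reduced-fuzz pool to be $\ge 0.9$
and the normal-fuzz pool to be $< 0.5$. `intersect_region_sets()`
intersects the two evidence routes; loci found by both are the strongest
candidates.

## Marker--trait association

`group_phenotype_by_genotype()` partitions plants by the three codes;
`marker_trait_test()` runs two-sided two-sample Student's t-tests with
pooled variance (the classical test; Welch's correction is available
behind a flag) for donor-vs-recurrent homozygotes and heterozygote
vs each homozygote. Contrasts with fewer than `min_group_size = 3`
observations on either side are reported untestable rather than failing.
No multiple-testing correction is applied by default, matching per-marker
reporting practice in this design; `p.adjust` on the output columns is a
one-liner for users who want it.

`classify_locus_effect()` turns the contrast pattern into a call:
*suppressor* (donor homozygotes significantly lower), *enhancer*
(significantly higher), *additive_major* (suppressor or enhancer whose
heterozygote mean lies strictly between the homozygote means and differs
significantly from both), else *none*. Strict betweenness -- rather than
a formal midpoint test -- is used because the biological claim being
encoded is only "intermediate".

## Expression dosage

For a duplicated regulator whose At copy cannot be assayed specifically,
`at_by_subtraction()` computes At = total − Dt, clamping small negative
differences (within 5% of total) to zero as measurement noise and
rejecting larger excesses as inconsistent. `homoeolog_proportions()`
reports per-timepoint shares. Expression values are relative quantities
in any consistent units; a ΔCt convertor (`ct_to_relative()`, perfect
doubling assumed) is provided, and per-primer efficiency correction is
deliberately not applied.

`dosage_classify()` encodes the two-threshold working model of fibre
initiation: total expression below threshold 2 at ~0 dpa means no lint
(*fibreless*); otherwise Dt expression below threshold 1 at ~3 dpa means
no fuzz (*fuzzless_linted*); otherwise *fuzzy_linted*. The thresholds'
magnitudes are unknown -- only the qualitative mapping is testable -- so
both are required user parameters. The fourth logical cell, lintless but
fuzzy, is intentionally unreachable (no such mutant has ever been
reported) and a unit test asserts the classifier can never emit it.

## The simulator

`sim_genome()` defaults to 26 chromosomes of 60 Mb with one marker per
250 kb (6240 markers, the order of magnitude of a polymorphic SNP-array
set), and a constant map of 1 cM/Mb under the Haldane model: crossover
counts Poisson in the chromosome's genetic length, positions uniform, no
interference. This is the simplest map consistent with what the analysis
assumes; real marker maps are irregular and real recombination is not
uniform, so window marker counts in real data vary more than simulated
ones do.

`ps_causal_model()` plants five loci on five chromosomes:

| locus | role | effect (fuzz-% points) |
|---|---|---|
| I (A08) | enhancer | +3 when donor-homozygous |
| II (A10) | additive modifier | −1.5 per donor copy |
| III (D07) | required recessive | 0 |
| IV (D11) | required recessive | 0 |
| V (D12) | required recessive + additive major | −2.5 per donor copy |

Three required loci give the 63:1 F2 expectation; locus V doubles as the
additive major locus (heterozygotes intermediate), locus I increases fuzz
when donor-homozygous (so transgressive segregants above the recurrent
baseline occur), and locus II is a weaker modifier. Baseline fuzz is 11%
(a normal-fuzz cultivar), phenotype noise SD 1.5, penetrance 1 by
default (sub-unity penetrance is available to emulate incompletely
fuzzless families). Fuzzless individuals draw residual fuzz from
$|N(0.7, 0.4)|$, anchored to the low end of fuzz measured on fuzzless
donor-type accessions; with the 1.5% class cut-off this classifies 97.7%
of true mutants as fuzzless, i.e. the simulator deliberately reproduces
the slight scoring ambiguity of a continuous phenotype. A side effect
worth knowing: plants homozygous donor at loci II and V but not at all
required loci average ~3% fuzz and occasionally score below the fuzzless
cut-off, slightly inflating observed mutant counts -- much as visual
scoring of a continuous gradation does.

`simulate_f2()` selfs the fully heterozygous F1. `simulate_nil_lines()`
emulates near-isogenic line development: four backcrosses to the
recurrent parent with marker-assisted retention of at least one donor
allele at every causal locus, then five selfing generations during which
fuzzless lines are driven to donor homozygosity at every causal locus
and segregating lines are kept heterozygous. Marker-assisted selection
stands in for the phenotypic selection used in real programmes; it is
reproducible and reaches the same endpoint. Bulks (`build_bulk()`)
default to 15 fuzzless-class progeny (recessive bulk) and 24 progeny of
segregating lines (segregating bulk). Drawing progeny from *several
independent* lines (defaults: 6 fuzzless, 4 segregating) matters: a
single inbred line fixes donor alleles at random background loci, and
only pooling across lines keeps such fixation from mimicking a candidate
region -- the false-positive mode the dual-bulk criterion is designed
against.

`simulate_pool_counts()` sequences a bulk in silico: per-marker coverage
Poisson(depth, default 30), donor reads binomial with success probability
$p(1-e) + (1-p)e$ where $p$ is the bulk's true frequency and $e$ a
per-read error rate (default 0). No read-level artifacts (mapping bias,
base quality, duplicates) are modelled; passing tests therefore
demonstrate the statistical logic of the pipeline, not robustness to
alignment pathologies.

All generators are deterministic given a seed.

## Problem sizes used in the test suite

The shipped tests run the full study stand-in at its native scale -- 26
chromosomes, an F2 of 169, bulks of 24/15 at 30x, three fixed seeds
(1, 2, 3, chosen up front) -- which completes in well under a minute per
seed; success is defined as candidate regions overlapping at least 4 of
the 5 planted loci with none on unplanted chromosomes, in at least 2 of
the 3 seeds. Distributional checks (Haldane recombination fractions,
1:2:1 segregation, binomial pool counts) use 4,000--10,000 draws with
roughly four-standard-deviation tolerances; oracle-equivalence checks
sweep 200 randomized chromosomes against a brute-force window scan and
every two-class outcome at $n \le 12$ against `chisq.test`.

## Worked example

```{r example, eval = FALSE}
# published-style worked values
ratio_chisq(3, 169, k = 3)   # chi^2 = 0.0497, p = 0.8236 (63:1 model)
select_model(5, 60, 1:4)$best_k  # 2 (15:1 model)

# an end-to-end simulated study
res <- run_pipeline(default_config(seed = 7), out_dir = "fuzzmap_run")
res$regions_mbs      # candidate regions from the dual-bulk scan
res$recovery         # which planted loci were recovered
res$segregation$best_k
```

## Known limitations

* The scan carries no confidence statement on window frequencies; the
  dual-bulk thresholds are decision rules, not tests.
* Marker maps are trusted as given; misplaced markers (a known hazard of
  array annotations) must be curated upstream.
* The phenotype model has no environmental term, though fuzz expression
  is known to respond to environment; `noise_sd` absorbs all
  non-genetic variance.
* The expression module summarizes replicates but does not test
  expression differences; its thresholds are user-supplied.
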