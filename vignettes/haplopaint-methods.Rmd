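---
title: "Models and methods behind haplopaint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind haplopaint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`haplopaint` analyses panels of inbred, effectively homozygous crop lines
genotyped at biallelic SNPs. This vignette is the package's account of the
models it implements, the tunable parameters that matter, the choices made
where the design was genuinely open, and what the synthetic-data tests do
and do not establish.

## The haploid representation

Every line contributes **one haploid allele copy** per SNP. Cultivars of a
selfing crop are near-homozygous, so a diploid representation would add no
information while complicating every estimator; heterozygous calls (e.g.
residual heterozygosity or clustering artefacts in VCF input) are set
missing at import and reported. All statistics below — Fst, AMOVA,
haplotype windows, r², the copying model — use this haploid coding
consistently.

## The copying-model HMM

A recipient haplotype is modelled as an imperfect mosaic of the donor
panel's haplotypes (the Li–Stephens approximate-coalescent view). The
hidden state at SNP *s* is the donor haplotype being copied. With `d` cM
between adjacent SNPs:

* **transition**: stay on the current haplotype with probability
  `exp(−ρ d)`; otherwise redraw a haplotype `j` with probability
  `f_pop(j) / n_pop(j)`, where `f` are per-subpopulation copying
  proportions (summing to 1) and `n_pop` the panel counts. A redraw may
  land on the same haplotype.
* **emission**: probability `1 − θ` when the donor allele matches the
  recipient call, `θ` on a mismatch; missing recipient calls are
  uninformative (likelihood 1 for every state); a missing donor allele
  emits 0.5.

Defaults: `ρ = 0.1`/cM, and a Watterson-style miscopy rate
`θ = w / (2(H + w))` with `w = 1/Σ_{i<H} 1/i` for `H` donor haplotypes
(≈ 0.002 for panels of a few dozen haplotypes). Both are overridable; ρ
and θ are deliberately *not* EM-updated by default because with a single
haploid observation per recipient they are weakly identified and trade off
against each other, whereas the copying proportions `f` are the quantity
of scientific interest.

Chromosomes are independent HMM instances. All recursions are rescaled
per site, so likelihoods are finite for any panel; forward, backward and
path sampling are implemented in C++.

### EM for copying proportions

`fit_em()` runs exactly `n_em_steps` (default 20) iterations. The E-step
is forward–backward for every recipient and chromosome. For the M-step the
complete-data log-likelihood term involving `f` is
`Σ_events log(f_pop(j)/n_pop(j))` over the *choice events* — the initial
state and every redraw. Its maximiser sets `f_k` proportional to the
expected number of choice events targeting subpopulation `k`, which the
E-step computes exactly from the scaled forward/backward quantities. This
is a genuine EM step, so the total log-likelihood is non-decreasing across
iterations — a contract the test suite asserts on every fixture. (The
looser alternative of updating `f_k` to the expected *copied-site*
fraction is not the Q-maximiser and cannot guarantee monotonicity; the two
updates agree closely in practice because segments are long.)

### Replicates and consensus

Painting replicates are independent full state paths drawn by stochastic
backward sampling from the forward recursion — exact draws from the path
posterior, so replicate variation reflects genuine posterior uncertainty
(given one fixed EM fit, replicate variation from EM restarts would be
negligible and would not vary per-SNP assignments meaningfully). Per SNP,
the replicate donor-subpopulation labels are accumulated into counts; the
**consensus** ancestor is the modal subpopulation of the (default 100)
replicates, with ties broken toward the smallest subpopulation id and
flagged. Summaries weight all SNPs equally (not by cM) — a convention, and
the reason per-chromosome SNP density should be reasonably even.

### Deviant regions

Given a group's per-locus profile (fraction of recipients assigned to each
donor at each SNP), a locus is *deviant* when the focal donor's fraction
drops below `dominance_frac` (default 0.5); maximal runs of at least
`min_snps` (default 3) consecutive deviant loci become regions, annotated
with every subpopulation whose mean in-region fraction exceeds 0.2. The
run-length threshold suppresses single-SNP noise; the detection floor is
set by SNP spacing — blocks shorter than a few inter-SNP distances cannot
be resolved, and consensus accuracy degrades once true segment lengths
fall below the map's SNP spacing.

## Differentiation statistics

**Weir–Cockerham Fst (haploid).** Per locus, a one-way ANOVA on the allele
indicators gives mean squares among (`MSA`) and within (`MSW`)
populations; with the unequal-size coefficient
`n_c = (N − Σn_i²/N)/(r−1)`, the components are `a = (MSA − MSW)/n_c`
(among) and `b = MSW` (within), combined across loci as `Σa / Σ(a+b)`.
Because the estimator subtracts the within-population sampling
expectation, it is unbiased around zero and **can be negative**; negative
estimates are reported as computed, not truncated. In particular, two
populations with *identical* genotype matrices yield a small deterministic
negative value (≈ −1/(n_c−1) scaled), not exactly zero — the price of
unbiasedness. Monomorphic loci contribute nothing.

**AMOVA.** Squared Euclidean allele-difference distances (pairwise-complete,
rescaled to the locus count) are partitioned over the nested design
region > subpopulation > within; variance components follow the standard
nested ANOVA expectations with unequal-size coefficients, percentages sum
to 100, and p-values come from permutation (samples among subpopulations;
for the region component, a whole-design shuffle). Defaults: 999
permutations, with the +1-corrected empirical p.

**Nei distance.** The 1972 standard distance
`D = −ln(J_xy/√(J_x J_y))` with gene identities averaged over loci is the
default (matching the common toolchain default); the 1978 small-sample
variant is an option. A pair fixed for opposite alleles everywhere has
`J_xy = 0` and infinite distance, reported as the capped sentinel
`−log(.Machine$double.xmin)` with a flag so neighbour joining still runs.

## Diversity, LD and effective size

Sliding 15-SNP windows (step 1; the default window matches one SNP per
~1.3 cM maps where LD blocks span ~20 cM) yield haplotype frequency
spectra; `HHe = 1 − Σpᵢ²` and `HAe = 1/Σpᵢ²` satisfy `HAe = 1/(1−HHe)`
exactly. Samples with any missing call in a window are dropped from that
window only — in the default pipeline imputation runs first, making this
moot.

`r²` is the squared correlation of allele indicators over
pairwise-complete samples (equivalently `D²/(p_A p_a p_B p_b)`), requiring
at least 10 shared samples. The **background threshold** is the empirical
99th percentile (R's type-7, linear-interpolation quantile — the rule is
fixed and tested) of inter-chromosomal r²; inter-chromosomal pair
enumeration is capped (default 10⁶, seeded subsampling) because the full
cross-product is quadratic and statistically unnecessary. **Block size**
is where the binned mean-r² decay curve (1-cM bins, centred 3-bin moving
average) first drops below the threshold, linearly interpolated between
bin midpoints; curves already below threshold report 0 and curves that
never cross report the maximum distance, both flagged. Bin width and
smoother are exposed because "block size" has no canonical definition.

**LD-based Nₑ** inverts the drift expectation `E[r²] ≈ 1/(3Nₑ) + 1/S`
(random mating, S haploid copies): `Nₑ = 1/(3(r̄² − 1/S))`, flagged
infinite when the observed mean r² does not exceed the sampling term. A
second mode applies the Waples (2006) second-order sampling correction
(`1/S + 3.19/S²`) with the quadratic inversion
`Nₑ = (1/3 + √(1/9 − 2.76 r²'))/(2 r²')`; both modes are provided because
the upstream tooling's exact settings are not documented. When a map is
available, intra-chromosomal pairs closer than 50 cM are excluded (the
method assumes unlinked loci). Note that duplicating every sample changes
the estimate only through `S` — the estimator sees sample size, not
information content.

## Donor-panel curation and its null

Reducing a worldwide panel to differentiated geographic subpopulations is
inherently judgement-laden; `curate_donors()` makes it auditable with four
passes over a clustering of the allele-difference distances: (1) cut into
`k` clusters (default: the number of subpopulations) — implemented as
average-linkage hierarchical clustering on the same distances the NJ tree
is drawn from, because an unrooted NJ tree has no canonical height cut;
(2) remove clusters whose majority-subpopulation fraction is below 0.6
(*admixed_cluster*); (3) keep each subpopulation's largest core cluster
(*outlier_accession* otherwise); (4) remove accessions whose 5 nearest
neighbours are majority-foreign (*foreign_cluster*). Every removal carries
its reason; a subpopulation that would drop below 8 members is retained
unfiltered with a warning. All thresholds are configuration.

The **resampling null** asks whether the curated panel's higher average
pairwise Fst is an artefact of smaller size: each replicate draws, within
each subpopulation, a random subset of the curated size and records the
average pairwise Fst; with target sizes equal to the full sizes every
replicate equals the full panel (SD exactly 0). The empirical p uses the
+1 correction — 100 replicates cannot produce p = 0 — and a
normal-approximation p from the null mean ± SD is reported alongside.

## The synthetic world

`simulate_donor_pops()` draws ancestral frequencies `p ~ U(0.05, 0.95)`
and Balding–Nichols subpopulation frequencies
`Beta(p(1−F)/F, (1−p)(1−F)/F)`, so `F` is the design Fst. Founder
haplotypes are drawn site-wise and then mixed for `g` (default 20)
generations — random pairing with **two complementary recombinant
offspring per pair**, which preserves per-locus allele counts exactly.
This choice matters: literal finite-population random mating would add
≈ `1 − (1 − 1/n)^g` of drift differentiation (≈ 0.4 for n = 40, g = 20)
on top of the design F, destroying the generator's only calibrated
property. The price is that mixing creates haplotype *mosaics* but no
excess allele-frequency drift.

Two consequences are documented rather than hidden. First, with founders
drawn site-wise independently, within-subpopulation loci are at linkage
equilibrium — fine for Fst/painting tests (recipients copy actual donor
haplotypes, so exact matches exist in the panel), but a world in which
LD-based imputation has nothing to work with. The `n_founders` knob
(default `n_per_pop`, i.e. the behaviour above) draws fewer distinct
founders and resamples them with replacement, creating the within-
population LD and haplotype sharing of real breeding panels; the
imputation accuracy test runs in such a world (6 founders, 4 SNPs/cM), and
mean window HHe rises monotonically with founder count. Second, the
generator emulates frequency differentiation and mosaic structure only —
not ascertainment bias, genotyping-batch effects, pedigree loops or
selection — so a green painting test establishes that the method recovers
ancestry *when the donor panel truly contains the ancestors*, the known
failure mode of real panels being precisely the pseudo-ancestry that
cleaner painting addresses.

`simulate_mosaic_recipients()` tiles each chromosome with segments whose
breakpoints are Poisson with the given rate per cM, copies one donor
haplotype per segment (subpopulation drawn by the target weights), applies
per-site miscopy noise ε = 0.002 (mimicking genotyping error without
swamping signal), and records segments, per-recipient cM proportions and
the true donor of every SNP. `simulate_wright_fisher()` runs a monoecious
diploid population of the stated size with free recombination between
unlinked loci; 50 generations suffice for unlinked-locus LD to reach its
drift equilibrium (it decays by half per generation).

## Period assignment

Recipient release years map to three breeding periods via two cut years
(defaults 1920 and 1970), **left-inclusive**: 1920 → period 1, 1970 →
period 2. The source phrasing ("pre X" / "from X+1") motivates the
inclusive-left convention, but since the boundary year's side is not
explicitly stated, the bounds are configuration (`period_bounds()`).

## Numerical conventions

* Scaled HMM recursions; any underflow raises an error rather than
  returning non-finite likelihoods.
* Consensus ties → smallest subpopulation id, flagged.
* Nei infinite distances → capped sentinel, flagged.
* Negative NJ branch lengths clamped to zero after tree construction.
* Intensity calling: per-axis SD-standardised Euclidean distance; ties
  (within 1e-9) and outliers beyond `max_z = 4` SD → missing. The
  tie/outlier rules are this package's operationalisation — the upstream
  custom caller's rules are unpublished — and are exposed as arguments.
* Missingness (> 0.5) and MAF (< 0.05) filters are strict inequalities, so
  boundary SNPs are kept.
* All simulators and the painting replicates are bit-reproducible given
  their seed; pipeline tables are stamped with a config hash and seed, and
  reruns are byte-identical.

## Known limitations

* Haploid-only: no phasing, no diploid/polyploid painting, no
  multi-allelic sites.
* The EM fits `f` only; ρ and θ are fixed defaults unless overridden.
* AMOVA region-component permutation uses a whole-design shuffle rather
  than restricted permutation of subpopulations among regions.
* Group ancestry profiles weight SNPs and recipients equally; no
  cM-weighting option yet.
* Admixture-date estimation and coancestry-matrix clustering are out of
  scope.
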