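---
title: "Quantifying restriction-modification defence against plasmid conjugation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying restriction-modification defence against plasmid conjugation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmconj)
```

## The problem

Restriction–modification (RM) systems pair a restriction endonuclease with a
DNA methyltransferase sharing one recognition sequence. Host DNA is
methylated at those sites; incoming DNA — for instance a conjugative plasmid
entering a recipient cell — is not, and is cleaved. How strong that barrier
is in practice depends on the plasmid (how many sites it carries, whether it
encodes methylases or anti-restriction genes) and on the RM system's
mechanistic type. `rmconj` implements the quantitative machinery needed to
measure this: site counting on plasmid sequences, compositional null models
for site avoidance, estimation of conjugative transfer and restriction
efficiencies from colony counts, regression of defence strength on site
numbers, and a simulator of the whole experiment.

## Recognition sites and the duplex convention

Recognition sequences are IUPAC strings: `GAATTC` (EcoRI, Type II),
`CCWGG` (EcoRII, Type II, W = A/T), `AGACC` (EcoP1, Type III, asymmetric),
or bipartite Type I sites such as `AACNNNNNNGTGC` (EcoKI) whose N spacer is
kept inline so the scanner is a single-pattern matcher. Matching uses
`Biostrings::matchPattern(fixed = FALSE)`; in the default lenient mode an
ambiguity code in the genome matches any compatible base (base sets must
intersect), while strict mode rejects non-A/C/G/T input outright.

Two conventions matter and are easy to get subtly wrong:

* **Topology.** Plasmids are circular; a site can span the sequence origin.
  `scan_strand()` appends the first `|motif| - 1` bases before matching and
  reports starts modulo the length, so counts are invariant under rotation
  of the deposited sequence. All positions are 1-based.
* **Duplex counting.** A degenerate-palindromic motif (equal to its IUPAC
  reverse complement) occupies the same duplex position on both strands, so
  it is counted on the forward strand only; an asymmetric motif (all Type I
  and III sites here) is counted on both strands, as forward matches of the
  motif plus forward matches of its reverse complement. Published site
  counts rarely state their convention, so `count_sites(duplex =)` exposes
  `"both"` and `"forward"` overrides; `"auto"` (the palindromy rule) is the
  default. Overlapping matches are all counted — each is an independently
  cleavable or methylatable site.

The scanner is validated against an independently written brute-force
matcher (position-by-position IUPAC set intersection, and rotation-by-
rotation prefix matching for circles) on hundreds of random sequence/motif
pairs in the test suite.

## Expected site counts and avoidance

Mobile elements tend to carry fewer Type II sites than chance predicts. The
null model is zero order by default: strand-symmetric base probabilities
p(G) = p(C) = gc/2, p(A) = p(T) = (1 − gc)/2 built from the plasmid's own
GC fraction. A motif's match probability is the product over positions of
the summed probabilities of the allowed bases (N contributes 1), and

> expected count = (scanned positions) × (match probability) × (1 or 2 strands)

with positions = L on a circle, L − k + 1 on a line, and the doubling
applied exactly when the scanner counts both strands, so observed and
expected are always on the same scale. A first-order (dinucleotide Markov)
option exists for sensitivity analysis but is not the default, because the
stated comparison is against size and GC content alone. Avoidance is
reported as the ratio observed/expected together with the lower-tail
Poisson probability P(X ≤ observed). The Poisson form ignores the slight
variance inflation from motif self-overlap; for 5–15 nt sites at
expectations of order 1–10 this is negligible relative to sampling noise.

## Transfer and restriction efficiency

The end-point transfer-efficiency estimator is

> γ (ml/cell/h) = T / (D · R · t)

with T, D, R the transconjugant, donor and recipient densities (cells/ml)
recovered from plate counts (colonies × dilution / plated volume) and t the
mating time in hours. It assumes densities are roughly constant over the
mating — the simulator makes the same assumption so recovery tests are
clean; growth-corrected dynamic estimators are out of scope.

**Censoring.** When no transconjugant colony appears, γ is not zero but
below detection. The detection threshold substitutes 0.5 colonies on the
lowest-dilution plate actually screened, so assay records for zero counts
must carry that plate's dilution and volume. Threshold estimates are
flagged `censored = TRUE`, propagate to any ratio built from them, and are
included in summaries by default (an option drops them). Note the
threshold rises as plating gets coarser — a smaller plated volume can only
raise, never lower, the censored γ.

**Restriction efficiency.** RE compares the same donor/plasmid toward a
recipient with and without the RM system. Replicates are paired by sorted
replicate index (pairing is arbitrary but fixed; unpaired extras are
dropped with a warning) and the package reports the fold restriction

> re_fold = γ(RM−) / γ(RM+)

so that larger values mean stronger defence and re_fold = 1 means none;
the reciprocal raw ratio is retained alongside. Group summaries use the
geometric mean (the natural average of fold ratios), plus median,
arithmetic mean, n, and the censored fraction.

## Linear models

All inference runs on log10-transformed quantities. The regression table
joins per-replicate REs to site counts; a site count of zero is replaced by
0.5 before the log so those combinations stay in the model. Models are
ordinary least squares with sequential (type-I) F tests — term order
follows the formula, matching how `anova(lm(...))` constructs the printed
statistics. `fit_re_model()` refuses rank-deficient designs by default and
names the aliased coefficients; `allow_aliased = TRUE` lets `lm()` drop
redundant columns, which is required for the saturated formula
`log10_re ~ rm_system * log10_nsites + rm_system * plasmid_id`, where the
site count is a deterministic function of the plasmid × RM cell and some
interaction columns are necessarily redundant.

Mutant screens are two-stage: a gate model
`log10_re ~ [experiment +] mutant * rm_system` must show a significant
mutant:RM interaction (P < 0.05) before any per-cell contrast is reported.
Contrasts are unpaired two-sided t-tests on log10 RE (Welch by default; a
pooled-variance option exists because the choice is rarely stated in
published work), with the Bonferroni family size set explicitly to
(number of RM systems) × (number of mutants tested) — deliberately counting
planned tests, not computed ones. Zero-variance cells take the analytic
limit (t = 0, p = 1 for identical samples; p = 0 under complete
separation), and cells with fewer than two replicates are reported missing
rather than silently skipped.

## The simulator

`generate_sequence()` draws i.i.d. bases at a target GC, scrubs every
spontaneous duplex occurrence of the controlled motifs by local resampling,
plants the requested copy numbers at random non-overlapping positions, and
verifies the final counts with the package's own scanner, retrying
(bounded) if planting created junction artefacts. `simulate_assay()` puts
Poisson noise where the experiment has it — every plate of the dilution
series receives a Poisson(density × volume / dilution) count, for
transconjugants, donors and recipients alike — and picks the counted plate
the way a practitioner does (the least-diluted plate with at most 300
colonies). `simulate_study()` ties these together: an RM-free control arm
per plasmid plus one arm per RM system.

Restriction enters as multiplicative per-site escape: a plasmid with n
unmethylated sites escapes with probability p_escape^n, so ground truth is
log10(RE) = n × (−log10 p_escape) and a regression of log10 RE on n should
recover that slope. An alternative `link = "log_sites"` makes log10 RE
linear in log10(n) instead (zeros again replaced by 0.5), matching the
empirical regressions used on real data, where the mechanistic link cannot
be assumed. Defaults emulate realistic study conditions: γ = 10⁻¹¹
ml/cell/h (the upper end of the observed 10⁻¹¹–10⁻¹⁶ range, so that
strongly restricted arms stay above the detection limit), donor and
recipient densities 10⁹ cells/ml, 4 h mating, 4 replicates, eight-step
tenfold dilution series, 0.1 ml plated. All randomness flows from one seed;
a fixed seed reproduces a study byte-for-byte, including its written
fixture files.

What the simulator does **not** emulate: growth and donor/recipient
dynamics during mating, overdispersed plating (a negative-binomial switch
would be the first robustness extension), methylation inheritance,
anti-restriction gene action, or plasmid fitness effects. Passing recovery
tests therefore show the estimators and models are correct under their own
assumptions — not that real mating assays meet those assumptions.

## Validation studies and numerical choices

The package validates itself at these problem sizes (chosen to give each
check sharp power while keeping the whole suite quick to run):

* scanner vs brute force on 200 random pairs (sequences ≤ 2 kb, motifs up
  to ~15 nt including N spacers);
* closed-form check that a palindromic 6-mer on a circular uniform 4096-bp
  sequence has expectation exactly 1.0, with a 500-sequence Monte-Carlo
  mean within 3 standard errors;
* exact γ arithmetic (γ = 10⁻¹² for T = 4×10⁴, D = R = 10⁸, t = 4;
  censored γ = 1.25×10⁻¹⁵ for a zero count on an undiluted 0.01-ml plate);
* slope recovery over 100 seeded studies (5 plasmids, n_sites 0–16,
  p_escape = 0.5): the 95% CI covers log10 2 in ≥ 93 of 100;
* calibration over 1000 null studies (p_escape = 1): RM-effect p-values
  uniform by Kolmogorov–Smirnov.

One design point deserves emphasis. In a real study every RM arm of a
plasmid is compared against the *same* control replicates, so per-replicate
REs are positively correlated within plasmids, and a one-way F test across
RM systems that ignores this is anticonservative — we measured its null
p-values as clearly non-uniform. The calibration study therefore gives each
simulated plasmid a single RM arm, which isolates the estimator itself;
analyses of real shared-control designs should treat per-plasmid
correlation explicitly (e.g. by modelling plasmid as a factor, as the
saturated formula does) rather than trusting marginal per-replicate tests.

Other numerical choices: expected counts are reported unrounded (round only
for display); ties in replicate pairing cannot arise because replicate
indices are unique within an arm; motif validation happens at every entry
point so invalid IUPAC letters fail fast with positions named; and the
shipped ten-enzyme catalog (`rm_enzyme_catalog()`) is data, loadable and
replaceable via `parse_enzyme_table()`, not constants baked into code.

## Limitations

* The γ estimator is the end-point formula; it is biased when densities
  change appreciably during mating.
* Censored REs are treated as values in summaries (flagged, excludable);
  no Tobit-style censoring-aware likelihood is provided.
* The Poisson null for site counts ignores overlap clumping.
* Reproducing the published per-plasmid numbers for the original 13-plasmid
  collection requires the deposited sequences and supplementary
  per-replicate data, which are not redistributable with the package; the
  corresponding checks run only when those files are supplied locally.
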