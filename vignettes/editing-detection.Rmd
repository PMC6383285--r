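---
title: "Detecting stress-induced site-specific C-to-U RNA editing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting stress-induced site-specific C-to-U RNA editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apoedit)
```

## The problem

APOBEC3 cytidine deaminases — A3G in particular, the dominant family member
in NK and cytotoxic T cells — can deaminate cytidines in cellular mRNA,
producing site-specific C-to-U edits that appear in RNA-seq as C>T (plus
strand) or G>A (minus strand) DNA–RNA mismatches. Such editing is
essentially absent in unstressed cells but is induced by cellular crowding
combined with hypoxia (about 1% O2). The analytical challenge is to separate
genuine condition-responsive editing from three confounders that produce
the same mismatch signal: unannotated genomic variants (alt fractions near
50% or 100% in every sample), low-level sequencing/alignment noise (alt
fractions of a few percent), and constitutive editing that does not respond
to the condition.

`apoedit` implements the full detection cascade for a paired
normoxia/hypoxia design, together with the enrichment statistics used to
validate the calls, Sanger peak-height quantification for targeted
confirmation, and a synthetic-data generator that reproduces the design so
that every stage is testable end to end without access to raw sequencing
data.

## The statistical model

At each candidate site, every sample contributes a pair of read counts
(`ref_count`, `alt_count`). The per-sample editing level is
`alt / (ref + alt)`. Alternate-base counts are modeled as binomial, and the
condition effect is estimated by binomial logistic regression with donor
fixed effects:

logit p(donor d, condition c) = beta0 + gamma_d + beta1 * [c = hypoxia]

`beta1` is the within-donor log odds ratio of editing in hypoxia versus
normoxia; the reference donor is absorbed into the intercept. Each site's
two-sided p-value comes from a Wald test on `beta1` (a likelihood-ratio
test is available with `test = "lrt"`). Benjamini–Hochberg adjustment is
applied across the whole family of tested sites, and a site is called
`hypoxia_higher` when `beta1 > 0` and `q < 0.05` (strict), symmetrically
`normoxia_higher` for `beta1 < 0`.

Three modeling choices here were genuinely open, and we fixed them as
follows:

* **Pairing as donor fixed effects.** "Paired samples" could mean donor
  covariates, conditional logistic pairing, or nothing beyond sample
  matching. Fixed effects are the simplest model in which `beta1` is a
  within-donor contrast, and with three donors there is no basis for
  estimating a random-intercept variance; a mixed model is deliberately out
  of scope.
* **Wald by default.** The Wald and LRT p-values agree closely at the read
  depths where sites survive the prevalence filter; Wald is reported by
  default because it comes with a standard error that downstream consumers
  can use directly.
* **Joint FDR family.** C>U and A>I events are adjusted together in one BH
  family per run; `family = "per_class"` switches to separate families.
  With one experiment and one hypothesis per site, a single family is the
  conservative, reproducible default.

**Separation.** When the condition-collapsed 2×2 table (alt/ref by
condition) contains a zero cell, the binomial MLE for `beta1` is infinite.
We then add 0.5 to each collapsed cell (Haldane–Anscombe), report the
corrected log OR with its asymptotic standard error
`sqrt(sum(1/cell))`, and flag the result `"haldane"`. This is
deterministic and conservative; Firth regression would be the main
alternative but adds nothing at the depths involved. Donor effects are not
estimable in the separated regime anyway, so the collapsed-table fallback
loses nothing.

## The filter cascade

Stages run in a fixed order, and each stage's output is checked to be a
subset of its input:

1. **Canonical classes.** Only C>T/G>A (C2U) and A>G/T>C (A2I) mismatches
   are kept.
2. **Known-SNP blacklist.** Sites whose (chrom, pos, ref, alt) key appears
   in the supplied blacklist (e.g. a dbSNP export) are removed *before*
   statistical filtering, matching the stated order of the original
   protocol.
3. **Prevalence.** A site must reach at least 5% editing level in at least
   one sample (inclusive ≥; zero-coverage samples are ignored).
4. **GLM + FDR + direction** as above.
5. **−1 dinucleotide (C>U only).** The base immediately 5' of the edited C
   on the edited strand must be C or T — the pyrimidine-C dinucleotide
   context of APOBEC3 substrates (A3G prefers CC, the others TC). An N at
   −1 fails, conservatively.
6. **Stem-loop + exon/UTR (C>U only).** The site must be annotated exonic
   or UTR and its edited C must qualify under the structural predicate
   below. A>I events stop after stage 4; their RADAR cross-reference is a
   reporting step, not a filter.

Minus-strand events are reverse-complemented to the edited strand before
stages 5–6, so all sequence logic sees a C-centered window.

## The stem-loop predicate

The structural filter formalizes, as a deterministic rule, a criterion
that was originally applied by manual curation: the edited C must sit at
the 3' end of a tri- or tetra-loop closed by a stem of at least 2
Watson–Crick base pairs when complementarity is perfect, or at least 4
pair positions when it is imperfect by exactly one single-base mismatch or
one single-base bulge on one arm.

With the edited base at window center `e` and loop length `L` in {3, 4},
the loop is `window[e-L+1 .. e]` and pair `i` pairs `window[e-L-i+1]` with
`window[e+i]`, a bulge shifting one arm outward by one for all later
pairs. Conventions the prose rule leaves open were fixed once:

* The loop-closing pair must be a true pair — a mismatch there would
  enlarge the loop and change `L`.
* The outermost counted pair must be a true pair — a terminal defect does
  not extend a stem. Defects are therefore strictly interior (mismatch
  offset 2..s−1; bulge strictly between counted pairs).
* At most one defect in total.
* G:T (G:U in RNA) wobble pairs are **not** complementary by default,
  reading "base complementarity" strictly; `wobble = TRUE` relaxes this.
* Any pair involving N is non-complementary.

When several geometries qualify the reported call follows a documented
preference order (perfect before defective; loop 3 before 4; longer stems
first; mismatch before bulge; smaller offset; 5' bulge first) — the
*qualifies* decision never depends on this order, only the reported
geometry does. `enumerate_structures()` is an independent brute-force
enumeration of every candidate geometry, validated pair-by-pair; the test
suite checks predicate/oracle agreement on tens of thousands of random
windows. Because a curated list and this formal rule can disagree at the
margins (wobble pairs, terminal defects), `manual_filters()` reports
per-site disagreements against an expected list rather than silently
reconciling them.

## Enrichment statistics

`chi2_2x2()` is the Pearson test without continuity correction — the
uncorrected statistic is what reproduces the published mismatch-class
p-value of 0.000183, and the Yates-corrected version does not.
`fisher_exact_2x2()` uses the two-sided point-probability rule (sum all
margin-fixed tables at most as probable as the observed one), with a
central doubled-one-tail option. `retention_test()` builds the 2×2 table
comparing the composition of a retained site set against its pre-filter
superset; the rows overlap by construction, which mirrors the published
computation and is labeled in the output. `pearson_corr()` is the sample
correlation with a two-sided t-test.

## Sanger quantification

Editing level from chromatogram peaks is `minor / (major + minor)`. The
base-calling software only reports a minor peak when it is at least 5% of
the major peak, so the implied detection threshold on the level scale is
5/105 ≈ 0.048; the boundary case counts as detected. Peak heights arrive
as a CSV (trace parsing is out of scope); rows with minor > major are
swapped with a warning.

## What the synthetic generator emulates

`synth_dataset()` reproduces the design the statistics assume: 3 donors ×
2 conditions, read depth uniform on 20–200 per site and sample, and six
truth classes. Defaults were chosen once to match the study conditions or,
where unstated, a realistic value, and are not tuned:

| parameter | default | rationale |
|---|---|---|
| `n_donors` | 3 | the study's paired cohort size |
| `depth_range` | 20–200 | typical exome-capture RNA-seq site coverage |
| `baseline_logit` | logit(0.02) | low constitutive editing in normoxia |
| `effect_logit` | +2.0 | lifts 2% baseline to ~10–30%, the observed stressed range |
| `donor_sd` | 0.3 | donor-to-donor spread; free parameter, no published value exists |
| `planted_stemloop_frac` | 1.0 | edited sites are deaminase substrates by hypothesis |
| `minus_one_c_frac` | 0.8 | CC-preferring A3G dominates, with a TC minority |
| class counts | 60/20/20/10/40/60 | desk-scale mix with all confounders represented |

Noise sites draw a per-site alt fraction uniform on (0, 0.04), below the
5% prevalence rule by construction; note that at finite depth the binomial
tail still lets a fraction of them pass (at depth 200 the exact removal
probability is 0.79, approaching 1 only at higher depth). SNP classes sit
at alt fractions ~0.5 and ~1.0 and are emitted in the blacklist. Donor
effects are shared random intercepts on the logit scale, which is what
makes the samples "paired". Background flank composition is i.i.d. uniform
over ACGT — a neutral null for motif and structure enrichment.

What it does **not** emulate: read-level artifacts (alignment error,
strand bias, PCR duplicates), RNA degradation, overdispersion beyond the
donor intercept, linkage between neighboring sites, and realistic genomic
base composition. Passing the end-to-end tests therefore demonstrates the
correctness and calibration of the statistical machinery under its own
assumptions, not robustness to upstream artifacts — those are the
responsibility of the variant-calling pipeline that produces the input
counts.

## Numerical and edge-case choices

* Coordinates are 1-based inclusive everywhere inside the package; BED
  input is converted at the boundary.
* Thresholds: prevalence is inclusive ("at least 5%"), FDR is strict
  ("< 0.05").
* Flank windows truncated at contig edges are N-padded; N fails every
  sequence predicate it touches.
* `editing_level()` is NA at zero coverage and such samples never satisfy
  the prevalence rule.
* PFM columns exclude N from the denominator, matching sequence-logo
  semantics of observed residues.
* Rejection sampling in the generator has a retry cap; exceeding it raises
  an error instead of looping, signaling mis-set parameters.

## Worked example

```{r example}
cfg <- sim_config(depth_range = c(100L, 200L), seed = 42L)
ds <- synth_dataset(cfg)
res <- run_cascade(ds$counts, ds$flanks, ds$blacklist)
res$report
```

```{r confusion}
retained <- res$results$site_id[res$results$retained %in% TRUE]
table(ds$truth$class[match(retained, ds$truth$site_id)])
```

All retained sites come from the condition-responsive edited classes; SNP
contaminants die at the blacklist stage and noise at the prevalence stage.

## Problem sizes

The shipped test-suite and acceptance-script simulations use 2000 null
sites for type-I error, 200 sites at depth 500 for effect recovery,
5,000–10,000 random windows for predicate/oracle agreement, and a ~210-site
end-to-end dataset. These sizes give Monte-Carlo standard errors well
inside the asserted tolerances while keeping a full run in the low
minutes on a single core.

## Known limitations

* The GLM is slightly conservative at low depth (type-I error ~0.035 at
  nominal 0.05) because of small-count Wald behavior and the flagged
  Haldane fallback; at depth 500 calibration is nominal.
* The stem-loop rule is a formalization of a manually applied criterion;
  where the original curation permitted wobble pairs or terminal defects,
  counts will differ, and the disagreement listing is the intended
  diagnostic.
* Only hairpins whose loop ends at the edited base are considered — no
  thermodynamic folding, no multi-branch structures.
* A>I events receive statistical treatment only; their sequence/structure
  biology (ADAR substrates) is out of scope.
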