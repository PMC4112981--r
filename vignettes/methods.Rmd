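---
title: "Predicting steroid immunoassay cross-reactivity from 2D structural similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting steroid immunoassay cross-reactivity from 2D structural similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossreact)
```

## The problem

Automated immunoassays are the workhorse method for measuring steroid hormones
(cortisol, DHEA sulfate, estradiol, progesterone, testosterone) in clinical
laboratories. Their antibodies are raised against a small hapten, and any
molecule that resembles that hapten closely enough can bind and register as
apparent analyte. Interferents include endogenous precursors that accumulate in
disease (21-deoxycortisol in 21-hydroxylase deficiency, 11-deoxycortisol after
a metyrapone challenge), synthetic glucocorticoids (prednisolone,
6-methylprednisolone), progestins (norethindrone, medroxyprogesterone) and
anabolic steroids (methyltestosterone, boldenone).

`crossreact` implements the quantitative chain from structure to clinical
judgement:

1. **Structural similarity** — 166-bit structural-key fingerprints and the
   Tanimoto coefficient between each candidate compound and the assay hapten.
2. **Cross-reactivity** — percent cross-reactivity (CR) from spiked-sample
   measurements, binned into four categories.
3. **Interference risk** — the apparent analyte concentration a cross-reactant
   produces at its published plasma concentrations, graded for clinical
   significance.
4. **Triage** — evaluation of similarity cutoffs as a cheap pre-screen for
   which compounds deserve wet-lab cross-reactivity testing.
5. **Simulation** — a synthetic panel generator so the statistical stages can
   be validated offline.

## Fingerprints and similarity

A structural-key fingerprint records, for each entry of a fixed dictionary of
substructure patterns, whether the pattern occurs (with at least a minimal
multiplicity) in the molecule. The packaged dictionary
(`inst/extdata/maccs_keys_v1.tsv`) is the public 166-key set in its commonly
published SMARTS rendering; three keys that no SMARTS can express (isotope,
"more than one aromatic ring", "more than one fragment") are computed
handlers. The dictionary is a versioned plain-text asset and can be swapped;
fingerprints carry their dictionary version and refuse comparison across
versions.

Similarity between fingerprints is the Tanimoto coefficient
$T(A,B) = |A \cap B| / |A \cup B|$ over the sets of set bits, ranging from 0
(maximally dissimilar) to 1 (maximally similar). Two all-zero fingerprints are
a degenerate case: by convention they score 1 against each other and 0 against
any non-empty fingerprint, and a message is emitted.

Structural keys are **stereo-blind**: diastereomers and enantiomers receive
identical fingerprints. Standardization therefore strips all stereo
descriptors before fingerprinting (and `compute_fingerprint()` refuses
unstandardized input). Standardization also keeps only the largest covalent
fragment — salts such as estropipate (estrone sulfate–piperazine) are reduced
to their active fragment — and normalizes protonation so that, for example,
sulfate conjugates are fingerprinted in their neutral acid form regardless of
how the input SMILES was drawn. Largest-fragment selection is by heavy-atom
count with molecular weight as tie-break. This is the conventional
salt-handling default; published panel studies do not state how salts were
prepared for similarity calculation, so this is a package design choice, not
an inference.

Two consequences of the coarseness of a 166-key dictionary are worth knowing.
First, compounds differing only in features the keys do not see can score
exactly 1.0 without being identical (boldenone versus testosterone: the extra
ring double bond changes no key). Second, different vendors' renderings of the
"public keys" differ in detail, so similarities reproduce published values
only approximately. On the packaged panels the deviations are small — estrone
vs estradiol scores 0.879 against a published 0.882, estriol 0.914 vs 0.917,
ethinyl estradiol 0.970 vs 0.943 — and the test suite cross-validates every
packaged fingerprint against an independent public-keys implementation
(agreement ≥ 95% of bits is asserted; in practice agreement is complete). One
published categorical claim is dialect-sensitive: under the packaged
dictionary, corticosterone (weak on the progesterone assay) scores 0.698,
slightly below the published 0.722 floor for strong/weak cross-reactants; the
seven compounds reported by name all sit at or above 0.722.

## Percent cross-reactivity and categories

A spiked-sample experiment adds a known concentration $S$ of test compound to
plasma and measures apparent analyte before ($B$) and after ($X$) spiking:

$$\mathrm{CR} = 100 \cdot \frac{\max(0, X - B)}{S} \quad [\%]$$

Negative baseline-corrected differences are measurement noise and are clipped
to zero (with a message). CR can exceed 100% when the interferent binds the
antibody better than the analyte itself (6-methylprednisolone reaches 249% on
the cortisol assay).

Categories use half-open bins so that every non-negative CR has exactly one
category: **strong** $[5, \infty)$, **weak** $[0.5, 5)$, **very weak**
$[0.05, 0.5)$, **none** $[0, 0.05)$. The conventional upper label "0.5–4.9%"
is read as a display rounding of "below 5". Values flagged *package insert* in
the fixtures are carried with that provenance and never recomputed.

```{r categories}
categorize_cr(c(12.2, 4.95, 0.05, 0.049))
classify_panel(load_fixture_panel("testosterone")$records)
```

## Interference estimates and likelihood grades

For a cross-reactant at plasma concentration $c$, the apparent analyte
contribution is deterministic point arithmetic,
$\mathrm{apparent} = \mathrm{CR}/100 \cdot c$, applied to both ends of the
published plasma range ("up to $X$" ranges get a lower bound of 0). No error
propagation is attempted; published figures present these as deterministic
ranges.

Published tables grade clinical significance qualitatively ("High", "Low,
except in patients with 21-hydroxylase deficiency", "Unknown, no human
pharmacokinetic data available"). Those grades are expert judgements; this
package codifies them as a ratio rule so they become reproducible:

$$R = \frac{\mathrm{apparent~high}}{D}, \qquad
  \mathrm{grade} = \begin{cases} \text{high} & R \ge 1 \\
  \text{possible} & 0.1 \le R < 1 \\ \text{low} & R < 0.1 \end{cases}$$

with `unknown` reserved for compounds lacking plasma data. The decision
concentration $D$ is chosen in two steps:

* If the plasma population names a sex ("women", "men following intramuscular
  injection"), $D$ comes from the matching reference interval — its lower
  bound when positive, else its upper bound. This captures, e.g., that
  pregnanolone concentrations in women are negligible against female
  progesterone levels, while the same apparent concentration would matter in
  an unsexed population.
* Otherwise $D$ is a per-assay **clinical decision level** packaged with the
  assay definition: cortisol 23 ng/mL (low bound of the afternoon adult
  interval), DHEA sulfate 400 ng/mL (a tenth of the adult upper bound — the
  analyte circulates at µg/mL, so sub-µg/mL contributions cannot alter
  interpretation), estradiol 0.04 ng/mL (male upper bound; male estradiol is
  the most interference-vulnerable measurement), progesterone 1.4 ng/mL (male
  upper bound, the ~1 ng/mL scale at which progesterone becomes diagnostically
  meaningful), testosterone 3 ng/mL (300 ng/dL, the conventional adult male
  hypogonadism threshold).

A single-anchor rule (for instance "lower bound of the least-sensitive
reference interval") cannot reproduce the published grades: on the
progesterone panel it would need an anchor between 2.38 and 2.46 ng/mL, which
corresponds to no reference bound. The two-step rule above reproduces every
published High/Low/Unknown label on the five packaged panels — the
acceptance test asserts this row by row — with the caveat that rows worded
"Possible …" are qualitative and are reported but not bound by the check. Two
rows graded here as `low` carry a published "Possible significant
contribution" wording (medroxyprogesterone and exemestane on the progesterone
assay, both sexed populations judged against the female interval); both
concern peak-concentration scenarios the published wording itself flags as
conditional. Thresholds (1 and 0.1) and decision levels are configuration,
not constants.

```{r interference}
p <- load_fixture_panel("cortisol")
rep <- interference_report(p$assay, p$records, p$ranges)
head(rep[, c("compound_name", "population", "apparent_high", "likelihood")])
```

## Similarity as a triage classifier

For triage, positives are the strong and weak cross-reactive compounds
("strong or even weak" is the phrasing the cutoff claims address); negatives
are the non-cross-reactive ones. The very-weak category is genuinely
ambiguous and is excluded by default (`very_weak = "exclude"`), with options
to count it on either side. Compounds exactly at the cutoff are flagged
("similarity of 0.8 or higher"). `threshold_sweep()` reports confusion counts,
sensitivity and specificity over a cutoff grid (default 0 to 1 in steps of
0.05); sensitivity is non-increasing and specificity non-decreasing in the
cutoff by construction, and the tests verify the counts against brute-force
enumeration.

## The synthetic panel generator

The simulator exists to validate the statistical stages (CR estimation,
categorisation, triage metrics) without instrument data. It draws similarities
uniformly on $[0,1]$ and links them to expected CR through a logistic:

$$E[\mathrm{CR}](s) = \frac{\mathrm{link\_max}}{1 + e^{-\mathrm{link\_slope}(s - \mathrm{link\_midpoint})}}$$

with lognormal scatter (`noise_sd_log`, default 0.2) for the true CR and
multiplicative Gaussian readout noise (`assay_cv`, default 0.05 — typical
automated immunoassay imprecision) for the measurements. Defaults
`link_midpoint = 0.8`, `link_slope = 40`, `link_max = 100` place the
strong-CR onset (5%) near similarity 0.73 and the weak onset (0.5%) near
0.67, the threshold-like pattern seen across the packaged steroid panels.
`baseline_level` defaults to 5 ng/mL: interference protocols spike into a
low-analyte matrix, and the spike (default 1000 ng/mL) dominates the readout.
All randomness flows from the single `seed`; equal configurations produce
bit-identical panels.

What the simulator deliberately does **not** emulate: real molecular
structures (similarities are drawn, not computed from simulated molecules —
fingerprinting is exercised on the real packaged structures instead), assay
calibration physics, and replicate-level outliers. Passing recovery tests
therefore validates the estimation arithmetic under the stated noise model,
not the chemistry.

`recovery_experiment()` replicates the measurement stage and reports bias and
category agreement. With the default noise model, CR estimation is unbiased
(the readout noise is multiplicative and symmetric; the only bias source is
zero-clipping, which is negligible above the quantification scale of ~0.5%),
and compounds whose true CR sits a factor ≥ 2 from every bin edge essentially
always classify correctly from 10 replicates. The packaged acceptance test
runs 500 compounds at `assay_cv = 0.05` with 10 replicates.

## Numerical and degenerate-input choices

* Bin edges are half-open; boundary values (exactly 0.05, 0.5, 5) take the
  upper category.
* Tanimoto on two empty fingerprints returns 1 (logged); empty versus
  non-empty returns 0.
* `flag_candidates()` breaks similarity ties alphabetically for stable output.
* Negative baseline-corrected CR differences clip to 0 with a message.
* Interference rows with no plasma data sort after all quantified rows.
* SMILES stereo stripping is textual (`@`, `/`, `\` removal); bracket
  hydrogen counts are preserved, so the constitution is unchanged — the
  structure is then re-canonicalized through OpenBabel.
* Aromatic-ring counting for key 125 uses ring perception on the canonical
  structure; for fused aromatics the count includes ring envelopes, which
  cannot change the ≥ 2 decision.

## Problem sizes

The packaged analyses are small by construction: 44 curated structures, 166
keys, five assay panels. The simulation-based tests use panels of 200–500
compounds with 10 measurement replicates, which is ample to detect bias at
the percent scale while keeping the whole suite fast.

## Known limitations

* Key-dialect parity with any specific commercial implementation is not
  promised; the dictionary is versioned and swappable.
* The likelihood rule reproduces published grades on the packaged panels but
  is a codification of expert judgement, not a validated clinical rule.
* Plasma-range citations are carried as opaque reference identifiers from the
  transcription source, not resolvable bibliography entries.
* The similarity–cross-reactivity link is empirical and assay-family
  specific; a high-similarity compound can still be non-cross-reactive
  (tetrahydrocortisone scores 0.911 to cortisol yet does not cross-react),
  which is why similarity is a triage tool, not a predictor of record.
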