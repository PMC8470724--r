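---
title: "Methods: untargeted LC-QTOF-MS screening with ngmscreen"
author: "ngmscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: untargeted LC-QTOF-MS screening with ngmscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ngmscreen)
```

# Scope

`ngmscreen` implements a single-patient, untargeted metabolomics screening
pipeline for liquid chromatography / quadrupole time-of-flight mass
spectrometry (LC-QTOF-MS) data, of the kind used for next-generation
metabolic screening of inborn errors of metabolism. A batch contains one
or more duplicate injections per patient, pooled quality-control (QC)
injections and spiked validation-plasma injections, acquired in positive
and/or negative electrospray mode. The question answered for each patient
is: *which features are significantly altered in this patient relative to
the other patients in the same batch*, with annotations against a
diagnostic panel and a compound library.

The package covers: exact-mass arithmetic (`chem`), batch I/O with
checksums and a write-once session configuration (`batch_io`),
feature alignment across injections (`align`), panel/library annotation
and related-feature grouping (`annotate`), single-patient robust
statistics (`stats`), QC and validation gating (`quality`), immutable
result records with filtering and an audited review workflow
(`interpret`), and a deterministic batch simulator (`synth`). A thin
command-line front-end lives in `exec/ngms`.

# Mass arithmetic

Monoisotopic masses are computed from CODATA/IUPAC atomic masses
(`mass_constants`), e.g. `monoisotopic_mass("C21H39NO4")` = 369.28791 Da.
Ion m/z uses electron-corrected adduct shifts:

$$ m/z = \frac{n\,M + \Delta_{\mathrm{adduct}} + k\,\delta_{13C}}{z} $$

where $\Delta_{\mathrm{adduct}}$ already accounts for the electron
(e.g. M+H uses the *proton* mass 1.00727646688 Da, M+Na uses
$m_{\mathrm{Na}} - m_e$), and $\delta_{13C} = 1.003354838$ Da is the
$^{13}\mathrm{C}-{}^{12}\mathrm{C}$ spacing used for isotopologues. Mass
deviations are expressed in parts per million,
$\mathrm{ppm} = 10^6 (m_{\mathrm{obs}} - m_{\mathrm{theo}}) / m_{\mathrm{theo}}$.

**Isotopologue model.** Only $^{13}$C isotopologues are modelled
(`max_isotope` defaults to 1). For CHNOS metabolites below ~1 kDa the
first isotope peak is dominated by $^{13}$C; $^{15}$N, $^{18}$O, $^{34}$S
contributions shift the centroid by well under the 5 ppm matching
tolerance at these masses, so a single-spacing model is adequate for
annotation (not for fine isotope structure, which a QTOF does not resolve
anyway).

# Batch I/O

Worklists (TSV) carry sample id, role (`patient`, `qc_pool`,
`validation`), injection index, ion mode, data-file name and an optional
SHA-256 checksum; `verify_checksums()` reports `pass / fail / missing /
unverified` per entry. Peak lists are read from TSV (written at full
`%.17g` precision so simulated batches round-trip bit-exactly) or from
centroided mzML via Bioconductor's `mzR`; profile-mode spectra are
rejected, and scan times are converted from seconds to minutes on read.
Session parameters are frozen in a write-once, read-only `session.json`
so that a screening session's tolerances cannot drift after the fact.

# Alignment

Features are formed by single-linkage clustering of peaks across
injections: two peaks are linked when their pairwise ppm distance (at the
pair-mean m/z) is within `mz_tolerance_ppm` **and** their retention-time
difference is within `rt_tolerance_min`. Connected components are found
by a sweep over m/z-sorted peaks with union–find. Each component is then
refined:

1. per injection, only the most intense peak is kept (duplicates from the
   same injection are released);
2. the component is iteratively trimmed: while any member deviates from
   the component medoid by more than the tolerance, the worst member
   (largest normalised badness $\max(|\mathrm{ppm}|/\mathrm{tol}_{mz},
   |\Delta rt|/\mathrm{tol}_{rt})$) is released;
3. released peaks are re-pooled and may form further features.

Every input peak is assigned to exactly one feature or explicitly
released (conservation invariant), and the result is independent of input
order. The test suite checks the optimised implementation against an
exhaustive brute-force oracle on random peak clouds.

**No retention-time warping.** Within a single batch on one column, RT
drift is small relative to the 0.5 min tolerance; the QC module measures
per-injection RT shift of built-in standards instead of correcting it.
Cross-batch alignment (which would need warping) is out of scope;
`compare_sessions()` compares *results*, not raw features, across
sessions.

# Annotation

A diagnostic panel (compound, formula, HMDB id, expected RT, adducts) is
expanded to an ion index over all (adduct, isotopologue) pairs for the
acquisition mode. Panel annotation requires both the m/z gate (ppm
tolerance) and the RT gate; library annotation is m/z-only (`mz_only`
level) and deliberately reports *all* in-tolerance compounds so that
isobars (e.g. leucine/isoleucine) remain visible to the reviewer.
`group_related_features()` clusters co-eluting features whose m/z
differences match adduct or $^{13}$C relations and back-calculates a
consensus neutral mass.

# Single-patient statistics

Duplicate injections are averaged per sample (NA-aware; a `partial` flag
marks samples with missing injections). For a target patient with mean
intensity $x_p$ and reference intensities $x_1,\dots,x_{n}$ from the
other patients:

$$ \mathrm{FC} = \frac{x_p}{\max(\mathrm{median}(x), \mathrm{floor})},
\qquad
 z = \frac{x_p - \mathrm{median}(x)}
          {\max(1.4826\,\mathrm{MAD}(x),\ 0.05\,\mathrm{median}(x),\ \mathrm{floor})} $$

with two-sided $p = 2\Phi(-|z|)$. The intensity floor (default 1000
counts) keeps near-noise denominators from producing spurious
fold-changes; the $0.05\,\mathrm{median}$ term keeps $z$ finite when the
reference spread is degenerate. A feature is flagged altered-up when
$z \ge z_{\min}$ and $\mathrm{FC} \ge \mathrm{fc_{up}}$ (defaults 3
and 2), altered-down symmetrically with $\mathrm{fc_{down}} = 0.5$.
Statuses distinguish `ok`, `patient_missing`, `insufficient_reference`
and `undefined`. These statistics are scale- and permutation-invariant
and identically zero at the reference median, which the tests assert
directly.

# Quality control and gating

Built-in standards (two internal, one external) are recovered from every
injection by m/z + RT matching; per standard the module reports the worst
ppm error, the maximal RT deviation from the median
(`rt_delta_pct`) and the intensity coefficient of variation.

**CV convention.** CV uses the *sample* standard deviation ($n-1$
denominator): intensities (90, 100, 110) give CV = 10%. This is the
convention used by QC software and avoids underestimating variability in
the small-$n$ regime typical of a batch.

**Why mid-gradient standards.** The built-in standards elute mid-gradient
(5.6, 6.1 and 12.6 min). Early-eluting compounds sit near the column
void volume where relative RT jitter is largest; mid-RT standards make
`rt_delta_pct` reflect gradient stability rather than void-volume noise.

Validation plasma is spiked with a known compound set;
`validation_report()` checks that each spiked panel compound is recovered
as an altered-up, panel-annotated feature and names any missing compound.
`session_gate()` releases a session for interpretation only when all
QC standards pass *and* the validation gate passes. `diagnostics_data()`
provides PCA scores (log10, complete rows), per-injection RT shift and
extracted-ion traces for visual inspection.

# Interpretation and audit

`interpretation_records()` joins statistics and annotations into records
whose result columns are immutable: assignment via `$`, `[[` or `[`
raises an error, so a reviewer can add notes but never edit a computed
value. Filters (`filter_spec()`) are pure conjunctions over RT/mz ranges,
p-value, absolute fold-change, annotation level and altered status;
`diagnostic_preset()` is the routine starting view (altered features with
panel annotation). The audit log is an append-only JSONL file; replaying
it is a pure fold over events with a linear review state machine
(`new → in_review → reviewed → approved`) in which only a
`lab_specialist` may approve. Re-writing or truncating an existing log is
refused.

# Batch simulator

`simulate_batch()` generates a full batch deterministically from a seed.
Randomness is *stream-keyed*: every (sample, injection, mode) triple gets
its own RNG stream seeded from a SHA-256 hash of
`(seed, sample, injection, mode)`, so adding samples or modes never
perturbs existing injections — a property the tests assert byte-exactly.

Per compound and sample, the endogenous level is
$\mathrm{base} \cdot \mathrm{LogNormal}(0, \sigma_{\mathrm{bio}})$ with
$\sigma_{\mathrm{bio}} = 0.2$; each injection adds technical noise with
$\sigma_{\mathrm{bio}}/3$. Ions are generated for adducts (relative
abundances 1 : 0.25 : 0.1) and the first $^{13}$C isotopologue (20% of
the monoisotopic intensity), with 2 ppm m/z noise, a shared per
compound-injection RT jitter (sd 0.05 min) and 1% random peak dropout.
The default batch — 20 patients × 2 injections + 3 QC-pool +
2 validation-plasma injections per mode — is the package's own choice of
a realistic routine-screening size; it is configurable via `sim_spec()`.

**Spikes set the level.** A spike of fold $f$ *replaces* the endogenous
biological draw with $\mathrm{base} \cdot f$ (technical noise only),
rather than multiplying the biological draw by $f$. This mirrors how
validation plasma is actually prepared — a known amount is added to a
pool, so the spiked concentration is controlled, not a random variable —
and it is what makes fold-change *recovery* a well-posed accuracy
question: the only error sources are technical noise and the
reference-median noise of the other patients. `vlcadd_scenario()` builds
the bundled worked example: nine long-chain acylcarnitines spiked into
patient P01 at folds between 29 and 1227, plus spiked validation plasma
in both modes.

# Numerical choices

- All intensities and masses are doubles; no single-precision paths.
- Peak-list TSVs use `%.17g` so written batches reload bit-identically.
- Matching uses `findInterval` on sorted ion tables ($O(\log n)$ per
  query); candidate ties are ordered by |ppm|, then m/z, then index, so
  results are deterministic.
- Exact identities (mass additivity, checksum round-trips, determinism)
  are tested with `expect_identical`; quantities subject to
  floating-point cancellation (e.g. isotopologue spacing obtained by
  *differencing* two ~400 Da values) are tested to 1e-12 Da.

# Default parameters

| parameter | default | rationale |
|---|---|---|
| `mz_tolerance_ppm` | 5 | routine QTOF mass accuracy with lock mass |
| `rt_tolerance_min` | 0.5 | within-batch RT stability on a 15–20 min gradient |
| `z_min` | 3 | ~0.3% two-sided false-positive rate per feature under normality |
| `fc_up`, `fc_down` | 2, 0.5 | two-fold biological relevance threshold |
| `intensity_floor` | 1000 | below typical QTOF noise floor |
| isotope depth | 1 | see isotopologue model above |

# Limitations

- Single-batch design: the reference population is the co-acquired
  patients, so systematic batch effects cancel but cohort-level
  normalisation is out of scope.
- No RT warping or cross-batch feature alignment (see above).
- $^{13}$C-only isotope model; no fine isotope structure or isotope-ratio
  scoring.
- Library annotation is m/z-only and therefore ambiguous for isobars by
  design; disambiguation is left to the reviewer (MS/MS is not modelled).
- The simulator models centroided peak lists, not raw profile spectra;
  peak picking itself is outside the package.
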