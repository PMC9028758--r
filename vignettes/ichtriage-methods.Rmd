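---
title: "Methods: extraction, weighted triage, and synthetic evaluation in ichtriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extraction, weighted triage, and synthetic evaluation in ichtriage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ichtriage)
```

`ichtriage` turns narrative emergency medical records of intracerebral
hemorrhage (ICH) patients into treatment-plan recommendations and evaluates
that pipeline end to end on synthetic cohorts. This vignette documents the
model, its assumptions, the tunable parameters, the numerical choices, and
what the synthetic experiments do and do not establish.

## The clinical decision model

An ICH case is summarized by a fixed schema of clinical variables
(`case_facts_schema()`): the Glasgow Coma Scale (eye 1–4, verbal 1–5, motor
1–6, total 3–15), vital signs (heart rate, blood pressure in mmHg, oxygen
saturation in %), consciousness grade (alert / drowsy / stupor / coma),
pathological reflexes, pupil state (equal-reactive / anisocoria /
bilateral fixed-dilated), the headache–nausea–vomiting symptom triad,
bleed location and laterality, hematoma volume in mL, ventricular cast and
shape, midline shift in mm, and the clinical trend (stable /
deteriorating). Every field carries an explicit unknown state (`NA`):
emergency documentation is lossy by nature, and the decision layer must
behave sensibly under missing data.

Treatment plans follow the three-tier convention for emergency ICH triage:
**Plan I** — an indication for emergency surgery exists; **Plan IIA** — no
surgical indication for the time being, but the condition is unstable and
surgery may become necessary; **Plan IIB** — no surgical indication and a
relatively stable course managed with drugs. Plans IIA and IIB collapse to
a coarse **Plan II** (non-surgical) for binary analyses, with Plan I as the
positive class.

### The logic table

The expert module evaluates an ordered set of conjunction rules over the
case facts. Each rule has a non-negative weight and an optional *mandate*
flag. The weighted score is the normalized fired-weight sum
\(s = \sum_{\text{fired}} w_r / \sum_r w_r \in [0,1]\); a fired mandate
forces Plan I outright, otherwise \(s \ge \text{cut\_high}\) gives Plan I,
\(\text{cut\_low} \le s < \text{cut\_high}\) Plan IIA, and below that
Plan IIB.

Numerical and semantic choices, all deliberate:

* **Ties at a cut-point resolve toward the more aggressive plan.** A score
  exactly at `cut_high` is Plan I, exactly at `cut_low` is Plan IIA. In an
  emergency setting the cost of under-triage dominates, so boundary cases
  escalate.
* **Unknown never fires a comparator.** A missing GCS cannot mandate
  surgery; conservative behavior under missing data is a safety property.
  A dedicated warning flags cases where both GCS total and hematoma volume
  are unknown — with the two highest-weight variables absent, the score is
  not trustworthy.
* **Mandate rules carry weight 0** in the default table. Hard surgical
  indications are absolute, not graded, so they contribute categorically
  (forced Plan I) rather than numerically; the score then reflects graded
  severity only. The normalizer is still the total table weight, so "all
  rules fire" still scores exactly 1.
* **Severity thresholds are cumulative, not banded.** The moderate-volume
  and moderate-GCS rules are `volume >= 10 mL` (weight 1) and
  `GCS <= 12` (weight 1), with the large-volume (`>= 30 mL`,
  supratentorial, weight 3) and deep-coma (`GCS <= 8`, weight 3) rules
  stacking on top. Band-shaped rules (e.g. "volume 10–30 mL") would make
  the score non-monotone — a hematoma growing past 30 mL in a location not
  covered by the large-volume rule would *lower* the score — violating the
  clinically obvious requirement that a larger bleed or a deeper coma never
  argues for less aggressive care. With cumulative thresholds, monotonicity
  holds structurally and is verified by property tests over randomized
  cases.

The shipped default table (`inst/extdata/logic_table.yaml`) encodes widely
published surgical indications: mandates for cerebellar hemorrhage ≥ 10 mL
(or with ventricular cast, or with brainstem-compression signs — stupor or
coma), large supratentorial hematoma (≥ 30 mL) with GCS ≤ 8, and
herniation signs (bilateral fixed-dilated pupils; anisocoria with coma);
graded weights 3/3/2/2/2/2/1/1/1 for large supratentorial volume, GCS ≤ 8,
midline shift ≥ 5 mm, ventricular cast, deterioration, anisocoria,
volume ≥ 10 mL, GCS ≤ 12, and pathological reflexes; cut-points 0.5 and
0.15. Brainstem hemorrhage deliberately routes through graded scoring
rather than a mandate — its surgical indication is controversial. All of
this is configuration: the table is data, validated at load time (unknown
fields and comparators are configuration errors), and the same machinery
evaluates any user-supplied table.

## Text extraction

The reference entity recognizer is a dictionary + regular-expression
matcher, deliberately chosen over a learned tagger: its behavior is
auditable, deterministic, and exactly testable, and the tagger contract
(records in, mentions out) lets a trained model replace it without touching
the rest of the pipeline.

Preprocessing lowercases the text, replaces non-text symbols (control
characters and decorative punctuation runs) with spaces, corrects
misspellings and expands abbreviations from lexicon tables, and collapses
whitespace — while threading an offset map from every output character back
to the raw text, so mentions remain reportable against the original
document. Matching then applies every lexicon entry to each section with
longest-match-first, left-to-right overlap resolution per label (the
standard dictionary-NER policy, and a deterministic one).

Three details matter for correctness:

* **Negation** uses a minimal clause-scope rule: a cue ("no", "denies",
  "without", "not", "absent") occurring earlier in the same clause
  (clauses split at `.` and `;`) sets tri-state fields to *absent* — which
  is different from *unknown*. "No midline shift" is a finding (0 mm); an
  unmentioned midline shift is missing data. Full negation parsing is out
  of scope.
* **Units** are normalized table-driven: volume accepts mL and cc; midline
  shift accepts mm and cm (× 10, rounded at 10⁻⁶ to absorb binary
  floating-point error in the conversion).
* **Conflict resolution** during fact assembly follows section precedence
  CT report > physical exam > history > chief complaint, then later offset
  wins within a section (later statements supersede earlier ones); every
  conflict is logged as data.

The lexicon dialect is English. The tokenization and all surface forms are
configuration, so a different language (e.g. a segmenter-based Chinese
lexicon) can be substituted file-for-file; the package ships and tests only
the English forms.

## The synthetic cohort generator

Real neurosurgical eEMR corpora are private. The generator stands in for
them with three components, each a documented modeling choice:

**Clinical priors** (`clinical_priors()`): bleed location is categorical
(basal ganglia 0.50, thalamus 0.15, lobar 0.15, cerebellum 0.09, brainstem
0.06, primary intraventricular 0.05 — literature-typical frequencies);
volume is location-conditional log-normal (medians 20/10/30/10/5/8 mL,
sdlog 0.7, clamped to 1–150 mL); GCS total is drawn around
\(15 - 8\,\mathrm{logit}^{-1}((v - 25)/12)\) with SD 1.8, so severity
rises with volume; the consciousness grade is banded deterministically
from the total (alert 13–15, drowsy 9–12, stupor 6–8, coma 3–5) and the
three components are sampled uniformly from the feasible compositions of
the total; midline shift couples positively to volume for supratentorial
bleeds; pupil abnormalities, pathological reflexes and a deteriorating
trend become more likely with severity; vitals and demographics (age
truncated to 10–80 years, the study population's inclusion range) come
from truncated normals. Every draw passes `validate_case_facts()`.

**Gold standard**: a reference logic table plays the role of the senior
raters. When the gold table equals the deployed table, a noiseless run
must score 100% — the end-to-end oracle. When it differs (e.g.
`with_cut_points(default_logic_table(), cut_high = 0.4)`), disagreement is
controlled and interpretable, which is how the evaluation layer is
exercised in a realistic sub-100% regime without human raters.

**Narrative rendering and noise**: one sentence per fact from template
files, canonical and exactly invertible at zero noise. The noise model has
five rates, defaults in parentheses: `misspelling_rate` (0.05) per keyword
token — drawn from the lexicon's misspelling table when a variant is
listed, otherwise an adjacent-character transposition on longer tokens
(real corpora contain typos no correction table knows; without these, the
extractor would repair every injected error and noise would not degrade
anything); `symbol_noise_rate` (0.10) per sentence; `abbreviation_rate`
(0.20) per expandable phrase; `field_dropout_rate` (0.02) per fact; and
`unit_variant_rate` (0.10) for cc/cm surface forms. Table-listed
misspellings and abbreviations are invisible to the pipeline by
construction (preprocessing inverts them); transpositions and dropouts are
not, and they produce the monotone accuracy degradation the tests verify.

What passing synthetic tests shows — and does not. They establish that the
extraction grammar, the assembly precedence, the scoring arithmetic and
the metric suite are correct, and that the pipeline degrades gracefully
under the modeled corruptions. They do not establish performance on real
records: real narratives have free word order, out-of-lexicon synonymy,
hedging, and cross-sentence discourse that the template grammar does not
emulate. Accuracy on this generator is an upper bound with respect to
linguistic variability.

## Evaluation suite

Binary metrics use the coarse confusion matrix with Plan I positive:
sensitivity tp/(tp+fn), specificity tn/(tn+fp), accuracy, PPV, NPV, each
with a 95% CI on its own denominator — Wald normal approximation by
default (the conventional presentation for clinical accuracy tables),
Wilson optionally; a zero denominator reports the metric as undefined
rather than 0. Per-plan accuracy is the recall of each plan in the 3×3
table; the fine (3-plan) accuracy is reported separately from the coarse
one, because an IIA↔IIB error changes only the former.

The ROC sweeps every distinct score threshold descending and integrates by
trapezoid, which equals the Mann–Whitney pair statistic with ties counted
½ (verified against a brute-force pair enumeration to 10⁻¹²); the CI uses
the Hanley–McNeil standard error. The score fed to the ROC is the weighted
score with mandate-fired cases lifted to 1.0 — a mandated case outranks
every graded case by construction. This adapter (`roc_score()`) is the one
place where that choice lives; nothing else depends on it.

Cohen's κ is computed on the fine 3-level labels,
\(\kappa = (p_o - p_e)/(1 - p_e)\), with the large-sample standard error
\(\sqrt{p_o(1-p_o)/(n(1-p_e)^2)}\); perfect observed agreement returns
κ = 1 even in the degenerate single-category case.

## Problem sizes and determinism

The test suite exercises the pipeline at sizes chosen to make the
statistical checks decisive while keeping a full run comfortable on one
CPU: 500-case cohorts for the noiseless round-trip and the noise-
degradation comparisons (paired generator seeds across misspelling rates
0/0.1/0.3), 1,000 randomized fact vectors for the monotonicity and bounds
properties, 2,000 cases for the controlled-disagreement evaluation, and
100 random label/score vectors (n ≤ 200) for the metric oracles. Both
published split presets are covered: 0.7/0.3/0 reproducing a 700/300
train/validation partition at n = 1000, and 6:2:2; split sizes use
largest-remainder rounding, so they are exact whenever the ratio divides
n. Every stochastic component is seed-determined; a cohort spec plus seed
reproduces a byte-identical corpus, and the pipeline runner derives
per-stage child seeds from the run seed by a fixed stage-name-keyed hash
so stages can be re-run in isolation.

## Known limitations

* The default logic table is a guideline-derived surrogate, not a fitted
  or validated clinical instrument; weights and cut-points are starting
  points for calibration against an institution's own gold standard.
* The dictionary recognizer has no recall beyond its lexicon; paraphrases
  outside the template grammar are missed (by design — the trainable
  tagger slot exists for exactly that).
* The score is not a calibrated probability; no outcome prediction
  (mortality, mRS) is attempted.
* CIs are large-sample approximations; at very small n or extreme
  proportions the Wald interval is known to under-cover (Wilson is
  available).
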