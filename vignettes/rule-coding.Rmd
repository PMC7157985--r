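---
title: "Rule-based ICD-10 coding: model, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based ICD-10 coding: model, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icdcoder)
```

## The coding model

`icdcoder` implements a semi-automatic coding machine for free-text
diagnosis descriptions. Its central object is the *description model*: a
single regular expression bound to exactly one diagnosis code, written to
accept every phrasing clinicians use for that diagnosis (synonyms,
optional qualifiers, abbreviations). A rule base is a collection of such
models with pairwise-distinct codes — one regexp per code, never more.

Matching is a containment test by default: a pattern without `^`/`$`
may match anywhere inside the normalized description, mirroring how a
SQL `REGEXP_LIKE` predicate behaves when such rules are deployed inside
a hospital information system. Assignment is maximally conservative:

* exactly one rule matches → the code is assigned and logged;
* zero rules match, or two or more match → the record goes to the
  failure log (`no_match` / `ambiguous`) for a human coder.

No tie-breaking (longest match, first match, rule priority) is ever
applied to ambiguous records. Ambiguity is a signal that two description
models overlap; resolving it is rule-maintenance work, not something the
matcher should guess at. For the same reason the batch matcher is
rule-order independent: permuting the rule base changes no status and no
assigned code, a property the test suite checks explicitly.

Code syntax follows ICD-10 with the Chinese CCD national extension: one
chapter letter, two digits, an optional `.`-subdivision of up to four
alphanumerics, and optionally a space plus two extension digits (so
`I25.101`, `I10 06` and `F09 01` are all valid). The chapter letter also
drives the per-cluster analytics.

### Regex dialect

Rule authors are guaranteed the construct set `^`, `$`, `*`, `.`, `|`,
`?`, grouping, and literal characters. Patterns are compiled with PCRE,
so richer constructs (`+`, `{m,n}`, character classes, escapes) work,
but `validate_rulebase()` attaches a portability warning to them: rule
bases written against the guaranteed set behave identically when pushed
down into other engines (POSIX ERE, database regexp predicates), while
anything beyond it is dialect-dependent.

### Normalization

Descriptions and rule labels are folded before matching, in a fixed
order: full-width → half-width characters (U+FF01–U+FF5E and the
ideographic space, common residue of CJK input methods), Latin case
fold, optional punctuation stripping (default: none), whitespace
collapse and trimming. The composite is idempotent, and a fingerprint of
the configuration is recorded on the compiled rule base so a run can be
tied to the normalization it used. Defaults are conservative —
whitespace, width and case folding on, stripping off — because stripping
punctuation can merge clinically distinct tokens (`type-2` vs `type 2`
is safe, but stripping is opt-in for anything beyond the characters the
caller nominates).

An `anchored = TRUE` compile switch turns every rule into a
whole-string match (`^(?:pattern)$`). Substring search is the default
because deployed rule engines of this kind test containment; fully
anchored rule bases are possible and some sites may prefer them, so the
choice is exposed rather than hard-coded.

## Audit and evaluation

Each audited record falls into one cell of a display-by-condition
taxonomy. *Condition positive* is operationalized via the modeled-code
set: a gold code with a rule is modelable, one without is not. Emitted
and equal to gold → TP; emitted and different → FP; not emitted with a
modeled gold code → FN; not emitted with an un-modeled gold code → TN
(a correct absence — the machine was never given a rule for that
diagnosis, so staying silent is the right answer). This makes accuracy
meaningful for partially covered code universes, where the bulk of rare
categories is deliberately un-modeled.

Metrics are percentages: precision `100·TP/(TP+FP)`, recall
`100·TP/(TP+FN)`, accuracy `100·(TP+TN)/total`, and the weighted
harmonic F-measure `1/(α/P + (1-α)/R)` with default `α = 0.5`, at which
it reduces algebraically to `2PR/(P+R)`.

Numerical choices:

* Count-based metrics are evaluated as exact rationals and rounded
  half-up to two decimals only at reporting (`digits = NA` returns the
  full-precision value). The half-up rounding is done in integer
  arithmetic, `⌊(200·s·num + den) / (2·den)⌋`, exact for any realistic
  count sizes.
* The F-measure is computed as `p·r/(α·r + (1-α)·p)`, which at
  `α = 0.5` is bit-identical in floating point to `2pr/(p+r)`; the
  reported F is computed from the already-rounded P and R, matching how
  coding reports are tabulated.
* Zero denominators yield `NA` — an explicit undefined-metric marker.
  They are never silently mapped to 0 or 100, and `metrics_report()`
  propagates them.
* `failure_breakdown()` reports the three audit hand-back categories:
  mismatch codes (= FP), loss codes (= FN), and repeated codes, defined
  at the patient-group level (the same code assigned more than once
  within one `group_id`) since per-record assignment is single-valued.

One published evaluation table this package is checked against contains
an internal inconsistency: the second stage's printed recall (27.90) is
not what its own printed counts give (85,838/(85,838+222,938) = 27.80,
with the printed F consistent with 27.90). The golden tests therefore
pin the second stage's precision and accuracy only, and check the
counts-derived recall (27.80) together with the harmonic-mean identity
for F.

During rule building, `majority_resolve()` handles historical
(description, code) pairs: the code with strictly greatest pooled coder
support wins; tied descriptions go to an unresolved queue for manual
handling rather than being broken arbitrarily.

## The synthetic-corpus generator

Hospital diagnosis streams are confidential, so validation runs on
generated corpora that reproduce the structural features the matcher
actually depends on:

* **Frequency skew.** Code occurrences follow a Zipf law over ranks,
  `w_k ∝ k^(-s)` with default exponent `s = 1` — real code-frequency
  distributions concentrate most occurrences in the top ~100 of several
  hundred categories, which is why rule building proceeds from the most
  frequent categories downward.
* **Partial coverage.** A `coverage` fraction of codes (default 0.5),
  taken from the most frequent rank downward, receives rules; records
  of uncovered codes must match nothing, emulating the large un-modeled
  tail.
* **Surface variation.** Each code has a primary and a synonym token
  (used with probability `p_synonym = 0.3`), an optional qualifier
  token (`p_optional = 0.3`), and spacing/width/case noise
  (`p_noise = 0.2`) that normalization must undo. The default universe
  has 500 code categories — the size of a high-frequency modeling set —
  about 10% of them in national-extension form, and records are grouped
  six to a patient, the typical number of diagnoses per discharge
  record.
* **Injected ambiguity.** A fraction `ambiguity_rate` (default 0.02) of
  covered records has a second rule's token phrase appended, guaranteeing
  a multi-rule hit.

Vocabulary is synthetic fixed-width token strings, deliberately
language-neutral: tokens of equal length can never be substrings of one
another, so the generator can *prove* its truth sidecar — in-coverage
non-ambiguous records match exactly their own rule, ambiguity-injected
records match at least two, out-of-coverage records match none. That by-
construction truth is what makes the end-to-end system test sharp: the
matcher must reproduce the truth statuses exactly, not approximately.

What the generator does **not** emulate: real clinical language
(morphology, abbreviation conventions, combination diagnoses), coder
behaviour over calendar time, and rule bases whose patterns are
imperfect for their own diagnosis. Passing the synthetic suite therefore
demonstrates that the machinery — normalization, matching, logging,
audit arithmetic — is correct, not that any particular hand-written rule
base will reach a given precision on real text.

All sampling is routed through a single integer seed
(`withr::with_seed`), so a corpus is a pure function of its spec: same
seed, byte-identical corpus.

## Validation strategy and problem sizes

The test suite runs at sizes chosen to exercise every code path while
keeping a full run in the tens of seconds: batch-vs-naive-scan oracle
equivalence on 100 random corpora of up to 50 rules × 200 records; the
harmonic-mean identity on 1,000 random count tuples; Zipf mass checked
against the analytic harmonic-number ratio at 10⁶ draws; and the
partial-coverage recall check at 10,000 records, where realized recall
(with every code treated as modelable, so uncovered records audit as
FN) must sit within two binomial standard errors of the covered ranks'
probability mass.

## Known limitations

* One description, one record: multi-diagnosis free text must be split
  upstream (the `group_id` field preserves the patient grouping).
* The matcher tests every rule against every record; for rule bases
  orders of magnitude beyond the ~10³ rules this system targets, a
  prefilter (literal-token index) would be the natural extension.
* Rules are authored by humans; the package validates and audits them
  but does not induce patterns from historical pairs.
* The FN definition is purely set-based. In a live deployment, records
  coded manually while the automatic pass is idle also surface as FN in
  that deployment's bookkeeping; such workflow effects are out of scope
  here.
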