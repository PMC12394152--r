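---
title: "Karyotype cohort analysis: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Karyotype cohort analysis: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyocohort)
```

`karyocohort` analyses cohorts of constitutional amniotic-fluid karyotypes.
This vignette documents the scientific model behind each stage, the
parameters a user may want to change, and the decisions taken where the
underlying conventions are genuinely open.

## The ISCN subset and its assumptions

A G-banded karyotype is reported as an ISCN string: one or more clones
separated by `/`, each with a modal chromosome number, a sex-chromosome
designation and a comma-separated list of abnormality tokens, optionally
followed by a `[n]` cell count; a whole-sample `mos ` (mosaic) or `chi `
(chimera) prefix may precede everything. The parser covers the classes that
occur in constitutional prenatal series:

* whole-chromosome gains/losses (`+21`, `-7`, `+mar`), including the
  sex-chromosome aneuploidies written in the header (`45,X`, `47,XXY`);
* `inv`, `t` (two- and three-way), `rob` (and the equivalent whole-arm
  `der(a;b)(q10;q10)` spelling), `del` (terminal and interstitial), `dup`,
  `i` (whole-arm only), `psu dic`, `der` with embedded translocation detail,
  `add`;
* the polymorphic length-variant tokens `1qh+`, `9qh+`, `16qh+`, `Yqh±`,
  and `ps+`/`pstk+` on the acrocentrics.

Assumptions worth stating explicitly:

* **Band designations are stored verbatim.** Breakpoints are (chromosome,
  arm, band-string) triples; no ideogram coordinate resolution or sub-band
  arithmetic is attempted. Cohort summaries aggregate by chromosome only.
* **Masked sex (`XN`)** is accepted and never participates in an
  abnormality; it occurs in reports that suppress fetal sex, classically
  with inv(9).
* **Modal-number consistency** is enforced only for clones whose
  abnormalities are purely numerical (so `46,XX,+21` is rejected as
  malformed), because structural tokens shift the count in
  notation-dependent ways (an isochromosome replaces a homolog, a
  Robertsonian fuses two).
* **Unsupported ISCN** (`fra`, `ins`, rings, non-pseudo dicentrics, FISH
  nomenclature, …) raises a dedicated condition class rather than a generic
  syntax error, so batch pipelines can separate "malformed" from "outside
  scope".
* Formatting emits a canonical spelling (normalised case and spacing,
  original token order); parse–format–parse is the identity on the parsed
  structure, which the test suite checks property-style on generated
  cohorts.

## The four-level classification

Each parsed karyotype is annotated hierarchically:

1. **Mosaicism.** A result is *mosaic* when at least two genetically
   distinct cell lines coexist — distinct in modal number, sex complement or
   abnormality set; cell counts are ignored, and no minimum-percentage
   threshold is applied. A single clone whose only findings are in the
   polymorphism set (inv(9), qh/ps/pstk variants) is a *polymorphism*; a
   single 46-count clone with no finding is *normal*; everything else is
   *non-mosaic* abnormal. Two special cases: the pure `46,XX/46,XY` pattern
   is hermaphroditism (a chimera, not somatic mosaicism) and is routed to
   the non-mosaic class; the same two clones plus any further abnormality
   are ordinary mosaicism.
2. **Structural class.** Every abnormality maps to a category; the full
   label set is retained and one *primary* label is reported using a fixed
   precedence: hermaphroditism > triploid > aneuploidy > Robertsonian >
   translocation > derivative > psu dic > isochromosome > deletion >
   duplication > addition > inversion > structural aberration > length
   polymorphism > normal. The precedence mirrors how mixed cases are
   conventionally tabulated (aneuploidy with a co-occurring structural
   change counts as aneuploidy); because the full set is kept, no
   information is lost to the tie-break. inv(9) is classified as an
   inversion at this level even though Level 1 calls the sample a
   polymorphism — the two levels answer different questions.
3. **Chromosome involvement.** The union of chromosomes over all
   abnormalities (markers keep the label `mar`). Hermaphroditism, triploidy
   and normal results involve no specific chromosome and carry the `None`
   sentinel — and only those three do, an invariant the tests enforce.
4. **Balance.** Material-neutral changes — inversions, reciprocal
   translocations, Robertsonian fusions with intact long arms, and all
   polymorphisms — are *balanced*; any gain or loss (aneuploidy, deletion,
   duplication, addition, non-Robertsonian derivative, isochromosome,
   psu dic, marker, triploidy, hermaphroditism) makes the sample
   *unbalanced*. Three-way translocations are treated as balanced when
   material-neutral; their pair tallies are flagged separately so a user
   can audit them.

## Breakage events

A breakage event is a recorded breakpoint outside the centromere. The
centromere is identified purely by band designation `10` (p10/q10); bands
`11`, `11.1`, … *count*, so pericentric inversions such as `inv(Y)(p11q11)`
contribute two events — this is what puts Y at the top of per-chromosome
break tallies in amniocentesis series. Consequences of the convention:
inversions contribute 2 events, reciprocal translocations 1 per involved
chromosome, interstitial deletions 2 and terminal deletions 1, duplications
2, additions 1, whole-arm isochromosomes and Robertsonian translocations 0.
Whether a duplication should count one or two breaks is not settled usage;
counting the two segment boundaries is the documented convention here.
Derivatives inherit the breakpoints of their embedded translocation;
`der(7)` without detail contributes none. Length-variant tokens carry no
breakpoints at all. Identical abnormalities shared by several clones of one
fetus count once.

At cohort level, fetuses with at least one event are stratified by Level-1
class; the polymorphism stratum is exactly the inv(9) carriers. The three
strata sum to the total by construction, and the tests assert this
additivity on every generated cohort.

## Indication rules

Referral categories follow the standard definitions, with cutoffs:
advanced maternal age ≥ 35 years at the estimated due date (inclusive — "at
or beyond"); serum risk strictly above 1/270 (trisomy 21) or 1/350 (trisomy
18), AFP strictly above 2.5 MoM; NT strictly above 3.0 mm; NIPT Z-score
strictly above 3 for trisomies 21/18/13; plus the boolean ultrasound,
family-history, monogenic, cord-blood and adverse-history flags. `others`
fires exactly when nothing else does. Boundary behaviour is deliberately
strict on the screening cutoffs and inclusive on age, matching the rules'
phrasing; the tests pin all six boundaries.

One sample gets one reported indication. No published tie-break exists, so
the default precedence (ultrasound > NT > NIPT > serum > parental
chromosomal abnormality > prior affected pregnancy > monogenic > parental
intellectual disability > cord blood > adverse history > advanced maternal
age > others) encodes "most specific finding first, demographic risk last"
and is a plain argument to `primary_indication()`; any permutation can be
supplied.

## Rates and rounding

All percentages are `round-half-up(100 · count/denominator, 2)`. Half-up
(not R's default half-even) is what clinical tables use: under it, every
published fraction/percent pair the package emulates recomputes exactly
(e.g. 353/38,636 → 0.91). A guard of 1e-9 absorbs binary representation
error in the quotient without affecting genuine sub-half values. One known
exception is documented rather than matched: 1,557/38,636 rounds to 4.03,
while the emulated source prints 4.02 — a truncation, which `rate()` does
not reproduce. Denominators are always *successfully karyotyped* samples;
`classify_cohort()` carries failed cultures as `NA` and the rate functions
refuse to run until they are excluded, so the exclusion is explicit in user
code.

## The synthetic-cohort generator

The study data the package is designed around are not public, so the
generator is a first-class module: it emits cohorts whose categorical
structure matches the published rates, with per-sample ground-truth labels
that equal `classify(parse_karyotype(k))` by construction (a property the
suite checks on 10,000 draws).

Defaults, fixed once and not tuned thereafter:

* Level-1 mix 4.68 / 0.71 / 1.70 / 92.91 % and a 16/38,652 culture-failure
  rate.
* Within non-mosaic abnormals, category weights from the published counts
  (1,338 aneuploidies, 97 Robertsonian, 70 non-9 inversions, 64 deletions,
  6 isochromosomes, 187 translocations-plus-derivatives); within mosaics
  219 aneuploidies, 31 translocations/derivatives, 8 deletions, 13
  isochromosomes, 2 inversions (chromosome 11). Where the source only
  reports a pooled number, the split is a documented plausible default: the
  187/31 translocation-plus-derivative cases are split 150/37 and 25/6, and
  the small residual categories are set to 12 duplications, 10 additions, 6
  psu dic, 15 triploids, 3 hermaphroditisms. No `structural_aberration`
  (catch-all) cases are generated, since the supported grammar has no token
  that classifies there.
* Aneuploidy chromosome shares differ by stratum (21-led non-mosaic,
  X-led mosaic), reproducing the sex-chromosome bias of mosaicism;
  Robertsonian pairs use the 11 observed types (13;14 dominant), reciprocal
  pairs mix recurrent types (11;22 first) with uniformly random autosome
  pairs; deletion, inversion and isochromosome chromosome weights follow
  the reported per-chromosome counts; polymorphisms are inv(9) with
  probability 353/655, otherwise a length variant with Y-led chromosome
  weights.
* Mosaics are two clones — the abnormal line plus a normal one — with cell
  counts uniform on 3–30 (no published cell-count data exist; the range
  brackets common colony counts).
* Indication mixes interpolate linearly between 2010 and 2024 endpoints
  (serum screening declining, NIPT/NT/ultrasound rising, advanced maternal
  age dominant throughout) and are sampled per year; maternal ages are a
  two-component mixture straddling the 35-year cutoff so the age rule is
  exercised on both sides. Years are uniform over 2010–2024 excluding 2017
  (no samples were collected that year in the emulated series); per-year
  sizes are only partially published, so uniformity is the documented
  default.

What the generator deliberately does **not** emulate: correlations between
indication and karyotype outcome (only marginal rates are published, so
records and karyotypes are drawn independently — the unbalanced-by-NIPT
enrichment seen in real data will not appear), maternal-age-dependent
trisomy risk curves, clone-count distributions beyond two, and any
within-year temporal structure. Passing tests therefore demonstrate that
the *pipeline* is correct and that configured frequencies are recovered —
not that real biological joint distributions are reproduced.

Determinism: the seed fixes the entire cohort byte-for-byte; all
randomness flows through R's RNG seeded once per `generate_cohort()` call.

## Numerical and degenerate-input choices

* Probability vectors must sum to 1 within 1e-9 and are validated before
  any sampling; invalid weights fail fast.
* `rate()` refuses zero denominators rather than returning a silent 0;
  `level1_table()` refuses empty cohorts.
* Empty label subsets (e.g. `category_rates(cl, "deletion")` on a cohort
  with no deletions) return zero-row tables, not errors.
* Query results are ordered by descending occurrence count then
  lexicographic karyotype, so output is stable across platforms.
* Classification is memoised per distinct string inside
  `classify_cohort()`; a 38,636-sample cohort (a few hundred distinct
  strings) classifies in about a second.

## Problem sizes used by the test suite

Unit and property tests run on cohorts of 1,000–30,000 samples; the
end-to-end checks use the full emulated scale of 38,636 samples, at which
the recovered non-mosaic and mosaic percentages are required to fall within
three binomial standard errors of the configured 4.68 % and 0.71 %
(± 0.32 and ± 0.13 points). Label-recovery is checked on 10,000 abnormal
draws across every category, and the query engine against a linear-scan
oracle on stores built from tens of thousands of samples. These sizes were
chosen so each property is tested well past where estimator noise could
hide a defect.

## Known limitations

* The grammar subset excludes `fra`, `ins`, rings, true dicentrics and FISH
  nomenclature; such strings are rejected with an explicit
  unsupported-notation condition rather than misparsed.
* Breakpoint summaries are per chromosome only; band-level hotspot analysis
  would require ideogram-aware coordinates the data model deliberately
  omits.
* No clinical interpretation: the package classifies notation, it does not
  call pathogenicity, parental origin, or confined placental mosaicism.
* Low-level pseudomosaicism is not adjudicated; any two distinct clones
  make a mosaic.
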