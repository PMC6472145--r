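---
title: "Mining marginal-significance reporting: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining marginal-significance reporting: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(margex)
```

## The estimand

When a test returns .05 < p ≤ .10, authors sometimes soften the verdict:
"marginally significant", "approached significance". `margex` measures the
prevalence of that practice in a plain-text article corpus at two levels:

* **p-value level** — of the p-values in (.05, .10], what percentage is
  accompanied by marginal language within ±200 characters? Because this
  percentage is *conditional on range membership*, it is insensitive to
  anything that shifts the p-value distribution (power, p-hacking,
  reporting volume). It is the more interpretable outcome.
* **article level** — of the articles containing any p-value, what
  percentage has at least one in-range p-value reported as marginal? The
  denominator is deliberately *all* articles with p-values, not just those
  with in-range values; an article with fifty p-values has a mechanically
  higher chance of containing one in-range value, so trends in this outcome
  confound reporting style with reporting volume. The package computes it
  because the literature does, and the two-level contrast is itself
  informative.

Both percentages carry 95% binomial confidence intervals — descriptive
summaries, not inferential tests: the sampling units are neither random nor
independent (one journal belongs to several disciplines, one article
contributes many p-values).

## Extraction grammar

The p-value report grammar is: a standalone `p`/`P` token (no adjacent
letter or digit), optional whitespace/markup remnants (`*`, `_` — HTML
conversion residue), a comparison sign, a number. Choices the source
method descriptions leave open, each a documented flag:

* plural `ps` is **not** matched by default (`match_plural_ps`);
* `<=`, `>=`, `=<`, `=>`, `≤`, `≥` are matched and canonicalised to
  `<=`/`>=` (`extended_signs = FALSE` restricts to `<`, `>`, `=`);
* exponent forms (`6e-05`) parse; a bare `.` is matched but carries the
  invalid marker, so the non-numeric filter can count it rather than lose
  it silently;
* values above 1 (misreports like `p=1.2`) parse as printed and are left
  for the range filter — misreports *inside* the range (`.099` meant as
  `.99`) are indistinguishable and stay, a known property of the method.

Offsets are 0-based character (not byte) indices; windows are counted in
characters and truncated, never padded, at document boundaries. Matching is
left-to-right and non-overlapping.

## Exact range boundaries

The filter keeps .05 < p ≤ .10 *on the printed decimal*. Binary floating
point cannot represent .05 or .10 exactly, so boundary comparisons use an
exact digit-string comparison of the printed number (`value_in_range()`);
`.05`, `0.0500000` and `5e-02` are all excluded, `.10`, `0.100000` and
`1e-01` all included, at any printed precision. The sign is ignored: a
value of exactly .05 is excluded whether reported as `<`, `>` or `=`.

## Classification and the window boundary

A mention is "reported as marginally significant" iff a word starting with
`margin` or `approach` (case-insensitive; both flags configurable) occurs
in either captured context window. `margin*` is read as a glob-style stem,
word-initial: preceded by a non-letter or the window start, continued by
letters only. This reproduces the deliberately minimal two-stem method,
false positives included ("profit margins" counts); extending the stem
list is supported but changes the estimand.

The classifier is a pure function of the two captured context strings and
sees nothing else. One boundary subtlety follows: a stem is found iff it
lies *entirely* within the window. On the before side, a stem whose first
character falls just outside the 200-character window arrives truncated
("argin…") and cannot match. The package fixes whole-stem-in-window
semantics on both sides — exact at 200 versus 201 characters, and
property-tested — because a pure context-window search admits no other
consistent reading.

## Filter cascade

Stages, applied in order, each row counted at the first stage that claims
it (so the stage counts partition the input):

1. *missing metadata*: DOI, journal **and** year all absent (rows with
   partial metadata go to the resolver instead);
2. *non-numeric*: the printed value failed to parse;
3. *core journal*: journals unique to a general/interdisciplinary "core"
   topic, which is not a discipline;
4. *out of range*: everything not in (.05, .10].

Discipline flags are multi-membership: a journal in two disciplines
contributes its rows fully to both, so discipline counts may sum to more
than the overall count (equality iff no journal is shared). The stratified
6%-per-journal test sample rounds half-up per stratum (documented choice;
the source is silent) and restores the caller's RNG state.

## Confidence intervals

No CI method is named by the tables this package mirrors; back-derivation
settles it. The Wald interval on the percentage scale,
100·(p̂ ± 1.96·√(p̂(1−p̂)/n)) with n the in-range count (p-value level) or
the count of articles with p-values (article level), reproduces all ten
published p-value-level brackets at 2 d.p. once the rounding of the
printed point estimate is accounted for (from the printed 2-d.p.
percentages alone, 7 of 10 reproduce exactly; the other three shift by one
final digit — back-deriving through the integer numerators consistent with
the printed percentage reproduces 10 of 10). Wald is therefore the
default; Wilson is available (`ci_method = "wilson"`) and preferable near
0% or 100%. Bounds are clamped to [0, 100]; cells with a zero denominator
report missing, never 0.

## Trends

Yearly series take the percentage per calendar year, omitting (not
zero-imputing) years with an empty denominator; rows with unresolved year
are excluded from yearly cells but kept in all-years cells. The trend is
an unweighted simple least-squares regression of percentage on year
(weighting by yearly p-value counts is available via `fit_trend(weights=)`
but is not the default, matching the unweighted convention). Slopes are in
percentage points per year; the intercept is also reported at a 1985
origin for readability. The slope SE is computed from the residuals
directly, so exact synthetic lines fit without spurious warnings.

## The synthetic world

`generate_corpus()` emits what the pipeline is built for: article bodies of
stem-free filler prose interleaved with p-value reports in the supported
grammar. Defaults mirror the corpus the method targets: years 1985–2016,
Poisson(17.59) reports per article, 5.5% of values in (.05, .10] (drawn
uniformly on a .001 grid — the p-value-level outcome is conditional on
range membership, so the in-range shape is immaterial), theta_marginal =
0.396, signs 40/50/10 for `<`/`=`/`>`, DOIs present with probability
0.999, ~1% gross misreports (`1.2`), a 10-journal panel with one
core-only journal, one two-discipline journal and two historical aliases,
0.5% resolvable metadata gaps, and a 2% decoy rate. These constants were
fixed from the published summary figures (or, where unpublished, from what
a corpus of this kind plausibly looks like) before any acceptance
measurement and are not revisited.

Ground truth records every report's exact character offset and whether a
stem-bearing phrase was placed entirely inside its window (distance
sampled so the whole phrase fits) or a decoy outside it (distance
201–400; or inside, when `decoy_in_window = TRUE`, to quantify the
method's false-positive channel). Consecutive reports are separated by at
least 450 filler characters so windows of distinct mentions never capture
each other's phrases; on a clean configuration extraction recall,
precision and label agreement are exactly 1 and are asserted as such.

What the generator does **not** emulate — and hence what a green test does
not establish: real HTML-conversion noise beyond `*`/`_` remnants,
reference sections, tables, the 508-phrasing diversity of real marginal
language (two stems only), p-value report formats outside the grammar, or
correlation between an article's p-value count and its reporting style.
Perfect recall on synthetic text is a *closure* property (the generator
emits only what the grammar accepts), not an estimate of recall on real
articles.

## Parameter recovery, sized honestly

With theta_marginal = 0.4 and ≥5,000 in-range p-values surviving the
cascade, the pipeline estimate must sit within 3 binomial SEs of 40%; with
a generated linear drift in theta (0.01/year, i.e. 1 percentage point per
year), the OLS slope must sit within 3 SEs of the generating slope. Corpus
sizes in the acceptance tests were chosen by expectation arithmetic
(including the ~8% of rows lost to the core-journal and metadata stages),
not by adjusting anything after seeing an estimate.

## Known limitations

* CSV record files cannot distinguish a free-text value `"NA"` from a
  missing value; the JSONL route is lossless and is the one the round-trip
  property test exercises for arbitrary content.
* The two-stem classifier undercounts real marginal language and counts
  stem-bearing decoys; `truth_compare()` quantifies the decoy channel but
  no semantic disambiguation is attempted — faithfully mirroring the
  method.
* Live DOI resolution is out of scope; `complete_metadata()` takes any
  injectable resolver and treats per-DOI failures as loggable, not fatal.
* Published headline percentages that depend on the full 44,200-article
  corpus are not reproducible here and are not claimed; the acceptance
  suite validates the arithmetic and CI machinery on the published summary
  counts, and everything else on synthetic ground truth.
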