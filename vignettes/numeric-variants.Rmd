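---
title: "Numeric lexical variants in clinical notes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Numeric lexical variants in clinical notes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinnum)
```

## The problem

Clinical notes write numbers in many surface forms. A staging may appear as
"stage 3", "stage III", or "stage 3B"; an ordinal as "3rd" or the
typo "3nd"; a Roman numeral in its canonical subtractive spelling ("IV") or
an additive one ("IIII"); a date may not exist on any calendar ("June 31");
a stated age may exceed any documented human lifespan ("135 year old"). For
information extraction these variants are noise; for cohort identification
they are worse, because a free-text search for one spelling silently misses
every patient whose notes use another. This package implements that whole
chain of reasoning as testable code: generate the variants, detect and
normalize them, search a note corpus exactly, and quantify what a
single-variant search misses.

## The missed-percentage statistic

Let two query phrases denote the same concept with different numeric
variants (phrase 1 Arabic, phrase 2 Roman, by convention). At the patient
level the combined cohort splits into three disjoint parts:

* $b$ — patients matched by phrase 1 only,
* $d$ — patients matched by both,
* $e$ — patients matched by phrase 2 only.

With $N = b + d + e$ the union cohort, the percentage of the cohort missed
by a single-variant search is

$$c = 100\,e/N \quad\text{(searching only phrase 1)}, \qquad
  f = 100\,b/N \quad\text{(searching only phrase 2)}.$$

Before rounding, $c + f + 100\,d/N = 100$ exactly. Percentages are rounded
half-away-from-zero to one decimal; this rule is verified in the test suite
against all twenty published percentages of the ten-pair cohort experiment
that `run_table18_demo()` re-renders from its shipped patient-count
triples. An all-zero triple raises an error rather than reporting 0%,
because a silent zero is indistinguishable from a broken search.

`union_size()` and `intersection_by_inclusion_exclusion()` provide the
derived arithmetic (e.g. two searches of 69 and 67 patients with a union of
109 share only 27 patients), and `count_majority_missed()` counts pairs
whose larger missed percentage strictly exceeds a threshold.

## Generators and detectors

Every variant category has a deterministic generator emitting
`surface_form` records (lowercase text, category, canonical value,
validity) and `classify_surface()` inverts all of them. Validity
distinguishes two failure modes: `malformed` strings have a well-formed
counterpart with the same value ("iiii" vs "iv", "1rd" vs "1st",
"one thirds"), while `invalid_value` strings are well-shaped but denote an
impossible value (June 31, a 135-year-old patient).

Numerical and linguistic choices that were genuinely open:

* **Lenient Roman parsing.** Strict mode accepts only the canonical
  subtractive spelling. Lenient mode scans the string into units (the six
  standard subtractive pairs, else single symbols) and requires unit values
  to be non-increasing; the value is the unit sum. This is the simplest
  rule that values the observed additive series IIII…IIIIIIIII as 4…9
  while still rejecting scrambled strings like "IIX". Generation is capped
  at 3999, the standard boundary of subtractive notation.
* **Calendar policy.** The studied date patterns carry no year, so
  February 29 is undecidable; the default `lenient_feb29` policy accepts
  it and `strict_feb29` rejects it. Both policies are checked against an
  independent calendar oracle (base R's `Date` parser) over the full
  month × day(1–39) grid.
* **Age plausibility.** The default bound is 122 years, the longest
  documented human lifespan; it is a parameter, not a constant, since
  surveillance tasks may want tighter bounds.
* **Decade terms.** The lexicon starts at quinquagenarian (50–59); ages
  below 50 return `NA` rather than inventing terms with no attested use.
  Open-ended brackets overlap, so lookup prefers the most specific term
  (supercentenarian over centenarian at 110+).
* **Classification compounds.** "iiib" is parsed as Roman "iii" + letter
  "b" only when the whole token is not itself a readable Roman numeral;
  "iiii" therefore stays a malformed Roman numeral, and the generator
  refuses to emit Roman+letter compounds like "vi" (= "v" + "i") that
  collapse into numerals, because no detector could recover them without
  context.
* **Ambiguity is flagged, never resolved.** Single-letter Roman numerals
  and lexicon-listed lookalikes ("iv" intravenous, "3d", "va", …) are
  annotated with `ambiguous = TRUE` and their canonical value is withheld.
  Word-sense disambiguation is out of scope by design.
* **Annotation granularity.** `annotate_document()` scans left to right,
  longest span (up to four tokens) first, spans never overlapping. One
  deliberate exception: a multi-token classification phrase ("type ii") is
  not swallowed as a single span — the numeral token alone is annotated —
  so the annotation layer remains a pure number normalizer and the
  surrounding clinical words stay untouched. `classify_surface("type ii")`
  still returns the classification reading for whole-string queries.

## Tokenization and the index

The tokenizer lowercases and keeps maximal runs of letters and digits;
every other character, hyphens and colons included, separates tokens and is
dropped. This reproduces every distinction the variant analysis relies on:
"T2DM" is one token, "thirty-three" splits into two, "type iidiabetes"
cannot match "type ii diabetes". Stop words are indexed like any token —
in clinical text they double as acronyms (IS, AND, OR) — and phrase search
is exact consecutive-position matching with no slop, counting each document
once. Patient-level results aggregate document hits through the
doc-to-patient map (`patient_set()`); the package takes the position that
cohort counts are note-level search results aggregated to patients, and
documents that choice rather than claiming it matches any particular
production system. The index lives in memory (occurrence codes
`doc * 2^20 + position`) with a versioned plain-text snapshot format;
the intended scale is up to about a million synthetic notes on one
machine, not a production deployment.

## The synthetic corpus and its ledger

No clinical corpus ships with the package, so validation runs on synthetic
corpora whose ground truth is known by construction. `generate_corpus()`:

* draws notes per patient from a truncated geometric distribution
  (default mean 3, maximum 20 — a synthetic choice; no per-patient note
  distribution is published for the corpora this emulates);
* marks each patient as a concept carrier with the spec's prevalence, and
  injects one variant of the concept phrase (Arabic / Roman / spelled-out
  word, drawn per note from the spec's probabilities) into every note of a
  carrier — patients acquire "both variants" status naturally by having
  several notes;
* appends standalone error-form sentences ("iiii", "1rd", "june 31",
  "135 year old") at small per-note rates so their detection is
  independently ledgered;
* builds filler text from a fixed clinical-flavored vocabulary from which
  every token of every injectable phrase is removed, so injected phrases
  cannot arise by accident; a post-generation scan asserts this;
* records every injection in a `ground_truth_ledger`.

All randomness flows through R's RNG seeded once per run, so a fixed seed
reproduces the corpus byte for byte. The default study conditions
(`default_specs()`) are two concepts: "stage 3 chronic kidney disease" at
prevalence 0.10 with variant mix 0.60/0.35/0.05, and "type 2 diabetes
mellitus" at prevalence 0.20 with 0.80/0.15/0.05. The package's own
experiments run at 2,000 patients, with variant-rate recovery checked over
50 seeds against the configured probabilities (within three binomial
standard errors of the pooled mention count).

What passing these tests shows — and does not. The ledger-identity test
proves the pipeline (tokenize, index, phrase-search, patient-aggregate,
overlap) is exact: whatever was injected is recovered, with zero
tolerance. It does not show that real clinical text is this clean: real
notes have copy-paste duplication, ambiguous abbreviations in context,
spelling errors, and phrase variants beyond the twelve modeled categories.
Corpus-specific frequency counts from any particular health system are
therefore not reproduced here; only the arithmetic of the published cohort
experiment is, from its printed patient counts.

## Limitations

* English only; no spelling-error variants ("sevin") and no unit variants
  ("lbs", "#").
* No word-sense disambiguation; ambiguous tokens are only flagged.
* `expand_phrase()` supports at most one numeric token per phrase;
  expressions like "2 by 4" contain two and are rejected as unsupported
  rather than guessed at.
* The tokenizer approximates a standard search-engine tokenizer on the
  constructs studied here; URL/email edge behavior and constructs like
  "2/2" simply follow the stated separator contract.
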