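---
title: "Soft tagging for cross-species gene normalization: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soft tagging for cross-species gene normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genenorm)
```

# The problem and the approach

Gene normalization links a textual mention of a gene or gene product to a
database identifier. Two things make the full-text, cross-species setting
hard: mention *boundaries* are ambiguous (is it "Na,K-ATPase" or
"Na,K-ATPase beta"? — they resolve to different records), and the same
name may belong to several species. A tagger that commits to one boundary
per mention loses recall that no downstream step can recover.

`genenorm` keeps the boundary question open as long as possible. The
tagger emits *overlapping* candidate mentions ("variants") from many
plausible labelings, a separate evaluator scores each variant's
probability of being curator-acceptable, and only then do filtering,
species assignment and dictionary matching commit to identifiers. The
package calls this soft tagging.

# Sentence and token model

Articles arrive as PMC-style XML (or plain text). All `sec` elements under
the body are flattened depth-first, each contributing its direct `p`
children; sections carrying a `sec-type` attribute (Methods, References,
...) are excluded from the normalization input, since such sections name
many genes peripherally. Section titles are likewise excluded — fixture
tests use body text only.

Sentence segmentation is a deliberately simple rule: split after `.?!`
followed by whitespace and an uppercase letter or digit, with a stop-list
of abbreviations (`et al.`, `e.g.`, `Fig.`, single initials). It is
deterministic, dependency-free and easily testable; segmentation errors
merge or split sentences but never corrupt character offsets, which are
0-based half-open at every level.

Tokenization is fine-grained: maximal runs of letters, maximal runs of
digits, and every other non-space character alone (`IL2R` → `IL`, `2`,
`R`). This maximizes boundary options for the tagger. "Letter" includes
non-ASCII letters, so Greek characters in names survive.

# The n-best CRF tagger

A linear-chain CRF over labels `{B, I, O}` with per-label weights for
sparse indicator features plus a 3×3 transition matrix and a start vector.
Feature templates: word identity, lowercased word, character prefixes and
suffixes of lengths 2–4, orthographic shape flags (case pattern, digits,
punctuation, letter–digit mixtures), and lowercased words at offsets −2..+2.
Part-of-speech templates are deliberately absent; the templates above are
reproducible without an external tagger and carry the signal that matters
for gene names (case/digit shape and local lexical context).

Training maximizes the L2-penalized conditional log-likelihood with
L-BFGS-B from a zero start — fully deterministic. The gradient comes from
standard forward–backward marginals. The penalty weight (`lambda`,
default 1; the shipped test models use 0.3) matters little at fixture
scale.

Decoding is exact k-best Viterbi: each lattice state keeps a ranked list
of the best k prefixes (the max-product lattice generalized from "best"
to "k best"), merged at each step. Two numerical choices:

* **Tie-breaking.** Equal-score labelings are ordered lexicographically
  with `B < I < O`. Scores are compared at 1e-9 resolution first, because
  mathematically identical path sums accumulate floating-point error in
  different orders; without the rounding, "ties" would be ordered by
  noise. This makes decoding reproducible and lets an enumeration oracle
  check it exactly.
* **Label validity.** Decoding ranks *all* label sequences, including
  invalid `O → I` transitions (a trained model makes them unlikely, not
  impossible). Strict consumers (`ibo2_to_mentions()`) reject invalid
  sequences; variant extraction first applies `ibo2_repair()`, which
  reads a stray `I` as `B` — the common IOB repair.

The backward model is trained and decoded on reversed token sequences.
Mention spans are mirrored and re-encoded as valid IOB2 in the reversed
reading order (naively reversing a label string would put `I` before
`B`), and decodings are mapped back to sentence order before use. Forward
and backward solutions are concatenated — 40 at the defaults — with
duplicates retained: the duplicate count is signal, not noise, because
variant frequency is measured over this multiset.

# Variants and their confidence scores

Every distinct `(text, span)` across the combined solutions is one
variant; identical text at two positions is two variants, because spans
are what dictionary matching and overlap resolution consume. Its
*frequency* is its occurrence count divided by the number of combined
solutions (not a hard-coded 40, since k is configurable).

The evaluator is ridge logistic regression (`glmnet`, `alpha = 0`), with
the penalty chosen by 5-fold cross-validation on misclassification error
under a fixed fold seed. Features: the continuous frequency; nine
morphological flags; binary indicators for the variant's content tokens
(lowercased, punctuation deleted — "removing punctuation" means deleting
non-alphanumeric characters before tokenizing); and binary indicators for
the two sentence tokens on each side. The binary vocabulary is whatever
the training data contains (frequency floor 1); unseen tokens at
inference simply activate nothing. Training labels are exact-span
matches: a variant is positive iff its span equals a curator-identified
mention or an explicitly acceptable alternative span. Overlap is not
enough — span identity is the whole point of boundary scoring. (Whether
"unique instance" should mean unique text rather than unique span is a
genuine ambiguity; span identity is used consistently here.)

Filtering keeps variants with score ≥ threshold. The default threshold of
0.2 favors recall into the dictionary stage; raising it trades recall for
precision, and retained sets are nested as the threshold rises — the
property the test suite asserts across a sweep. For hard gene-mention
output the package also provides the recursive selector: pick the
globally maximal-score variant (ties: longer, then leftmost), discard
everything overlapping it, recurse. Its output is an independent set in
the overlap graph; note that a later pick may overlap a *discarded*
higher-scoring variant — that is the recursion's defined behavior, and
the exhaustive test checks exactly that definition.

# Abbreviation veto

Definition pairs are detected with the Schwartz–Hearst character
alignment: a parenthesized short form (2–10 characters, ≤ 2 words,
starting alphanumeric) is aligned right-to-left into at most
min(|short| + 5, 2·|short|) preceding words, requiring the short form's
first character to begin a long-form word. A learned detector could
substitute here; the veto rule — the part that matters — is agnostic to
the detector. The rule: if a definition sentence has the short form
tagged but no retained variant overlapping the long-form occurrence
(boundary variants of the long form count as tagged), every variant in
the article whose text equals the short form is removed. Removal is
exact-text and case-sensitive; case-insensitive removal would also strip
legitimate genes that share letters with the abbreviation.

# Species designation

A two-column name → TaxID dictionary (first occurrence wins on
duplicates) is scanned longest-match with word boundaries. Matching is
case-insensitive for multi-word or longer names but case-sensitive for
names of ≤ 4 characters, so genus abbreviations do not fire inside
ordinary words.

Rules, in precedence order:

1. a species name inside the variant; else the *nearest preceding*
   mention in the same sentence (rule 1 must be tighter than the
   sentence-wide rule 2, so "preceding" is scoped to the sentence); else
   a single-letter prefix (`h`, `y`, `m`, `r`, `d`) — only when followed
   by an uppercase letter or digit (`hTAK1` yes, `humidity` no);
2. the mention nearest to the variant anywhere in the same sentence
   (nearest, not first — a paper-level gap resolved here in favor of
   locality);
3. the most frequent species in the article, ties broken by first
   occurrence — this guarantees every variant in a species-bearing
   article is assigned.

Variants in articles with no species mention at all are dropped (with a
warning) unless a default TaxID is configured. Rule subsets are runnable
(`rules = c(1)`, `c(1,2)`, ...) for ablation; on fixtures, recall is
non-decreasing as rules are added.

# The gene dictionary

Records come from a `gene_info`-layout table: one record per (row, name
column, pipe-separated name) over Symbol, Synonyms, dbXrefs (stripped of
their `SOURCE:` prefixes), description, the two nomenclature-authority
columns and Other designations.

Name normalization applies five rewrite rules in order — split an
uppercase run (≥2) from a following lowercase run (≥2); the converse;
replace every character that is not a word character (except `.`) with a
space; space-delimit digit/dot runs; collapse whitespace — then
lowercases. The third rule's character class is stated in a Java-dialect
regex in the source material and is ambiguous as printed; the
interpretation here ("anything outside `[\\w.]` becomes a space") is the
one that reproduces the worked `IL1-ALPHA → il 1 alpha` behavior, and
tests pin it. Normalization is idempotent.

Queries attach interchange classes per token: Arabic numerals alternate
with Roman numerals, Greek-letter words with their Latin initials, and
vice versa. Roman conversion is algorithmic over 1–3999 (base R
`as.roman`) rather than a small lookup table: the worked `p53` case
requires `53 ~ liii`, which a 1–20 table would miss, and the algorithmic
form is no less testable.

Retrieval returns records of the designated TaxID sharing at least one
token with the query, ranked by Dice token overlap under the interchange
classes and truncated at 50. The scoring is a token-overlap stand-in for
a full-text engine's ranking, and deliberately so: only two properties
are load-bearing and tested — a record whose normalized name token-equals
the query scores exactly 1 (top rank), and the cap. Correctness lives in
the next step: an **anchored** regex built from the query (all tokens in
order, each through its alternation set, nothing extra) filters the
candidates. Anchoring at both ends is essential — a substring match would
keep `IL-1R-alpha` for the query `IL-1 alpha`.

Resolution: a unique surviving GeneID is assigned; with several, the
best-ranked candidate from an authority column (Symbol, AuthorizedSymbol,
the nomenclature-authority symbol/full-name columns) decides; otherwise
the list is ignored. Within an overlap group, at most one GeneID is
emitted: that of the longest resolved variant (ties: higher confidence,
then leftmost) — the longest variant carries the most boundary
information. Per article, one row per GeneID, keeping the maximum variant
confidence as the score: confidence is the ranking signal downstream, and
the maximum preserves it under aggregation. A configurable TaxID-redirect
map handles dictionary-version migrations (e.g. a yeast TaxID moving
between releases); deeper version reconciliation is out of scope, as is
approximate string matching, which manufactures ambiguities the anchored
filter exists to avoid.

# Evaluation

Precision/recall/F are micro-averaged over (article, GeneID) pairs — the
shared-task convention — with macro-averaging switchable. TAP-k truncates
each article's score-ranked list at its k-th false positive (or the list
end), adds a terminal precision-at-cutoff term to the truncated average
precision, and divides by (gold count + 1); articles average equally.
With short output lists the k-th false positive often never arrives, so
TAP-5/10/20 coincide — an emergent behavior of short lists, observed on
fixtures but not asserted. An exhaustive test checks TAP-k against an
independent hand-trace on every ranking of length ≤ 6.

# The synthetic generator

`corpus_spec()` / `make_tagged_corpus()` generate, as a pure function of
the spec: articles of template sentences with planted mentions (valid
IOB2 labels, exact offsets), curator-acceptable sub-span alternatives,
species mentions with the focus species in the article majority,
single-letter prefix forms, abbreviation definitions whose long forms
align by construction, non-gene decoy abbreviations (`MRI`, `PCR`, ...),
cross-species ambiguous names at a configurable rate, sibling names
differing only in a trailing Greek token, and candidate spans at a
configured ~1:3 positive:negative ratio for scorer training.
`make_gene_dict()` / `make_species_dict()` write matching dictionaries,
including the shipped worked-example records (with the one misprinted
synonym available verbatim or corrected, in separately named fixtures).

Defaults (200 sentences, 30 genes, species rate 0.5, ambiguity rate 0.1,
acceptable-alternative rate 0.6) are chosen to make every pipeline stage
exercise its contract at desk scale. The test suite trains on a
120-sentence corpus and sweeps thresholds on a 1000-sentence corpus —
sizes chosen so properties are measurable with stable margins.

What the generator does *not* emulate: real nomenclature drift and
misspellings, descriptive multi-clause names, figure/table captions, PDF
artifacts, genuine distributional ambiguity requiring contextual
disambiguation, and corpus-scale class imbalance. Passing fixtures
therefore demonstrates that the machinery implements its contracts — not
benchmark performance on curated corpora, which requires the external
corpora themselves.

# Known limitations

* No contextual disambiguation: when the anchored filter leaves several
  GeneIDs and no authority record, the list is dropped — precision over
  recall by construction.
* Species designation is lexical; cell-line or strain inference beyond
  name lookup is absent, and articles that never name a species yield
  nothing without a configured default.
* The dictionary ranking is not a calibrated relevance score; do not
  interpret candidate scores across queries.
* The CLI's `build-index` persists the index as an R serialization for
  reuse; all model artifacts, by contrast, are versioned flat text.
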