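# genenorm

Cross-species, full-text **gene normalization** (GN): linking every gene or
gene-product mention in an article to a standard gene database identifier
(an Entrez-style GeneID), for text-mining and bio-curation workflows where
articles span many organisms and mention boundaries are genuinely ambiguous.

## The method

Committing early to a single pair of mention boundaries loses exactly the
token (a trailing `beta`, a species word) that decides which dictionary
record matches. `genenorm` instead performs **soft tagging**:

1. **n-best CRF tagging.** Two linear-chain conditional random fields over
   IOB2 labels `{B, I, O}` — one reading the token sequence forward, one
   reading it reversed — each emit their top *k* = 20 label sequences by
   exact k-best Viterbi decoding, giving 40 solutions per sentence. Every
   maximal `B(I)*` run in any solution becomes an overlapping candidate
   mention *variant*.
2. **Variant confidence scoring.** A logistic-regression evaluator scores
   each variant in (0, 1) from four feature families: its frequency across
   the 40 solutions, nine morphological flags (has/starts/ends-with ×
   upper/lower/digit), content-token indicators and ±2 context-token
   indicators. Variants under a threshold (default 0.2) are dropped; the
   rest are kept *with* their overlaps.
3. **Abbreviation veto.** Short form/long form definition pairs
   ("N-acetyl-aspartate (NAA)") are detected by character alignment; a
   tagged short form whose long form was not tagged at its definition is
   removed article-wide.
4. **Species designation.** Each variant gets a taxonomy ID by precedence:
   a species name within or immediately preceding the variant (including
   `h/y/m/r/d` symbol prefixes), else one in the same sentence, else the
   article-majority species.
5. **Dictionary resolution.** Gene names from a `gene_info`-layout table
   are rewritten by five normalization rules (case folding, splitting
   letter-case and digit boundaries, punctuation to spaces) and indexed.
   A variant's query carries interchange classes (`1`~`I`, `alpha`~`a`),
   retrieves up to 50 candidates of the designated TaxID, and an anchored
   whole-name regex removes partial matches; a unique surviving GeneID (or
   one backed by an authority name column) is assigned. Per overlap group,
   the longest resolved variant wins; per article, each GeneID keeps its
   maximum variant confidence as the output score.

Everything trains and tests against a built-in synthetic corpus/dictionary
generator — no external downloads.

## Worked example

The retrieval worked example — resolving the variant `"IL-1 alpha"`
(designated TaxID 9606) against its printed candidate list:

```r
library(genenorm)
cand <- load_candidates(system.file("extdata", "il1a_candidates.tsv",
                                    package = "genenorm"))
q <- compile_query("IL-1 alpha", 9606)
print(q)
#> <gn_query> TaxID:9606 il {1|i} {alpha|a}
kept <- regex_filter(cand, q)
unique(kept$name)
#> [1] "IL1ALPHA"   "IL-1A"      "IL1A"       "IL1-ALPHA"  "IL-1 alpha"
resolve_candidates(kept)
#> [1] 3552
```

The anchored pattern keeps only whole-name matches (partial matches such
as `IL-1` and `IL-1R-alpha` are removed); all survivors share GeneID 3552,
which is assigned.

A full pipeline run over generated fixtures, via the bundled CLI
(`system.file("scripts", "genenorm", package = "genenorm")`):

```sh
genenorm make-fixtures --dir fix --sentences 60 --seed 5
genenorm train-tagger  --sentences 60 --seed 5 --out-prefix models
genenorm train-scorer  --sentences 60 --seed 5 --models models --out scorer.tsv
genenorm run --articles "fix/articles/*.xml" --models models --scorer scorer.tsv \
             --gene-info fix/gene_info.tsv --species fix/species.tsv --out pred.tsv
genenorm evaluate --pred pred.tsv --gold fix/gold.tsv
#>   precision    recall   f_score      tap5     tap10     tap20
#> 1         1 0.8571429 0.9230769 0.8777778 0.8777778 0.8777778
```

Each `pred.tsv` row is one (article, GeneID) with its confidence score and
provenance (variant text, span, TaxID, species rule); `evaluate` reports
micro-averaged precision/recall/F-score and threshold average precision
(TAP-k), which truncates each article's ranked list at its k-th false
positive.

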