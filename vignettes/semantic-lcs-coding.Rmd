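---
title: "Semantic-LCS coding of clinical diagnoses: model, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic-LCS coding of clinical diagnoses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcscoder)
```

## The coding problem and the model

Assigning ICD-10 codes to free-text diagnoses is a terminology-normalization
task: the query ("preliminary diagnosis") must be mapped to one entry of a
standard diagnosis library (SDL) whose names are standardized but whose
queries are not — clinicians abbreviate ("JIA GAN" for hepatitis A),
paraphrase with synonyms, drop or insert modifiers, and make small spelling
mistakes. `lcscoder` treats this as a ranked string-similarity problem over
*word* sequences:

1. segment the query and every SDL name into word tokens,
2. compute the longest common subsequence (LCS) between the two token
   sequences, counting a token pair as matched when its semantic similarity
   exceeds a threshold ε,
3. turn the LCS length into a normalized similarity,
4. output the best-scoring code, routed automatically or to manual review
   depending on its confidence.

The LCS is order-aware but gap-tolerant, which fits diagnosis names well:
modifiers may be missing or extra, but the relative order of surviving
medical terms is stable.

### The semantic LCS recurrence

For token sequences $A = a_1..a_m$, $B = b_1..b_n$:

$$
c[i][j] =
\begin{cases}
0 & i = 0 \text{ or } j = 0\\
c[i-1][j-1] + 1 & \operatorname{sim}(a_i, b_j) > \varepsilon\\
\max(c[i-1][j],\, c[i][j-1]) & \text{otherwise}
\end{cases}
$$

The two non-base branches are exclusive: when the similarity clears the
threshold the diagonal branch fires, otherwise the maximum of the two
neighbours is taken. For any *symmetric* token-similarity relation this
recurrence computes exactly the maximum non-crossing matching between the
sequences (the classic exchange argument never needs transitivity, because
two pairs using $a_i$ and $b_j$ separately would have to cross), so the DP
remains correct even though synonym similarity is not transitive. The test
suite checks this against an independent brute-force subsequence enumerator
on hundreds of random sequence/ontology/ε combinations.

The threshold test is strict (`>`), following the method's prose
description; `inclusive = TRUE` switches to `>=`, the behaviour of the
accompanying reference listing. At `ε = 1` nothing can match — similarities
are capped at 1 — so the LCS length is 0 by construction.

### Token similarity

The method's description never fixes $\operatorname{sim}$ concretely beyond
"synonyms or near synonyms from a disease ontology". We define

$$\operatorname{sim}(a,b) = \max(\mathbf{1}[a=b],\; w_{\text{group}}(a,b),\; d(a,b))$$

where $w_{\text{group}}$ is the largest weight of a synonym group containing
both surfaces (0 if none) and $d$ is an optional character-bigram Dice
fallback for small spelling variants (off by default). This covers the
three motivating error classes — synonyms, near-synonyms, spelling slips —
with one scalar each. No transitive closure is applied across groups: the
source material gives no closure rule, and closure would silently merge
distinct clinical concepts through chains of near-synonyms.

**Defaults.** Group weight 0.9 and ε 0.8 (both unitless, in (0,1]): the
weight must exceed ε or listed synonyms would never count as matches; 0.9
leaves room to down-weight weaker near-synonym groups while staying above
the threshold. Neither value reproduces an empirically reported number —
the experiments behind the method never state the ε used — so both are
explicit configuration.

### Similarity measures

With $LCSL = c[m][n]$ and lengths $L(A) \le L(B)$ (operands are swapped if
needed):

* LCS ratio: $LCSL / \max(L(A), L(B))$
* T-LCS: $2 \cdot LCSL / (L(A)+L(B))$
* W-LCS: $(LCSL+1) \cdot LCSL / (L(A) \cdot LCSL + L(B))$, defined as 0 at
  $LCSL = 0$ for continuity with the other two.

For every admissible triple $1 \le LCSL \le L(A) \le L(B)$,
$\text{W-LCS} \ge \text{T-LCS} \ge \text{LCS}$ (algebraically:
$(LCSL-1)(L(B)-L(A)) \ge 0$), which is the point of the weighting — it
stretches the upper range of scores so that a confidence threshold has more
resolution among good candidates. The package verifies the ordering
exhaustively up to length 12 and reproduces the published 20-row reference
table (L(A) 1–4) exactly at two half-up-rounded decimals. The reference
table's rows with L(A) ∈ {5, 6} are internally inconsistent with the printed
formulas (e.g. the L(A)=5, L(B)=6 LCS cell prints 0.81 where the formula
gives 5/6 ≈ 0.83); we treat them as typographical errors, flag them
programmatically in `paper_fixtures()$table3$consistent`, and exclude them
from regression. Notably the two diagonal rows (5,5,5) and (6,6,6) do
recompute correctly, so 22 of 30 rows carry a `TRUE` flag.

Two baselines are included for comparison: **word matching** (similarity 1
iff the token sequences are identical, the regime of exact lookup) and a
**token-bigram Dice** baseline. The bigram formula is not printed in the
source material; we use the standard Dice coefficient over adjacent token
pairs with start/end boundary markers added to *both* sequences — uniform
padding keeps length-0/1 sequences well defined and makes the measure 1
exactly on identical sequences.

## Segmentation

The built-in segmenter is deterministic forward maximum matching (FMM) over
a user-supplied lexicon, with single-unit fallback for uncovered spans and
a character-level mode. The original system used an external statistical
segmenter; we deliberately ship a lexicon FMM instead so that results are
reproducible without a third-party model — segmentation *accuracy* claims
are out of scope here, and the coding pipeline is agnostic to where tokens
come from.

Text is first normalized (Unicode NFC, case-folded, whitespace squeezed)
and split into **units**: a whitespace-separated chunk of ASCII is one unit
(in pinyin transcription one syllable stands for one Chinese character),
while CJK chunks split into per-character units. Lexicon matching runs over
unit sequences, so the two-character word "JIA XING" is one token in
transcription exactly as 甲型 would be in native text. At each position the
longest lexicon entry wins; ties on length cannot occur within a set of
distinct entries.

Stop-word filtering removes connective words (the bundled list contains
only "BAN"/with, the one connective the worked examples use) but always
retains negation words ("BU BAN"/without), flagging them on the token:
removing "without" would collapse "hepatitis A without hepatic coma" onto
its opposite and assign a wrong code with high confidence. Filtering is
idempotent and order-preserving.

## Coding, confidence and evaluation

Candidate scoring scans the full SDL linearly — about 22,000 entries of 2–8
tokens is desk scale, and correctness is easier to audit than with pruning;
the per-query cost is kept low by caching the library's token vocabulary
and running the DP kernel in C++. Ties in confidence are broken by larger
LCS length (longer matches are more specific), then smaller entry length
(fewer unmatched tokens), then lexicographic code, making the ranking total
and deterministic.

The **confidence** of an assignment is exactly the similarity of the top
candidate. The routing policy outputs the code automatically when the
confidence strictly exceeds the threshold, else routes to manual review.
The default threshold 0.803 is the operating point reported for the method
— at that point roughly four fifths of a hospital test set could be
auto-coded at F ≈ 0.80 — retained here as a configurable default, not a
reproduced measurement.

Evaluation is top-1 and retrieval-framed: a correct auto-coded query is a
true positive, a wrong one a false positive, and an abstention (manual
review) a false negative — an unreturned relevant record. When nothing is
auto-coded, precision is defined as 0 (with a warning in direct calls) so
the F-score stays computable across a sweep. `threshold_sweep()` scores
each query once per measure and re-applies the policy per threshold, so
coverage (fraction auto-coded) is non-increasing in the threshold by
construction.

## The synthetic benchmark

The hospital EMR test sets behind the method's headline tables are private,
so absolute published metrics are not reproducible. `generate_benchmark()`
emulates their *structure* instead: diagnosis names are 2–8-token
compositions (0–3 modifiers, one disease root, optionally the connective
"ban" plus a complication) over a pinyin-like synthetic vocabulary; a
synonym ontology aliases a configurable fraction of the vocabulary (default
0.5) at weight 0.9 and registers first+last-syllable abbreviations for
multi-syllable roots; queries are perturbed with the five error classes the
method motivates (synonym swap 0.4, modifier drop 0.25, filler insert 0.15,
character typo 0.15, root abbreviation 0.25 — moderate rates that leave
most queries 1–2 edits from their standard name, as the worked examples
suggest). Defaults of 100 codes / 200 queries / 60 vocabulary words keep a
full sweep fast while leaving headroom between the measures.

Two invariants guarantee usable gold labels without human adjudication: the
disease root is never dropped or typo'd (it may be swapped for its
*ontology-registered* alias or abbreviation, which the semantic LCS can
recover), and every library entry's filtered token sequence is unique, so
verbatim self-retrieval is unambiguous. Generation is a pure function of
(parameters, seed).

What passing on this benchmark does **not** show: real EMR typo
distributions, segmentation errors of a statistical segmenter, ontology
incompleteness, or the absolute F-scores of the original hospital data. It
does show the method's *directional* claims — semantic matching dominates
exact word matching under synonym noise, and coverage trades off against
accuracy along the confidence threshold — which the acceptance tests assert
as a trend over ten seeds rather than per run.

## Numerical and degenerate-input choices

* Display rounding is half-up to 2 decimals (`round_half_up()`), matching
  the reference table's format; internal values are full precision.
* Two empty sequences have undefined measure values (an error in the
  measure functions); in batch coding an entry that filters to zero tokens
  simply scores 0, and a *query* that filters to zero tokens is an explicit
  error.
* `brute_force_lcs()` (the test oracle) refuses sequences longer than 12
  tokens; it enumerates index subsets longest-first and greedily embeds
  them, which is exact for any match predicate.
* DP traceback prefers diagonal, then up, then left, so `matched_pairs` is
  deterministic.
* Problem sizes in the test suite (500 oracle cases at lengths ≤ 8; a
  200-entry self-retrieval library; ten 40×60 benchmark seeds) were chosen
  as the smallest sizes at which the properties are meaningfully exercised
  while the whole suite stays interactive.

## Known limitations

* FMM segmentation is greedy: a lexicon with pathological overlaps can
  split differently than a statistical segmenter would; the pluggable
  `SegmenterConfig` (and character-level mode) is the escape hatch.
* Synonym similarity is flat within a group; no hyponymy, no sememe-style
  graded similarity.
* One code per query (top-1); multi-code documents are out of scope.
* The confidence is a raw similarity, not a calibrated probability.
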