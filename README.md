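# jpdeid

De-identification of Japanese clinical free text: finding and removing
protected health information (PHI) — ages, sexes, dates and times, hospital
names, person names — from electronic health records and pathology reports.
The package is aimed at medical-NLP practitioners who need a runnable
Japanese de-identification pipeline and a controlled test bed for comparing
rule-based and learned taggers when the clinical corpora themselves cannot
be shared.

## What is inside

Three span taggers over the five-type tag set `a` (age), `x` (sex), `t`
(time), `h` (hospital), `p` (person), all producing non-overlapping
character spans (0-based code-point offsets, half-open):

* **Rule tagger** (`rule_tag()`) — deterministic keyword/suffix rules:
  numeral + 歳/才/代 for age; 男性/女性 and English sex words; slash dates
  `yyyy/mm`, `mm/dd` under the bounds 1 ≤ mm ≤ 12, 1 ≤ dd ≤ 31, calendar
  keywords, numeral + classifier units, each extended once over a following
  extender (より, まで, 頃から, ...); hospital context words (当院, 近医,
  同院) and noun/placeholder runs ending in 病院/クリニック/医院. No rule
  exists for person names.
* **Linear-chain CRF** (`fit_crf()`) — exactly five feature families per
  token (POS, detailed POS, character type, user-dictionary membership,
  sentence beginning) over a ±2 context window; exact maximum conditional
  likelihood via forward–backward + L-BFGS with L2; IOB2-constrained
  Viterbi decoding. For an emission matrix `E`, transitions `A` and a label
  path `y` the model maximizes
  `log p(y|x) = Σ_t E[t, y_t] + Σ_t A[y_{t-1}, y_t] − log Z(x)`.
* **BiLSTM-CRF** (`fit_lstm()`) — each word is represented as
  `V_x = [W_x ; h_fwd(chars of x) ; h_bwd(chars of x)]`, the concatenation
  of its word embedding and the final states of a character BiLSTM; a
  sentence BiLSTM over the `V_x` feeds a CRF output layer. Defaults follow
  the published settings (word 200, char 100, char hidden 100, LSTM hidden
  300, learning rate 0.001); backpropagation and Adam are implemented in
  the package and verified against finite differences.

Around them: the inline-tag corpus format (`<a>64歳</a>` ...) with exact
parse/render round trips, IOB2 conversion and CoNLL-style TSV files,
strict span-level precision/recall/F1 with micro-averaged totals,
document-level k-fold cross-validation, inter-annotator agreement (mean
pairwise F1), a three-style synthetic corpus generator with gold spans,
surrogate replacement of masking placeholders (●◯▲■) by dummy names, and a
command-line front end (`inst/cli/deid.R`) over the `cmd_*()` functions.

## Worked example

```r
library(jpdeid)

pred <- rule_tag("工場に勤めている64歳の男性。昨日より発熱し、本日当院を受診した。")
pred$spans[[1]]
#> # A tibble: 5 × 3
#>   tag_type begin   end
#>   <chr>    <int> <int>
#> 1 a            8    11
#> 2 x           12    14
#> 3 t           15    19
#> 4 t           23    25
#> 5 h           25    27

render_inline(pred)
#> [1] "工場に勤めている<a>64歳</a>の<x>男性</x>。<t>昨日より</t>発熱し、<t>本日</t><h>当院</h>を受診した。"
```

The five spans are the patient's age (64歳), sex (男性), two time
expressions — 昨日より, where the extender より is pulled into the span,
and 本日 — and the hospital context word 当院. Evaluating against a gold
annotation under strict span matching:

```r
gold <- parse_inline(
  "工場に勤めている<a>64歳</a>の<x>男性</x>。<t>昨日より</t>発熱し、<t>本日</t><h>当院</h>を受診した。")
format_metrics(strict_match_metrics(gold, pred))
#> # A tibble: 6 × 8
#>   tag_type n_gold    tp    fp    fn precision recall f1
#>   <chr>     <int> <int> <int> <int> <chr>     <chr>  <chr>
#> 1 a             1     1     0     0 100.00    100.00 100.00
#> 2 x             1     1     0     0 100.00    100.00 100.00
#> 3 t             2     2     0     0 100.00    100.00 100.00
#> 4 h             1     1     0     0 100.00    100.00 100.00
#> 5 p             0     0     0     0 N/A       N/A    N/A
#> 6 total         5     5     0     0 100.00    100.00 100.00
```

Scores are printed ×100; `N/A` marks a tag type with neither gold nor
predicted spans. Training the learned taggers on a synthetic corpus:

```r
lists  <- make_name_lists(seed = 1)
tok    <- benchmark_tokenizer(lists)
corpus <- generate_corpus(synth_config(100, "mednlp", seed = 1), lists)

cv <- cross_validate(corpus, lstm_factory(tok, lstm_config_small(seed = 1)),
                     k = 4, seed = 1)
format_metrics(cv[cv$fold == "pooled", ])
```

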