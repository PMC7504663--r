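---
title: "De-identifying Japanese clinical text: models, rules and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De-identifying Japanese clinical text: models, rules and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jpdeid)
```

## The problem

Japanese electronic health records (EHRs) and pathology reports contain
protected health information (PHI) — patient and clinician names, hospital
names, ages, sexes and dates — embedded in free text without word
boundaries. Before such text can be shared for research it must be
de-identified: every PHI mention located as a character span and removed or
replaced. `jpdeid` implements three span taggers over the five-type tag set
used by the Japanese medical-NLP community (`a` age, `x` sex, `t` time,
`h` hospital, `p` person), together with the corpus formats, the strict
span-level evaluation protocol, and a synthetic-corpus generator that
stands in for clinical datasets that cannot be published.

## Tokenization

Japanese has no inter-word spaces, so all taggers operate on the output of
a morphological analyzer. The package defines a pluggable backend contract
(`deid_tokenizer()`) and ships a deterministic built-in backend: longest
match against a user dictionary and a built-in lexicon (counters such as
歳/日/時, calendar words, particles, clinical vocabulary), falling back to
maximal runs of one character class (hiragana, katakana, kanji, number,
latin, symbol). POS output is normalized to a small vocabulary — `noun`,
`particle`, `symbol`, `other`, with detailed classes such as `numeral`,
`suffix`, `temporal`, `non-autonomous word`, `placeholder` — so the rules
do not depend on the tagset dialect of any particular analyzer. Offsets
count Unicode code points, 0-based and half-open, which keeps spans
independent of byte encoding and tokenizer choice.

Two properties are guaranteed and tested: token surfaces tile the input
text exactly, and tokenization is deterministic for a fixed backend and
dictionary. User dictionaries (`register_dictionary()`) merge registered
surfaces into single tokens and set their `in_dictionary` flag, emulating
how IPADIC-style analyzers consume custom dictionaries; entries carry a POS
subcategory (e.g. `organization` vs `disease`), as real analyzer
dictionaries do.

## The rule-based tagger

The rules cover four of the five types; there is no workable surface rule
for person names:

* **age** — a numeral token immediately followed by 歳, 才 or 代.
* **sex** — a token equal to 男性 or 女性, or an English sex word
  (man/woman/men/women, case-insensitive).
* **time** — (i) slash dates `yyyy/mm` and `mm/dd`, accepted only inside
  the bounds 1 ≤ mm ≤ 12 and 1 ≤ dd ≤ 31 (clinical inspection values such
  as 13/40 share the surface pattern; the bound is a workaround, and truly
  resolving such collisions needs context, which is exactly where the
  learned taggers help); (ii) standalone calendar keywords (昨日, 今年,
  翌日, ...); (iii) a numeral plus a classifier unit (年/月/週間/日/時/分).
  Each detected span is then *extended once* over a following extender
  string (より, まで, 頃, から, and compounds such as 頃から), longest
  match winning. Extension is deliberately not cascaded: the extender list
  is finite and one application reproduces all attested examples, while
  cascading could grow unbounded spans.
* **hospital** — context keywords (近医, 当院, 同院), and a maximal run of
  noun tokens (detailed POS other than "non-autonomous word") or masking
  placeholders (●◯▲■) immediately followed by a name suffix (病院,
  クリニック, 医院). A bare suffix with no preceding run is not tagged —
  every hospital mention in scope has either a name stem or a placeholder
  run before the suffix, and tagging bare 病院 would flood generic
  mentions.

Overlaps between rule outputs are resolved longest-span-first, ties broken
by the fixed priority age > time > hospital > sex. Longest-match is the
standard convention in rule NER; the priority order puts the most
form-constrained patterns first so that, e.g., 64歳 is an age span rather
than a numeral-plus-classifier time span. The tagger is deterministic and
idempotent, and the whole pipeline is validated against an independent
brute-force reference (enumerate all token windows, apply the predicates
naively) on thousands of adversarial random sentences.

The keyword inventory lives in `default_rule_lexicon()` and can be
overridden per set from a YAML file (`read_rule_lexicon()`).

```{r rules}
rule_tag("工場に勤めている64歳の男性。")$spans[[1]]
```

## The linear-chain CRF

`fit_crf()` trains a linear-chain conditional random field with exactly
five feature families per token: POS, detailed POS, character type (the
majority class of the surface's characters, ties to the first character),
a binary user-dictionary membership flag, and a binary
sentence-beginning flag. Those are the published feature set; choices the
source leaves open are isolated in the training config:

* a ±2 token context window at template level (standard for NER),
* L2 regularization strength 1.0,
* L-BFGS with at most `max_iter` iterations from a zero initialization,
  which makes training fully deterministic.

The implementation is exact maximum conditional likelihood: log-space
forward–backward for the gradient (unary and pairwise marginals), with the
analytic gradient verified against finite differences in the test suite.
Decoding is Viterbi under IOB2 structural constraints (an `I-τ` may only
follow `B-τ`/`I-τ`, no sequence starts with `I-τ`), so decoded output is
always IOB2-valid regardless of the learned weights.

Because the five families never include the word surface itself, the CRF
is deliberately weaker lexically than the BiLSTM-CRF — it must recover
entities from POS/dictionary/character-class patterns in context. This is
the behavior the package's benchmarks measure and the reason the
character-embedding model overtakes it on unseen names.

## The BiLSTM-CRF

`fit_lstm()` trains the neural tagger: each word is represented by the
concatenation of a word-embedding lookup and the final forward/backward
hidden states of a character-level BiLSTM over its letters; the sequence
of word representations feeds a sentence-level BiLSTM whose concatenated
outputs are projected to per-label emission scores; a CRF output layer
scores label transitions, trained by exact sequence negative
log-likelihood. Backpropagation through both BiLSTM levels and the CRF
layer is hand-written in matrix code and checked against finite
differences in the tests.

The five published architecture parameters are the package defaults and
asserted by a test: word embeddings 200, character embeddings 100,
character hidden layer 100, sentence LSTM hidden layer 300, learning rate
0.001. Training choices the source does not pin down are explicit in
`lstm_config()`: Adam at the published learning rate, batch size 16,
30 epochs, dropout 0.5 before the output layer, global gradient-norm clip
5, and fine-tuned word embeddings (a config switch can freeze them).
Pretrained word2vec vectors (text or binary format) can seed the embedding
table via `load_word_vectors()`; out-of-vocabulary words share a trainable
unknown vector, while their characters still drive the character BiLSTM —
that path is what generalizes to unseen surnames.

Training is seeded and reproducible: initialization, shuffling and dropout
all derive from `config$seed`. Test suites and the reproducibility script
use `lstm_config_small()` — the same architecture at reduced sizes (word
24, char 8/12, hidden 24, learning rate 0.01, 12 epochs) — which trains in
seconds on one CPU; the published sizes remain the model defaults.

## Evaluation protocol

`strict_match_metrics()` scores a prediction as a true positive only if an
identical `(begin, end, tag_type)` gold span exists — strict phrase-level
matching. Precision, recall and F1 are reported per type and in total; the
total row is micro-averaged (counts summed over types, then recomputed),
which is the convention under which per-type and total rows coexist in
published result tables. Zero denominators score 0; a type with neither
gold nor predicted spans is reported `N/A`. `token_accuracy()` is the
word-level agreement ratio of B-*/I-*/O labels. `format_metrics()` prints
scores ×100 with two decimals.

`cross_validate()` shuffles documents with a seed and partitions them into
k folds at *document* level — sentence-level splits would leak a patient's
record across the train/test boundary. Pooled metrics sum tp/fp/fn over
folds. `pairwise_agreement()` computes inter-annotator agreement as the
mean strict-match F1 over all unordered annotator pairs, pooled over the
corpus (per-document averaging would over-weight short documents).

## The synthetic corpus generator

The clinical corpora this methodology was developed on are not publicly
distributable, so `generate_corpus()` produces annotated stand-ins from
handcrafted clinical sentence templates in three style presets:

* `mednlp` — discharge-summary-like text: age/sex/time/hospital, no person
  names; 3–7 sentences per document.
* `dummy_ehr` — longer narrative: all five types, person rare; 8–16
  sentences.
* `pathology` — short reports where person/hospital/time dominate and
  age/sex are absent; 2–4 lines.

The presets preserve the *qualitative* tag distribution of the emulated
sources (which types occur, their rank order), with rates boosted enough
that every in-style type appears at test-corpus scale; the generator's
purpose is statistical structure, not linguistic realism. A per-style
fraction of documents (0.8 mednlp, 0.7 dummy_ehr, 0.25 pathology) is
restricted to *rule-conforming* entity realizations; the remainder mixes in
rule-breaking variants — kanji-numeral ages (六十五歳), bare 男/女, clinic
names without a suffix, time words outside the keyword inventory, and
xx/yy inspection values that collide with the slash-date rule. The
pathology preset is mostly non-conforming because person names, which no
rule covers, dominate that style. This contrast is what gives the learned
taggers room to beat the rules, mirroring how the methods compare on real
data. Generation is end-to-end seeded: identical config and seed yield a
byte-identical corpus.

`make_name_lists()` emulates the external surrogate resources: hospital
names built as place/specialty stems plus one of the suffixes
病院/クリニック/医院 (a loader can substitute a real list file), and the
20 dummy family names and 20 dummy given names from which person
surrogates are formed — a family name alone or family plus given name.
`surrogate_replace()` performs the replacement of manual masking
placeholders (runs of ●◯▲■) with sampled names, recomputing all span
offsets; a run's type must be given by a covering gold span or be
inferable from an immediately following hospital suffix, and anything else
is an error listing the offset rather than a guess.

What passing tests on this generator do **not** show: robustness to real
clinical spelling variation, abbreviations, layout noise, or annotation
idiosyncrasies. The generator shares its lexical inventory with the rule
lexicon by construction, so rule scores on conforming documents are an
internal consistency check, not an external validity claim.

## Benchmarks the package ships

The test suite and `scripts/acceptance.R` rerun the full experimental
loop at desk scale (sizes chosen so the whole suite runs in minutes on one
CPU):

* worked-example fidelity of the rule tagger on the three published
  example sentences;
* equality of the rule tagger with the brute-force reference on 1000
  random sentences of at most 40 characters;
* the slash-date bound property over all `a/b`, a,b ∈ 0–99;
* exactness of inline ↔ span ↔ IOB2 round trips on 1000 random documents;
* 4-fold document-level cross-validation of both learned taggers on a
  100-document (~500-sentence) `mednlp`-style corpus with the benchmark
  tokenizer (`benchmark_tokenizer()`, whose dictionary registers hospital
  names as organization entries and common disease/symptom terms as
  disease entries — emulating a custom dictionary built from named-entity
  lists and a disease-code master);
* memorization of a 20-sentence corpus by the BiLSTM-CRF (capacity check);
* the out-of-vocabulary person experiment (`oov_person_split()`): test
  surnames are unseen combinations of characters that all occur in
  training surnames, so the character path of the BiLSTM-CRF generalizes
  where the five-feature CRF cannot — the package's directional claim is
  that LSTM person-F1 exceeds CRF person-F1 on that split.

## Numerical and design notes

* Forward–backward and Viterbi run in log space; `-Inf` masks implement
  the IOB2 decoding constraints.
* Empty sentences, zero-epoch models, unknown decode-time features and
  unseen characters/words are all defined behaviors (empty output,
  untrained but length-preserving decode, dropped features, UNK rows).
* IOB2 repair (`I-τ` after `O` read as `B-τ`) exists only in lenient mode
  for third-party tagger output and warns; strict mode is the default
  everywhere inside the package.
* The five-type tag alphabet and the span non-overlap invariant are
  enforced at construction (`phi_spans()`), parse time and render time.
* The rule tagger's hospital run may absorb a preceding temporal noun
  (e.g. 昨日クリニック...) — the run condition excludes only
  non-autonomous-word nouns, matching the published rule; templates avoid
  this configuration, and real text rarely produces it.

## Limitations

The built-in tokenizer is a deliberately simple analyzer: real analyzers
disambiguate with a trained lattice model, and segmentations differ. All
results in the package are internally consistent under the built-in
backend, and every component accepts any backend honoring the tokenizer
contract. The synthetic corpora cannot estimate real-world
de-identification performance; published scores on the original clinical
datasets are not reproducible without those datasets, which is why the
package's acceptance checks are property-based (fidelity, equivalence,
bounds, learnability, directional comparisons) rather than attempts to
match those numbers.
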