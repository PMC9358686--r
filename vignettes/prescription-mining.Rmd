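---
title: "Mining analgesic co-prescription patterns in rheumatoid arthritis records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining analgesic co-prescription patterns in rheumatoid arthritis records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbminer)
library(tibble)
```

## The analysis

`herbminer` implements a prescription-mining workflow for traditional
Chinese medicine (TCM) case records of rheumatoid-arthritis (RA) chronic
pain. The unit of analysis is a *case*: one patient visit carrying clinical
scores, a list of recorded symptom terms, and the list of herbs prescribed.
The workflow turns a pile of such records into:

1. an **eligible cohort**, via a clinical screen (age 18–70, disease
   duration ≥ 6 months, moderate disease activity before treatment,
   3.2 < DAS28 < 5.1, remission after, DAS28 < 2.6; HAQ-DI ≥ 1 before and
   < 0.5 after; decreased VAS; ALT/AST < 2× the upper limit of normal;
   WBC > 3.5×10⁹/L; consent; TCM-treated);
2. a **canonical transaction** per case: symptom and herb terms mapped onto
   a controlled vocabulary and deduplicated into sets;
3. **frequency and proportion tables** with a 10% enrollment filter;
4. **association rules** between herbs and between herbs and symptoms,
   mined with a level-wise Apriori search; and
5. a **co-prescription dendrogram** of the heavily used herbs.

Each step is an ordinary function over a tibble, so the pipeline composes
with the usual tidyverse verbs; `run_pipeline()` chains all of them and
writes a reproducible report bundle.

## Terminology standardization

Raw records spell the same clinical concept many ways. A
`term_dictionary()` maps every raw term to exactly one canonical term, and
canonical terms map to themselves, which makes standardization idempotent —
a property the test suite checks over the whole packaged dictionary.
Unknown terms pass through unchanged rather than erroring: no dictionary of
clinical free text is exhaustive, and silently dropping unmapped terms
would bias frequency tables. Two deliberate *non*-merges are worth calling
out: name pairs that denote different drugs in the same prescription
("Chuanniuxi"/"Niuxigen") and different parts of the same plant
("Jinyinhua"/"Rendongteng") keep their distinct names.

Regional pain terms are special. Wrist, elbow, shoulder and finger-joint
pain standardize to "Upper limb joint pain"; ankle and knee pain to "Joint
pain of lower extremity"; lumbar, hip and sacral pain to "Lumbosacral
pain". When a single case names pain in **two or more** of these body
regions, the regional terms are *replaced* by the single term
"Polyarthralgia". Replacement (rather than adding the multi-joint term
alongside the regional ones) keeps the symptom categories disjoint, so each
case contributes to exactly one row of the pain-location breakdown.

## Screening semantics

Every inequality in the screen is implemented with exactly the strictness
of its clinical statement: DAS28 before treatment must be *strictly*
between 3.2 and 5.1, a WBC of exactly 3.5×10⁹/L is excluded, an HAQ-DI of
exactly 1 before treatment is included, and so on. The screen is a pure
conjunction: `screen_cases()` reports the full list of failed criterion
ids, and fixing any single failing field removes exactly that id. Records
with missing required fields are rejected wholesale with the id
`incomplete_record`, mirroring a complete-records design.

## Frequency analysis and the enrollment filter

`frequency_table()` counts, for each item, the number of cases whose set
contains it; the rate divides by the number of eligible cases N. One N is
used everywhere. (Published per-herb rates in this literature occasionally
imply a slightly different denominator than the stated cohort size — e.g. a
count of 182 printed as 58.15% implies N = 313 rather than 311; the
packaged monograph table stores such rates as printed, but every rate this
package *computes* is count/N for a single N.)

The enrollment filter keeps items prescribed or reported in at least 10% of
cases. The threshold is implemented **inclusively** (rate ≥ 0.10): the
boundary is unobserved in practice (the least frequent enrolled symptom in
the packaged tables sits at 12.22%), and an inclusive bound avoids
floating-point equality pathologies at exactly 10%.

`pain_share()` is occurrence-weighted: each (case, symptom) pair counts
once, pain occurrences are those in the dictionary's pain lexicon (the
three regional terms plus Polyarthralgia), and the by-location fractions
sum to the overall pain share.

## Monographs, category shares and the attribute network

Each high-frequency herb carries a monograph: thermal property, flavors,
meridian tropism and one of eight efficacy categories.
`category_shares()` supports two weightings. The default, *frequency*
weighting, lets each herb contribute its prescription count — the shares
are then shares of prescriptions, not of herbs — because the published
category percentages in this area are not multiples of 1/16 and are only
reproducible under count weighting of this kind. Plain *count* weighting
(each herb contributes 1) is available by flag.

The packaged category assignment itself deserves a note: public tables in
this field typically print only the category *percentages*, not which herb
belongs to which category. The packaged `ra_monographs()` assignment
follows standard pharmacopeia classes (e.g. Jinyinhua and Tufuling as
heat-clearing; Qingfengteng, Fangji, Sangjisheng and Duhuo as wind-dampness
dispelling; Chaobaishao, Tusizi and Baizhu as tonifying; Fuzi as
interior-warming; Guizhi and Qianghuo as exterior-releasing; Shuizhi and
Huainiuxi as blood-activating; Yiyiren as dampness-draining; Wugong as
liver/wind-soothing), and under frequency weighting this assignment
reproduces the published shares after rounding (21/20/17/11/9/9/8/5) — a
check in the test suite.

`attribute_edges()` flattens monographs into one (herb, attribute) edge per
incidence, ordered deterministically, and `write_sif()` emits the simple
interaction format plus a node-attribute table for network tools.

## Association rule mining

Transactions are the canonical item sets; second-order runs use herbs only
(herb–herb pairs), third-order runs mix herbs and symptoms (two-item LHS,
one-item RHS). `frequent_itemsets()` is a from-scratch level-wise Apriori
search: size-k candidates come only from joining frequent (k−1)-sets on a
shared prefix and are pruned when any (k−1)-subset is infrequent, which is
sound because support is anti-monotone on the itemset lattice.

Rule metrics follow the standard definitions: support is the fraction of
transactions containing LHS ∪ RHS, confidence divides by the LHS fraction,
and **lift = confidence / support(RHS)** — 1 under independence, above 1
for positive association. (Informal descriptions of lift sometimes reduce
to a ratio of the two marginals, which measures nothing about association;
this package uses the standard definition throughout.)

The acceptance filter keeps rules with support ≥ 10%, confidence ≥ 50% and
lift ≥ 1.2, plus a minimum absolute co-occurrence count of 1. Thresholds
are inclusive (`>=`): with counts being integers, rules can land exactly on
a boundary, and inclusive comparison makes the filter reproducible. For the
same reason confidence and lift are computed from **integer counts**
(`count(set)/count(lhs)`), in exactly the same arithmetic expressions as
the exhaustive oracle, so both routes agree bit-for-bit even at boundary
values like lift = 1.

Completeness is the property that matters most here — a missing qualifying
rule is silent and invisible in output. It is tested two ways:
`brute_force_rules()` enumerates every (LHS, RHS) split directly with no
pruning (guarded to ≤ 15 items), and the suite checks set-equality of rules
and metrics on 200 random datasets plus synthetic datasets at study scale.

## The synthetic generator

Real case records of this kind are not publicly deposited, so the package
ships a generator whose defaults encode the study conditions the analyses
assume: `ra_config()` draws 311 eligible cases over the 16 high-frequency
herbs and 18 high-frequency symptoms, each at its observed marginal rate
(count/311).

The dependence model is a **latent-class mixture**: a case draws a class,
then every item independently with its class-specific probability. This
mimics the "syndrome pattern" structure of TCM co-prescription (patients of
one presentation receive correlated bundles of herbs) and — crucially for
testing — yields closed-form rule metrics. For an itemset S,
P(S) = Σ_c w_c Π_{i∈S} p_{c,i}, from which `expected_rule_metrics()`
computes exact support, confidence and lift. The packaged
`planted_config()` (two equal classes, the planted pair at 0.9 vs 0.1)
gives support 0.41, confidence 0.82, lift 1.64 — comfortably past the
filter — and `independence_config()` is the matched null with all marginals
≤ 0.5. Both carry an always-present base herb and base symptom so that no
case needs redrawing and the closed forms stay exact; rules through an
always-present item have lift exactly 1 and are filtered.

Validation sizes, chosen so each check is decisive at desk scale: marginal
recovery at n = 1000 within four binomial standard errors; planted-rule
recovery in 20/20 seeds at n = 2000; the null control at n = 20000 over 20
seeds tolerating at most one false rule; miner/oracle equivalence on 200
random datasets of ≤ 13 items and ≤ 60 transactions.

What the generator does **not** emulate: raw-synonym noise (it emits
canonical vocabulary, so standardization is exercised by hand-built
fixtures instead), dosage, visit sequences, longitudinal score dynamics,
and any dependence structure beyond class mixing. Passing tests therefore
demonstrate correctness of the algorithms under the stated statistical
model, not fidelity of any particular clinical dataset.

## Hierarchical clustering

`build_incidence()` forms the binary herb × case matrix over herbs
prescribed in strictly more than 50 cases (the enrollment rule for the
cluster analysis is a strict bound, unlike the 10% frequency filter).
`herb_linkage()` is a deliberately plain agglomerative loop — at ~20 herbs
there is nothing to optimize — with two properties the generic library
routine does not guarantee: a **deterministic tie-break** (ties in
inter-cluster distance resolve toward the lexicographically smallest pair
of cluster representatives, so permuting input rows cannot change the
tree) and an explicit merge record convertible to `stats::hclust` form.
Euclidean distance with complete linkage is the default, matching the
documented defaults of the standard clustering routine this analysis
descends from; Jaccard distance and average/single linkage are available
because binary incidence data often motivate them. Agreement with
`stats::hclust` on tie-free data is part of the test suite.

`cut_groups()` removes the k−1 highest merges (default k = 3 groups) and
labels components in first-leaf order. `to_newick()` writes an ultrametric
tree (each child sits at half the merge height below its parent), so the
cophenetic distance between two leaves equals the height of their lowest
common ancestor; round-trips through `ape::read.tree()` preserve topology
and heights to 10⁻⁹.

One modelling choice is worth stating: herbs are clustered as row vectors
over **cases** (co-prescription space), not over symptoms. The 0/1 matrix
the procedure describes is herb-presence per case, and co-prescription is
the quantity the resulting groups are read as.

## Numerical and degenerate-input conventions

* Rates and metric proportions are kept as proportions internally and
  rendered as percentages (2 decimals) only in report files.
* Frequency tables sort by count descending with alphabetical tie-break;
  itemsets sort by (size, support desc, label); rules by (lift desc,
  support desc, label). All output orderings are total, hence stable.
* Empty inputs error early and loudly (`frequency_table()` on zero cases,
  `herb_linkage()` on fewer than two rows, cleaning that empties a case's
  herb or symptom set raises `degenerate_case`).
* All generator randomness flows from one explicit seed via an isolated RNG
  scope; the global random state is never touched, and a configuration is
  byte-identical across runs.

## Limitations

* The packaged dictionary covers the vocabulary of the packaged tables,
  not clinical free text at large; unmapped terms pass through.
* Presence/absence only: dose, preparation and administration are out of
  scope.
* Each record is treated as an independent transaction; repeated visits by
  one patient are not modelled.
* The mined associations are co-prescription patterns. They indicate what
  clinicians prescribe together for which presentations — not efficacy.
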