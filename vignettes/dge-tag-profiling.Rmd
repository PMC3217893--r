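---
title: "DGE tag profiling against predicted gene models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DGE tag profiling against predicted gene models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgetag)
```

## The assay and the problem

Digital gene expression (DGE) tag profiling is a SAGE-like assay: cDNA is
digested with an anchoring restriction enzyme (DpnII, site `GATC`, or
NlaIII, site `CATG`), and a type IIS enzyme then releases a short fixed-
length tag immediately downstream of the 3'-most anchoring site of each
transcript. After adapter trimming each transcript is represented by one
16-nt **authentic tag**, and tag counts measure transcript abundance.
Two artifact classes accompany the authentic tag: **internal sense** tags
from restriction fragments that are not washed away (tags downstream of
non-terminal sites) and **antisense** tags from inefficient restriction.

`dgetag` implements the complete desk-scale analysis of such libraries
from two unreplicated libraries of closely related genotypes — a wild
type (`CS`) and a mutant (`CG`) — against a catalogue of predicted cDNA
gene models, together with an RNA-Seq arm used to corroborate expression
trends, and a seeded synthetic-data generator that provides ground truth
for every stage.

## Tag catalogue and the authentic-tag rule

`build_tag_catalog()` digests each model cDNA in silico. For a site at
0-based position $s$ with enzyme length $e$ and tag length $k$:

* a *sense* tag occupies $[s+e,\; s+e+k)$ when the model retains $k$
  bases downstream;
* an *antisense* tag occupies $[s-k,\; s)$, read on the reverse
  complement, when $k$ bases precede the site.

The sense tag at the 3'-most site with a full-length downstream tag is
labelled `authentic`; remaining sense tags are `internal_sense` and all
antisense tags `antisense`. Two deliberate choices:

* **Tag composition.** The 16-nt tag *excludes* the recognition-site
  bases and starts immediately downstream of them. Protocol descriptions
  are ambiguous on whether site bases are reported as part of the tag;
  exclusion is fixed here, and `tag_len` is configurable so the inclusive
  convention can be emulated by a caller.
* **Eligibility fallback.** When the 3'-most site has fewer than
  `tag_len` bases downstream, authenticity falls back to the next
  eligible upstream site: the chemistry anchors on the 3'-most fragment,
  but a tag must be full length, and a model is better represented by an
  upstream full-length tag than by none.

The MmeI cut-counting chemistry (17-bp cut, adapter ligation) is not
modelled base by base; the catalogue abstracts it to "`tag_len` bases
adjacent to a site", which is what the trimmed data show. Non-palindromic
enzymes are searched on both strands; for palindromes such as `GATC` the
two searches collapse into one. Tags containing `N` are dropped — they
can never satisfy a 0-mismatch criterion.

## Model extension and the five regions

Predicted gene models frequently truncate the 3'UTR, so the authentic tag
of a transcript can fall *outside* its annotated model. `extend_model()`
appends up to `flank_bp` (default 250) bases of contiguous genomic
sequence to each end of the spliced cDNA, oriented 5'→3' on the model's
sense strand. Two choices matter here:

* Flanks are genomic sequence adjoining the model's outermost genomic
  coordinates, appended to the *spliced* cDNA: a 3'UTR continuation is
  contiguous with the terminal exon, which is the case the extension is
  designed to rescue.
* Flanks are clipped at chromosome ends and the realized lengths
  recorded, never padded with `N` (padding would silently make tags
  unmatchable at 0 mismatches).

`classify_region()` places any tag interval into exactly one of five
labels — `extra_left`, `junction_left`, `model`, `junction_right`,
`extra_right` — with junction labels taking precedence when an interval
overlaps a flank/model boundary. The tally of these labels over all tag
matches summarizes how much expression the annotation fails to cover.

## Matching, owner resolution, and normalization

Observed tags are matched at **0 mismatches** against a k-mer index of
both strands of every extended model (`build_tag_index()`,
`match_tags()`). Every occurrence is reported; a genome rich in paralogs
makes multi-model tags common. Three bookkeeping rules:

* **Alignment totals** count each sequenced tag once however many
  positions it matches, so `sum(cpm) == 1e6` per library exactly.
* **Owner resolution** (`resolve_owner()`): a tag shared by several
  models belongs to the model that carries it as its *authentic*
  catalogue entry; if none or several do, it is ambiguous and excluded
  from per-model expression (it still participates in tag-level
  analyses). This generalizes the reasoning used to assign shared tags in
  the original analysis.
* Tags are filtered by a raw-count floor (default: ≥ 5 in at least one
  library) before analysis.

Normalization is tags per million aligned (`cpm()`) for DGE and reads
per kilobase of model per million mapped reads (`rpkm()`) for RNA-Seq.
Fold changes are CS/CG on unrounded values; a zero CG value with positive
CS propagates `+Inf` rather than being capped, and 0/0 is `NA`.

## The differential-expression screen

`fc_screen()` implements the headline screen: a record is called
over-expressed in CS at ratio ≥ 2 and under-expressed at ratio ≤ 0.5
(configurable), and passes the screen only if the **larger** of its two
library values reaches the 42-cpm floor. Applying the floor to the
maximum rather than to both libraries is deliberate: requiring both would
exclude exactly the most interesting genes — those silenced in one line,
whose ratio is extreme because one denominator is near zero.

## The no-replicate negative-binomial test

With one library per genotype there are no replicates; the test borrows
the assumption that near-isogenic lines express most genes identically,
treating the two libraries as blind replicates of one condition:

1. **Size factors** (`size_factors()`): median-of-ratios across ids with
   positive counts in both libraries, rescaled to geometric mean 1.
2. **Dispersion** (`nb_fit()`): per-id base mean $\hat q$ = mean of
   size-factor-normalized counts; raw dispersion from the two-sample
   variance after subtracting the shot-noise term; a parametric function
   $\alpha(q) = a_0/q + a_1$ fitted by ordinary least squares and clamped
   at 0 after fitting. A parametric fit is used instead of a local
   regression: with only two libraries the raw dispersions are extremely
   noisy and the two-parameter pool is the robust choice.
3. **Test** (`nb_test_noreps()`): conditioning on the pair total
   $T = k_{CS} + k_{CG}$, the two-sided p-value sums conditional
   probabilities of all splits $(a, T-a)$ whose joint probability under
   independent $\mathrm{NB}(s_j \hat q, \alpha(\hat q))$ does not exceed
   the observed split's, computed in log space. In the $\alpha \to 0$
   limit this reduces exactly to the conditional binomial (Poisson
   split) test, which is the tested contract. For totals above a cap
   (default 10,000) the enumeration is restricted to ±20 conditional
   standard deviations around the conditional mean and renormalized; the
   omitted tail mass is far below double precision at that width.

Benjamini–Hochberg adjustment is applied via `bh_adjust()` (a thin,
validated wrapper over the standard step-up). The package makes no claim
of numerically replicating any particular DESeq release; the test is a
documented exact-conditional variant with the same modelling assumptions.

## RNA-Seq arm

`map_reads()` is a desk-scale ungapped mapper: ≤ 3 mismatches
(configurable), both orientations, exhaustive by pigeonhole seeding (the
read is partitioned into `mismatches + 1` disjoint exact seeds), at most
25 alignments reported per read, best-mismatch stratum first. Multi-
mapped reads contribute fractionally ($1/k$ over the $k$ models hit in
the best stratum), which preserves read-count conservation in a
paralog-rich transcriptome; only the best stratum is quantified.
Spliced alignment, indels and quality scores are out of scope — the
reference is a cDNA model set, not a genome.

`concordance()` joins tag-level DGE calls to model-level RNA-Seq calls
through the owner map and scores agreement as both fold changes lying on
the same side of 1; pairs where either platform's ratio is undefined
(0/0) are excluded from the denominator and reported separately.

## The synthetic-data generator

`make_genome()`, `make_sim_truth()`, `simulate_dge()` and
`simulate_rnaseq()` are pure functions of their parameters and a seed.
Their defaults define the validation conditions used by the test suite
and the acceptance script:

* 50 models of 600–2000 bp at GC 0.35 on one chromosome, 30% on the
  minus strand, 10% duplicated as ≥ 98%-identity paralog pairs, every
  model guaranteed an eligible `GATC` site;
* log-normal baseline abundances (sdlog 1); 10% of models planted with a
  4-fold CS/CG change (alternating direction), libraries renormalized;
* DGE depth 10^6 tags per library, drawn multinomially over catalogue
  entries with artifact-class proportions (0.80 authentic, 0.15 internal
  sense, 0.05 antisense). The real artifact rates of the assay are
  unknown; these defaults merely make authentic tags dominant, and no
  test asserts them beyond the configured truth. Counts are multinomial
  at fixed depth; overdispersion beyond multinomial is introduced only in
  the NB calibration experiments, which simulate NB counts directly;
* RNA-Seq: 75-bp reads, 20,000 per library, model chosen by abundance ×
  number of valid start positions, uniform start, random strand, 0.1%
  substitution errors;
* truncation experiments remove 100–200 bp from the annotated 3' end of
  30% of models, leaving the genome untouched, so displaced authentic
  tags land in the right junction/flank of the extended model (100–200 bp
  is within the 250-bp flank, so displaced tags remain matchable).

What the generator does **not** emulate: sequencing-quality profiles,
adapter contamination, splicing (models are unspliced), polyA tails,
cultivar-level SNPs between sample and reference (the real analysis loses
~10% of tags to such mismatches), and the unknown true artifact rates.
Passing recovery tests therefore demonstrates correctness of the
pipeline's logic under its stated sampling model, not field performance
on real libraries.

## Numerical and degenerate-input choices

* All internal coordinates are 0-based half-open on the forward genomic
  strand; GFF input is converted on read, BED taken as is.
* Ranking ties are broken lexicographically by id; "expressed at cutoff"
  is boundary-inclusive (`>=`).
* Models with no eligible site yield an empty catalogue (and can never
  own a tag); all-zero count pairs give `NA` p-values; `NA` propagates
  through BH adjustment.
* p-value tie detection in the conditional test uses a `1e-7` log-space
  slack so float noise cannot split genuinely tied splits.
* Problem sizes in the tests (50-model genomes, 10^6-tag libraries,
  3 seeds, 20,000-read RNA-Seq sets, 1000-model oracle sweeps) were
  chosen as the smallest scales at which every recovery property is
  comfortably outside sampling noise.

## Known limitations

* Near-identical paralogs whose authentic 16-mers coincide are
  *correctly* reported ambiguous and excluded from per-model DGE
  expression; at the default 10% paralog fraction this caps model-level
  recall below tag-level recall. Tag-level results do not suffer this.
* Fractional multi-map allocation biases per-model RPKM of near-identical
  paralog pairs toward their mean; ratio-recovery checks therefore use
  distinct-sequence models.
* The screen has no variance component: at very low counts a 2-fold
  ratio is sampling noise. The raw-count floor and the cpm floor are the
  only guards, as in the original screen; the NB test is the
  variance-aware companion.
* With one library per condition the NB test's dispersion is pooled
  across ids; a gene violating the "most genes unchanged" assumption
  inflates the pooled dispersion and costs power everywhere.
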