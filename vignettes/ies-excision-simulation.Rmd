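---
title: "Simulating and scoring IES excision: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and scoring IES excision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iesim)
library(data.table)
```

## The biological model

In *Paramecium*, the somatic macronuclear (MAC) genome is derived from the
germline genome by precise excision of tens of thousands of short Internal
Eliminated Sequences (IESs). The features that this package encodes as hard
model constraints are:

* **TA-bounded excision.** Every IES is flanked by a TA dinucleotide at each
  end; exactly one TA remains at the junction after excision. We represent
  an IES as a 1-based inclusive interval `[start, end]` on the germline that
  *contains* one TA copy at its 5' end, with the second copy immediately
  downstream at `[end+1, end+2]`. Removing `[start, end]` then leaves a
  single TA — the "one TA remains" rule becomes an algebraic identity, and
  excising all annotated intervals reproduces the somatic genome
  byte-for-byte (a round-trip invariant asserted in the tests).
* **Periodic length distribution.** IES lengths are drawn from a mixture of
  Gaussian peaks centred at `min_len + k * period` with `min_len = 26` bp
  and `period = 10.2` bp, truncated to `[26, 150]` and rounded. The second
  peak (36–37 bp) receives near-zero weight by default, mirroring the
  "forbidden" peak of the genomic distribution. The length convention
  counts one TA copy inside the IES; whether genome annotations count one or
  both copies is not fixed in the literature we model, so the convention is
  simply documented and used consistently everywhere (annotation, length
  model, size-peak windows).
* **End consensus.** Both IES ends carry a degenerate octamer read TA-inward,
  5'-TAYAGYNR-3'. The left octamer is the first 8 IES bases; the right end
  is built so that the reverse complement of the last 6 IES bases plus the
  downstream TA matches the same consensus. `consensus_fidelity` is the
  probability that each degenerate position is drawn from the consensus
  alphabet rather than the background composition (default 0.85; 1.0 gives
  an exact-consensus genome, which the motif tests use).
* **AT-rich background.** Random DNA uses 28% GC, approximating the
  *Paramecium* genome. This matters quantitatively for the internal-TA scan:
  under a uniform random core, a TA starts at a given internal offset with
  probability `p(T) * p(A) = 0.36² ≈ 0.13`.

## What one simulated experiment is

A `sim_config()` describes a sequencing experiment as a mixture of molecule
populations. Per scaffold, a pool of `n_molecules` new-MAC molecules is
built; each molecule independently realizes, for every IES: *retained*
(probability `retention_prob`, scalar or per-IES), *correctly excised*, or
*erroneously excised* (probability `error_rate` among excising molecules)
through a planted alternative TA-bounded junction. A second, parental pool
is fully excised except for `parental_error_junctions` pre-existing
erroneous junctions carried by a fraction of molecules. Reads are
fixed-length windows (default 100 nt, single-end, forward strand, error-free)
drawn uniformly from molecules; the autogamous sample draws an
`old_mac_fraction` of its reads from the parental pool, emulating old-MAC
contamination. Ground truth (per-IES realized retention, planted events with
class and offsets, per-read origin) is returned alongside the reads.

Defaults were chosen once as a realistic desk-scale caricature and are not
tuned to any test outcome: single-end 100 nt reads at 100× coverage (the
sequenced studies used 76–160× with paired 100–150 nt reads; single-end
windows suffice because every statistic depends on junction content only),
`error_rate = 0.03` (wild-type vegetative MACs show ~2.4–3%
erroneous excision reads), a boundary-shift model with 80% of shifts at
10–11 bp, `old_mac_fraction = 0.1`, and 5 parental error junctions.

### Planted erroneous junctions

For every IES an alternative junction is planned at genome-construction time
(class from `error_class_mix`, shifts from `shift_model()`): partial
internal/external keep one canonical boundary, internal/external/overlapping
move both. If the required alternative TA does not occur naturally, it is
created by local substitution — inside the IES (germline only) or in flank
DNA (applied to both references, which share flanks) — and flagged
`ta_planted`. Planting at construction time (rather than per-read) keeps the
invariant that every erroneous junction is TA-bounded on the *final*
germline reference, which the mapper's output contract asserts. Internal
alternative boundaries keep ≥3 bp from canonical ones so planted errors
survive the >2 bp shift filter of the spectrum analysis.

## Junction mapping without an aligner

Reads are classified by a deterministic seed-and-extend split matcher
(`build_index()`, `classify_reads()`, `detect_deletion()`), replacing an
external aligner so results are exactly reproducible:

* a unique-k-mer map (k = 12) anchors the read's first and last k-mers on
  the germline;
* a read matching contiguously is scanned for IES boundary spans: it is
  IES+ evidence for a boundary if it covers ≥ `min_anchor` (12) bases on
  each side — equivalently, it contains the boundary's 2×12-mer probe;
* otherwise the read is explained, if possible, as
  `germline[p..a-1] + germline[b+1..q]` with ≥ `min_anchor` exact bases on
  both sides of a single deletion `[a, b]`. Deletions equal to an annotated
  IES are IES− junction evidence; other TA-bounded deletions are alternative
  deletions; anything else is uninformative. Matching is exact
  (mismatch tolerance of the original alignment-based analyses is not
  modelled) and on the given strand; a reverse-complement fallback exists
  behind a flag but the simulator emits forward-strand reads.

**Micro-homology normalization.** Because the excised segment is flanked by
a TA direct repeat, the deletion interval is ambiguous: shifting `[a, b]` by
`d` within the homology range leaves the spliced sequence unchanged. We
enumerate the exact homology range (character-by-character extension on both
sides), keep TA-led representations (interval starts with TA, retained TA
downstream), and report the one equal to an annotated IES if present, else
the leftmost. An earlier implementation walked in 2 bp steps requiring TA at
every intermediate step; that provably misses TA-led representations at odd
offsets inside TA-rich homology and was replaced after a brute-force oracle
disagreement — the oracle-equivalence acceptance test now passes at 100%
across seeds. Normalization is idempotent, and preferring the annotated
representation makes canonical-excision reads land exactly on annotated
intervals.

## Retention scoring and significance

Boundary score = `plus / (plus + minus)`, undefined (NA) for uncovered
boundaries; IRS = mean of defined boundary scores. An IES− read attests
excision at *both* boundaries and is counted into both minus tallies. For
significance, each boundary's counts are compared to the matched control
boundary with a one-sided Fisher exact test for elevated retention (computed
as the hypergeometric tail, which is algebraically the same test; the unit
tests cross-check against `fisher.test`), BH-adjusted across all boundaries.
An IES is significantly retained when at least one boundary passes
(`policy = "either"`, default; `"both"` is stricter and switchable — which
rule the original retention software used is not documented, so both are
provided). IESs failing the test form the "excised" set; `irs < 0.025`
(the lowest histogram bin) flags fully excised IESs. Because old-MAC
contamination dilutes IES+ evidence, absolute IRS values are not comparable
across experiments; the result table carries this caveat as an attribute,
and the package deliberately does not attempt contamination deconvolution.

## Error accounting

Alternative deletions and IES− evidence are collapsed to one event per
distinct normalized `(scaffold, a, b)` junction — an error junction counts
once however many reads support it. Classification against the annotation
assigns the maximal-overlap IES (ties to the leftmost, flagged `multi_ies`;
the source analyses never specify this case), with offsets measured TA-start
to TA-start, observed minus canonical on both sides. Deletions overlapping
no IES are reported separately as UNMATCHED rather than folded into IES
error classes. De novo errors are the set difference of error junctions
(autogamous minus parental), normalized per million mapped reads. The shift
spectrum counts |shift| over partial-internal events, excluding shifts ≤2 bp
(indistinguishable from junction micro-heterogeneity), and reports the mode.

## Numerical choices and degenerate inputs

* IRS histogram bins are left-closed widths of 0.025 with the final bin
  closed (0.024 and 0.026 fall in different bins; IRS = 1 is counted).
* Mann–Whitney length comparisons use `stats::wilcox.test` (exact small-
  sample p without ties, normal approximation with tie correction
  otherwise); the suite cross-checks small-n p-values against full
  enumeration of rank assignments.
* Undefined boundary scores propagate: one-sided IESs keep their defined
  side's score; doubly-undefined IESs are excluded from histograms and
  counted separately.
* Empty inputs (no IESs, no evidence, empty event tables) return typed empty
  tables, and a zero `total_mapped_reads` denominator is an error rather
  than an Inf rate.
* Seeds: every simulation entry point derives child seeds (kept below 2³¹)
  from the user seed per stage, so sample/control/parental draws are
  independent but jointly reproducible; identical configuration + seed gives
  byte-identical artifacts.

## What the simulator does not emulate

Green tests establish that the pipeline recovers what was planted under the
stated model — not that it reproduces every property of real sequencing:
no base-quality or indel error model (only optional uniform substitutions),
no paired-end insert-size information, no chromosome fragmentation or
imprecise transposon elimination, no ploidy or endoduplication modelling,
uniform coverage without GC or mappability bias, and old-MAC contamination
as a simple read-mixture fraction. Genome-scale published counts (thousands
of excised IESs, de novo error totals per KD) depend on the real deposited
datasets and are out of reach of desk-scale simulation; the acceptance
suite therefore checks properties — round-trip identity, oracle
equivalence, planted-parameter recovery, null calibration, exact set
accounting and qualitative size-bias reproduction — rather than published
numbers.
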