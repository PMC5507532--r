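---
title: "Stem-loop inhibition amplicon panels: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stem-loop inhibition amplicon panels: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slimamp)
```

## The problem

Sequencing the full coding region of a gene with amplicons requires *tiled*
amplicons: adjacent amplicons must overlap, so that every primer binding
site is itself covered by the insert of a neighbour and no base is
interrogated only through a primer (where a template variant is overwritten
by the primer sequence). But tiled amplicons cannot normally share one PCR:
the two *inner* primers of each overlapping pair (the reverse primer of the
left amplicon, R1, and the forward primer of the right amplicon, F2) prime a
short overlap product, and because every longer species templates it, the
overlap product outgrows everything else. With all efficiencies at 1, the
expected folds at cycle $n$ are

$$A_1 = A_2 = n\,2^n, \qquad A_4 = 2^n, \qquad A_3 = n^2\,2^n,$$

for the two targets, the long spanning product (outer primers) and the
overlap product respectively — the overlap product runs $n$-fold ahead of
the targets. `fold_closed_form()` returns these folds; `simulate_branching()`
iterates the underlying per-cycle recurrence (spanning doubles from itself,
each target gains from itself and the spanning product, the overlap gains
from every longer species). The recurrence's exact solutions are
$A_1 = n\,2^{\,n-1}$ and $A_3 = n(n+1)\,2^{\,n-2}$ — the same growth orders
as the closed forms up to constant factors, which is why our tests compare
ratios and growth orders between the two layers, never absolute copy
numbers.

## The inhibition mechanism

The package designs panels in which both inner primers of a junction carry
the *same* universal 5' tag, and a short 5' prefix of F2's gene-specific
sequence (denoted F2^, 7–14 nt in deployed designs) is inserted between the
tag and the gene-specific part of R1 (or symmetrically R1^ into F2). After
the first cycles, the overlap product then carries `tag + F2^` on one end
and its reverse complement on the other: the single strand folds into a
hairpin whose *terminal stem* sequesters both the tag and the first bases
of the F2 binding site. Re-priming of the overlap product now requires
annealing with only the 3'-terminal `gene length − insert length` bases —
too few at the raised second-stage annealing temperature — so the overlap
product stops amplifying. Crucially, a *tag-only* stem (same tag, no
insert, however long the tag extension) leaves the entire F2 site in the
loop; the primer outcompetes the stem and the overlap product amplifies
normally. The contrast between those two constructions is the core of the
method, and `find_terminal_stem()` makes it measurable: it reports the
longest exact terminal duplex (no wobble pairs, no bulges — the designed
stems are exact by construction, and the designed stem length is always
`tag length + insert length`; random interior sequence can extend the
duplex by a base or two, which the tests allow for).

## Melting temperatures

`melting_temp()` implements the Wallace 2+4 rule and a nearest-neighbor
calculation with the unified SantaLucia stack parameters, an entropy salt
correction of $0.368\,(N-1)\ln[\mathrm{Na}^+]$, and
$T_m = \Delta H / (\Delta S + R \ln(C/4))$. Defaults are 250 nM oligo and
an *effective monovalent cation concentration of 150 mM*. The effective
concentration stands in for a PCR buffer's combined monovalent and divalent
(Mg$^{2+}$) content; at a literal 50 mM Na$^+$ the published demonstration
primers evaluate to ~54–56 °C, outside the 60 ± 3 °C window they were
designed into, while at the 150 mM default all four fall inside it
(58.4–60.8 °C). Both parameters are exposed as arguments.

## The two-stage kinetic model

`simulate_slimamp()` turns a panel into a "virtual gel". Each species
(target, per-junction overlap, per-junction spanning product) gets one
efficiency per stage:

* **priming**: $e = \mathrm{logistic}\big((T_m^{\text{acc}} - T_{\text{anneal}} +
  \Delta T)/s\big)$, where $T_m^{\text{acc}}$ is the Tm of the *accessible*
  3' portion of the primer's binding site. Stage 1 (default 5 cycles at
  60 °C) uses the gene-specific portions — everything amplifies and the
  overlap species acquires its tagged, stem-forming ends. Stage 2 (default
  30 further cycles at 72 °C) uses the full tagged oligo on open templates,
  the full gene-specific site on tag-only-stem overlap templates, and
  `gene − insert` bases on stem-loop-inhibited overlap templates. The
  offset $\Delta T = 12$ °C and slope $s = 3$ °C are calibration constants
  chosen once so that a full-length tagged primer on an open template at
  72 °C primes at >0.9 while a 6-nt accessible site is inert; they are
  exposed in `slim_sim_params()`.
* **length gate**: extension efficiency is multiplied by
  $1/(1+\exp((L - L_{1/2})/w))$ with $L_{1/2} = 650$ bp, $w = 25$ bp, so
  the ~700 bp spanning product extends poorly while ≤550 bp species are
  unaffected. An exponential decay $e^{-\lambda L}$ was tried first and
  rejected: no single $\lambda$ both keeps the targets amplifying and
  prevents the spanning product from overtaking the (static) inhibited
  overlap product over 30 cycles; the sharper logistic gate reflects the
  threshold nature of incomplete extension in fast two-step cycling.

One efficiency per species means production of overlap molecules from
internal priming sites on longer templates is folded into the overlap
species' own (stem-gated) efficiency — every newly formed overlap molecule
immediately sequesters its ends, so its template route is what the stem
controls. This is a deliberate simplification: the model is qualitative,
aimed at reproducing the gel-level facts (inhibition increasing with insert
length, near-complete inhibition from 12 nt inserts, indifference to
tag-only stem length, faint spanning product), not quantitative kinetics.
No primer or dNTP depletion is modelled and cycle counts stay ≤ 40, so
expected copy numbers remain within floating-point range. Deterministic
expected-value kinetics only; there is no stochastic mode.

## Panel design

`tile_roi()` places amplicon inserts (primer sites included) over each
target interval, extended by a 30 bp margin so outermost primers sit
outside the region of interest. For a long interval of length $G$ the
amplicon count is $k = \mathrm{round}\!\big((G - o_t)/(L_t - o_t)\big)$
with target insert length $L_t = 331$ bp and target overlap $o_t = 100$ bp,
then a uniform layout is solved under the hard bounds (insert 263–380 bp,
overlap 49–193 bp), searching outward from $k$ if infeasible. A
maximise-the-insert greedy would tile a 4.9 kb interval with ~15 amplicons
of 380 bp; real deployed panels of this kind average ~331 bp and use ~21
amplicons over 4.9 kb, so the target-length layout is the default.
Everything is deterministic.

Primer selection (`slim_select_primers()`) anchors candidates at the
amplicon boundaries, allowing a bounded shift in either direction, and
requires Tm in 57–63 °C, no homopolymer run longer than 4, and no masked
SNP with minor allele frequency above 0.09% under the 3'-terminal 10 bases
(`check_3prime_snps()`; the threshold is kept as published even though it
is strikingly low, and is configurable). Ranking is |Tm − 60|, then 3' G/C
clamp, then genomic position — a total order, so design is reproducible.
Tags are assigned by 2-colouring each chain (`assign_tags()`): within an
amplicon the tags differ, at each junction the inner primers share one.
Both constraints are asserted after assignment rather than assumed.

## Synthetic data

`make_reference()`, `apply_variants()` and `simulate_reads()` generate the
package's own test data. Reads include the tag sequences (as in the real
library), mates are the first and last 250 bases of the tagged fragment,
substitution errors are injected at the profile's rate with base qualities
set to match ($Q = -10\log_{10} p$), and per-amplicon depth is log-normal
(σ = 0.35 by default) as a stand-in for amplification bias. Heterozygous
and homozygous variants are realised by sampling two haplotypes at equal
fractions (`build_haplotypes()`). The full-scale generator
(`synthetic_panel()`) tiles eight exon-like intervals — including one
4.9 kb and one 3.4 kb block, which tile into 21- and 15-amplicon chains —
for a 91-amplicon panel, the scale of a two-gene clinical coding panel.

What the generator does *not* emulate: PCR duplicates and chimeras, indel
sequencing errors (indels enter only through haplotypes), sequencer-specific
quality decay, mispriming against off-target genomic sequence. Passing
tests therefore demonstrate the pipeline's bookkeeping and statistics, not
robustness to every artefact of real libraries.

## Variant calling

Pairs are assigned to amplicons by their primer prefixes (exact panel
knowledge replaces genome-wide mapping: for a fixed panel the full forward
and reverse oligos are unique read prefixes, tolerating 2 substitutions
each). Reads are realigned to the expected tagged amplicon sequence with a
banded affine-gap Smith–Waterman (match +2, mismatch −4, gap open −6, gap
extend −1; a gap of length $L$ costs $6 + L$). The band half-width (96 by
default) comfortably covers the largest validated indels (40 bp); a
property test pins banded scores to an independent unbanded implementation.
Mates are merged into a phred-weighted consensus: agreeing bases add
qualities (capped at 60), conflicting bases keep the higher-quality base at
quality $|Q_1 - Q_2|$ (floored at 2), and pairs whose indel structures
disagree inside their overlap are dropped. Primer and tag bases are then
soft-clipped, so pileups cover only amplicon interiors.

Noise is estimated per segment: for every (position, non-reference base)
the quality-weighted frequency (weights $1 - 10^{-Q/10}$) joins the noise
collection if it is below a 5% candidate-exclusion ceiling (so true
variants do not inflate the gate); candidates must exceed
$\mu + 6\sigma$ of that collection, and pass only with ≥ 20 supporting
merged reads *and* ≥ 20% allele frequency — the stricter reading of the
published filter sentence, chosen as the clinically sensible one and
configurable. When a segment's $\sigma$ is exactly zero (error-free
synthetic data), a configurable absolute floor (0.005) replaces the gate.
Indels are aggregated from the alignment edit paths and left-aligned;
substitution noise pools per-(position, allele), the per-allele convention
making the expected background under a uniform error rate $p$ equal to
$p/3$ per alternative allele. Calls duplicated by overlapping amplicons
are collapsed, keeping the deeper segment's record.

Coverage is reported from merged (pair-collapsed) reads over the region of
interest: mean/median/min/max, the fraction of bases above
$k \times$ mean for $k \in \{0.1, 0.15, 0.2, 0.3, 0.4, 0.5, 0.75, 1\}$,
uniformity (the 0.2× row), and per-amplicon coverage on each amplicon's
non-overlapping region. Throughput projection scales from the constant
91,500 raw pairs per library for 500× mean amplicon coverage, flooring to
the nearest 100 (matching the published kit table's 1707→1700 and
2846→2800), with minimum coverage defined as 0.2× of the mean; the
pairs-to-coverage constant embeds an unstated efficiency factor and is
used as given, not derived. Confidence intervals are exact
Clopper–Pearson from the beta-quantile closed form, cross-checked against
`binom.test`.

## Problem sizes in the test-suite

The suite exercises the full study scale: the 91-amplicon synthetic panel
at ~1000× mean depth (≈ 90k read pairs) with 0.1% substitution error and
injected SNVs plus 1–40 bp indels at 50%/100% allele fraction, which must
yield 100% sensitivity, zero false positives and ≥ 98% uniformity; smaller
3-amplicon panels back the per-operation tests. Realignment equivalence is
checked on 200 random indel fixtures. These sizes were chosen to mirror
the study conditions while keeping a full run on one CPU in a few minutes.

## Known limitations

* The kinetic model is qualitative; it predicts orderings and suppression
  ratios, not molar yields, and encodes the tag-only-stem escape (branch
  migration through a tag-only stem) only through the accessibility rule.
* Stem detection is exact-complementarity only; G·U pairs, bulged stems
  and genuinely thermodynamic (ΔG) stability are out of scope.
* Primer assignment assumes panel oligo prefixes are mutually distinct
  beyond the mismatch tolerance — true for designed panels with distinct
  gene-specific primers, not for arbitrary oligo sets.
* The caller targets germline allele fractions (≥ 20%); somatic low-VAF
  calling is explicitly out of scope, as is annotation (HGVS/VEP) and
  mapping to a public genome build.
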