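---
title: "Anti-rRNA probe design: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anti-rRNA probe design: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribodesign)
```

## The problem

Enzymatic rRNA depletion hybridizes short single-stranded DNA probes to
ribosomal RNA and digests the resulting RNA:DNA duplexes with a
thermostable RNase H at 65 °C. Designing the probe set is a constrained
tiling problem: every rRNA species (and, ideally, the precursor-only
leader/spacer/trailer regions of the operon) must be covered densely
enough that no fragment survives, each probe must stay duplexed at the
reaction temperature, and probes must not be complementary enough to mRNA
to deplete genuine signal. This vignette documents the model this package
implements, the parameters that matter, and the choices made where the
design space was genuinely open.

## Duplex melting temperature

`melting_temperature()` implements the two-state unified nearest-neighbor
model: enthalpy and entropy are sums over stacked dinucleotides plus
initiation terms distinguishing terminal G·C from A·T pairs, and

$$T_m = \frac{\Delta H^\circ}{\Delta S^\circ_{salt} + R \ln C_T} - 273.15.$$

Two conventions deserve justification:

* **Duplex concentration.** We use $C_T$ = total probe concentration
  (default 0.25 µM) rather than $C_T/4$. The $C_T/4$ form assumes two
  strands at equal concentration; in the depletion reaction the synthetic
  probes are in large molar excess over their rRNA targets, for which the
  excess-strand form is the appropriate limit.
* **Salt.** The monovalent correction is entropic,
  $\Delta S^\circ_{salt} = \Delta S^\circ + 0.368\,(N{-}1)\ln[\mathrm{Mon}^+]$,
  and divalent magnesium (less dNTP chelation) enters as the standard
  monovalent equivalent $120\sqrt{[\mathrm{Mg}^{2+}]}$ mM.

**Default solution conditions.** The defaults are
`thermo_params(monovalent_mM = 100, divalent_mM = 3)`, the ionic milieu of
the depletion reaction itself (≈100 mM K⁺ from the hybridization buffer,
≈3 mM MgCl₂ co-delivered with the probes). This is a deliberate choice:
the 68 °C acceptance threshold — 3 °C above the 65 °C digestion
temperature — is only meaningful on the temperature scale of the reaction
the probes must survive in. At plain 50 mM Na⁺ a 32-mer at bacterial rRNA
GC content (~54%) melts in the mid-60s under any nearest-neighbor
parameterization, so a 68 °C threshold would reject most windows genome
wide; at reaction ionic strength the same windows melt in the low-to-mid
70s and nearly every designed probe clears the threshold, which matches
how the published panels behave. Low-salt evaluation remains available
(`thermo_params(monovalent_mM = 50, divalent_mM = 0)`) and the unit tests
pin the model against an independent nearest-neighbor implementation in
both regimes (0.5 °C tolerance).

The model assumes strictly A/C/G/T input of at least 8 nt (shorter
duplexes are outside the model's calibration) and treats the probe/rRNA
hybrid as DNA:DNA — the convention of the oligo calculators these
thresholds were historically chosen with — rather than using RNA:DNA
hybrid parameters.

## Consensus templates

Bacterial genomes carry several near-identical rRNA operons; probes are
designed once per rRNA type against a consensus:

* equal-length copies: column-wise majority, with per-position agreement
  (majority count / copies); ties take the base of the lowest-index copy,
  which makes the consensus deterministic and reproducible;
* unequal lengths: no alignment is attempted — the medoid copy (minimum
  summed 8-mer set distance to the others) becomes the backbone, agreement
  is computed over the equal-length members, and the template is flagged
  `"medoid"`. Indels among rRNA copies are rare enough in practice that a
  positional consensus after picking the right backbone is adequate, and
  it keeps the pipeline free of alignment heuristics.

## The tiling rule

With defaults (probe length L = 32, head offset 50, max gap 50, search
space 10, threshold 68 °C):

1. The first candidate window covers template positions 50–81 (1-based,
   inclusive). The head offset exists because the extreme 5′ end of the
   annotated rDNA is trimmed during rRNA maturation.
2. After accepting a probe ending at $e$, the next candidate starts at
   $e + \mathrm{max\_gap} + 1$ — "gap" counts template nucleotides covered
   by no probe. With L = 32 and gap 50 this produces one probe per 82 nt
   (~12 probes/kb); a gap of ~8 reproduces the denser ~40-nt spacing
   (~25 probes/kb) of published panels.
3. A candidate position whose window melts below threshold is slid
   upstream one position at a time (never into the previous probe; at most
   `search_space` positions). The first passing position is accepted —
   this keeps gaps maximal and the panel small. Only if all evaluated
   positions fail is the hottest one recorded, flagged
   `below_threshold = TRUE`; Tm ties resolve to the most downstream
   position.
4. With `allow_length_adjust` (off by default for mature rRNA; forced on
   for pre-rRNA regions), a below-threshold winner is extended one
   nucleotide at a time at its 3′ (template-downstream) edge, up to 43 nt,
   and keeps the first length that passes. If no extension passes, the
   original 32-mer is kept flagged — extension is an adjustment for
   passing, not an unconditional lengthening.
5. Windows that would overrun the template are clamped to end exactly at
   the template end; design stops when a clamped window would overlap the
   previous probe. Consequently no uncovered stretch between probes — and
   no tail — ever exceeds `max_gap`, and the head gap is `head_offset` − 1.

Probes are emitted as the reverse complement of their template slice
(they must hybridize the RNA), named `{template}_{index}`, and serialized
as FASTA plus a CSV of metadata (Tm reported to 0.01 °C; comparisons
internally use unrounded values). When genomic provenance is known, a BED6
of binding sites is emitted (0-based half-open, score = Tm × 100 clipped
to 0–1000, one line per gene copy).

## Pre-rRNA regions

Operons are transcribed as a single precursor; leaders, internal spacers
and trailers are present in pre-rRNA but absent from mature rRNA, so they
escape a mature-only panel — visible as residual intergenic read islands
in depletion experiments. `derive_pre_rrna_regions()` returns those
regions (default flanks 150 nt each side, a compromise covering the
processing stems without reaching into neighboring genes; the true
precursor extent varies by species). Each region is tiled as its own
template under the same head-offset rule, with length adjustment forced on
because spacers are AT-rich.

## Evaluation criteria

* **Transfer.** A probe "matches" a foreign rRNA if it has a full-length,
  indel-free placement with at most `max_mismatches` substitutions
  (default 1). The underlying criterion in published cross-species
  applications is not stated anywhere, so it is a parameter (0–3); under a
  substitution-only divergence model the expected matched fraction has the
  closed form $\sum_{i \le m} \binom{L}{i} d^i (1-d)^{L-i}$, which the
  test suite checks to within 3 standard errors.
* **Off-target.** The scanner reports every maximal exact shared run of
  `min_run` nt or more (inclusive ≥, default 15 — the run length above
  which off-target probe binding measurably suppresses gene expression)
  between a probe and the non-rRNA genome, on both strands. Alignment
  scores and E-values are deliberately not computed: the run-length
  criterion is the component that predicts expression bias, and it is
  exactly computable. The implementation is seed-and-extend
  (`min_run`-mer lookup with maximal extension, runs contained in a longer
  run of the same probe/strand dropped) and is required by the tests to
  agree exactly with a naive quadratic diagonal scan.

## Read accounting

`classify_reads()` assigns each mapped read to the labelled interval
(5S/16S/23S/pre-rRNA) with the largest overlap — at least one nucleotide;
ties go to the interval with the smaller start; otherwise `other` — with
strand ignored, since depletion targets both strands' read-through
equally. From SAM input only primary mapped alignments are counted, so
each read counts once. `rrna_fraction()` reports
$100 (n_{5S}+n_{16S}+n_{23S})/n_{mapped}$, with pre-rRNA as its own
category outside the subtotal, rounded to two decimals half away from
zero — the direction fixed by a published control row whose unrounded
value is 97.225005…% and prints as 97.23. Four of the 55 bundled published
accounting rows print a percentage exactly 0.01 above what their own count
columns give; they are flagged `known_discrepancy` in the bundled fixture
and the recomputation pins the offset rather than reproducing it.

## The synthetic generator

`generate_operon_genome()` emulates the features the tools above depend
on: multi-copy 16S–spacer–23S–spacer–5S operons (defaults 1542/2904/120 nt
genes, 440/90 nt spacers), copies mutated from a master at 0.2%
substitutions (bacterial intra-genome rRNA copies are >99.8% identical),
rRNA at GC 0.54 in background at GC 0.50, and at least one minus-strand
operon. Everything is substitution-only and truth-tabled, so probe
footprints map positionally and per-probe mismatch counts are computable
from the truth table. It does **not** emulate rRNA secondary structure,
conserved domains, indels, or sequencing error — so passing tests
demonstrate the correctness of the algorithms on operon-structured input,
not the biological performance of a panel on a real organism. Likewise
`simulate_depletion()` is an idealized model (a molecule is removed iff
some probe matches it perfectly) used to check end-to-end bookkeeping —
mature panels remove exactly the mature-rRNA molecules and spare
pre-rRNA; adding pre-rRNA probes removes those too — not a kinetic model
of RNase H digestion.

## Problem sizes and numerical choices

The checks in `scripts/acceptance.R` and the test suite run at desk scale:
two-operon synthetic genomes (~16 kb), panels of ~60–80 probes, off-target
subjects of 5–10 kb against naive-oracle comparison, 500-probe transfer
cohorts for the binomial comparison, and 1,000 short random templates for
the gap-bound property. Determinism: all generators draw from R's RNG
under locally scoped seeds (restored afterwards); identical seeds give
byte-identical artifacts. Degenerate inputs are contracts, not crashes:
templates shorter than the first window yield an empty probe set with a
warning; windows containing ambiguity codes are skipped with a warning;
empty read sets, empty probe sets at serialization, and mixed consensus
input are validation errors.

## Known limitations

* DNA:DNA thermodynamics stand in for the actual DNA:RNA hybrids.
* No secondary-structure or hairpin screening of probes.
* Transfer mapping is substitution-only (no indels).
* The consensus does not align copies of unequal length.
* Off-target screening reports exact shared runs only; thermodynamically
  assisted near-matches below `min_run` are not flagged.
* Cross-hybridization against host (e.g. human) transcriptomes is out of
  scope.
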