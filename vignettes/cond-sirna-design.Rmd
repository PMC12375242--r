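---
title: "Designing conditional siRNA riboswitch constructs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing conditional siRNA riboswitch constructs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condsirna)
```

## The design problem

A conditional siRNA (Cond-siRNA) is a three-strand RNA device whose
silencing activity is OFF until a chosen trigger mRNA switches it ON. The
worked example shipped with this package pairs a sensor for the *Nppa* 3'
UTR (natriuretic peptide A, upregulated in stressed cardiomyocytes) with a
guide against calcineurin A-alpha (*Ppp3ca*), so that the silencer activates
only in cells exhibiting the hypertrophic stress signature.

The three strands are:

* **guide** — the antisense siRNA strand (after activation, Dicer processes
  the central duplex and the guide loads into RISC);
* **core** — the central strand: its middle 23 bases pair the guide (the
  Dicer substrate), and its 5' and 3' ends fold back onto the sensor;
* **sensor** — the strand complementary to the trigger mRNA. Its first 23
  bases clamp the core's two overhangs (split 11/12), holding the construct
  in the inactive state; its 3' tail is a single-stranded toehold.

The trigger invades at the toehold and displaces the sensor by branch
migration: the full-length trigger:sensor duplex (31–33 bp) out-competes the
11 + 12 bp clamps, uncaging the Dicer substrate.

## The design pipeline

### 1. Window screening (`screen_trigger()`)

Every 31–33 nt window of the trigger is enumerated and scored:

| parameter | default | meaning |
|---|---|---|
| `window_lengths` | 31–33 | candidate segment lengths (toehold = length − 23) |
| `gc_lo`, `gc_hi` | 0.45, 0.55 | GC-fraction bounds ("about 50% GC") |
| `motifs` | GGGG, MMMM | forbidden motifs; M matches A or U |
| `fold_ceiling` | 6 pairs | advisory ceiling on sensor self-structure |
| `k` | 15 | off-target k-mer length |

GC content is computed on the window (it is identical for both strands);
motif scanning is applied to the derived sensor — the strand that is
actually synthesized, where a G quartet or a run of four weak (A/U) bases is
a synthesis or stability liability — with an option to screen both strands.
The worked-example sensor (GC 17/31 ≈ 0.548, no motif hits) passes these
defaults, which is one of the regression anchors in the test suite.

**Hard filters vs. advisory flags.** A window is excluded when it has a
motif hit, GC outside the bounds, or (when a background is supplied) at
least one off-target hit. The Nussinov fold score is *advisory*
(`fold_ok`): maximum-base-pair counts run structurally high — a random
31-mer usually admits 8–11 nested pairs — so a hard ceiling at the default
of 6 would empty most screens; the score is instead used for ranking, where
lower self-structure wins. Survivors are ordered by the deterministic tuple
(|GC − 0.5|, fold score, 5'-most start), a total order, so repeated runs
produce byte-identical reports. The ranking formula is a package policy (the
published protocol says only that candidates were "prioritized") and every
component of it is overridable through `screen_config()`.

### 2. Off-target screening (`build_kmer_index()`)

The published protocol screened candidate sensors with BLAST against the
mouse/rat genome. Offline and deterministically, this package instead builds
an exact k-mer index over a user-supplied background transcriptome and
counts records sharing any k-mer with the sensor. Matching is
**strand-agnostic** — each sensor k-mer is looked up as-is and as its
reverse complement — because an alignment search covers both strands and
because the transcript the sensor is *meant* to hit contains the reverse
complement of the sensor, not the sensor itself; the intended target is
then removed by id (`exclude_ids`). The default k = 15 is a conservative
proxy for a "meaningful" exact match; no mismatch tolerance is attempted
(a gapped or mismatch-tolerant search is out of scope), so the screen
under-counts near-matches relative to BLAST and k should be lowered rather
than raised when in doubt.

### 3. Construct assembly (`build_sensor()`, `build_guide()`, `build_core()`)

The geometry is fixed by three complementarity rules (positions 1-based,
sequences 5'→3'):

* sensor = reverse complement of the window; toehold = positions 24..end;
* guide = 5' extension + validated siRNA + 3' dinucleotide overhang, with
  positions 1..23 forming the Dicer duplex;
* core = revcomp(sensor[1..11]) ∥ revcomp(guide[1..23]) ∥
  revcomp(sensor[12..23]).

For a generalized sensor-pairing region of P bases the core split is
floor(P/2)/ceiling(P/2), which reproduces the canonical 11/12 at P = 23.
Longer windows (32, 33 nt) extend the toehold only; the clamped region
stays at 23 bases, since the toehold is the component whose length tunes
activation kinetics while the clamp geometry defines the OFF state.

A subtlety in the guide arithmetic: a canonical 21-nt siRNA guide already
carries its 2-nt 3' overhang (19 paired bases + UU). `build_guide()`
therefore appends the overhang only when the input does not already end
with it (`includes_overhang` overrides the suffix auto-detection), so a
21-nt UU-ended siRNA needs a 4-base 5' extension to reach the 23-base
pairing region — exactly the "four GC-rich bases" of the worked example. A
supplied extension must be GC-rich (≥ 3 of 4 bases G/C — the worked-example
extension CGAG shows "GC-rich" does not mean all-GC); an omitted extension
is auto-chosen from {G,C} by exhaustive search minimizing the
nearest-neighbor ΔG of the extended duplex, ties broken G before C.

`assemble_construct()` re-derives all three duplexes base by base and
refuses any mismatch, naming the first offending position pair;
`verify_assembly()` reports duplex lengths and ΔG37, the unpaired regions,
and the nick between the core's central and 3' segments (the locus treated
as the "middle toehold" by the modification presets).

### 4. Thermodynamic evaluation (`duplex_dG()`, `nussinov_fold()`, `displacement_ddG()`)

Binding affinities use the unified RNA/RNA nearest-neighbor ΔG°37
parameters (Xia et al. 1998), shipped as a versioned plain-text asset:

ΔG37(duplex) = ΔG(init) + Σ stacks + 0.45 × (terminal A·U pairs).

Only perfect duplexes are evaluated — every duplex in the construct is
perfect by construction — so loop/bulge parameters are unnecessary. The
self-complementarity symmetry correction is likewise omitted: designed
strands are never self-complementary duplexes. Temperature is fixed at
37 °C; no salt correction is applied.

Sensor secondary structure is screened with a Nussinov maximum-base-pair
dynamic program (Watson–Crick pairs, optional G·U wobble off by default,
minimum hairpin loop 3). Maximum pair count was chosen over MFE because the
screen needs only a monotone, parameter-free "how much structure could this
strand form" signal with an exactly testable oracle (explicit enumeration
of all well-nested structures at small n). The traceback is deterministic:
when pairing the 3' base ties with leaving it unpaired, it is paired, with
its 5'-most admissible partner. `rnafold_crosscheck()` is a documented hook
that folds the same strand with ViennaRNA's `RNAfold` when that executable
is installed; it is a qualitative comparison aid only and nothing in the
package requires it.

The strand-displacement score summarizes switchability:

ΔΔG = ΔG(trigger:sensor) − [ΔG(clamp 5') + ΔG(clamp 3')],

negative when the trigger thermodynamically displaces the sensor. It is an
equilibrium statement only — toehold-mediated displacement *kinetics* are
out of scope.

### 5. Chemical modifications (`apply_preset()`, `serialize_notation()`)

Three generations of chemistry ship as editable YAML presets: `firstG`
(LNA at the 3' toehold end and the middle toehold, sparse terminal
phosphorothioates on the sensor), `secondG` (adds 2'-O-methyl across the
guide pairing region), `cholConj` (adds a sensor 3' cholesterol-TEG
conjugate). The published account specifies these patterns only
qualitatively (the per-position chemistry appears only in a color-coded
figure), so the preset *positions* are illustrative defaults, clearly
intended to be edited before an actual synthesis order; what is load-bearing
in the package is the machinery: named-region resolution on a concrete
construct, deterministic and idempotent application, and a lossless
vendor-style notation (`m` = 2'-O-methyl, `+` = LNA, `*` = phosphorothioate
linkage, bracketed terminal conjugate tags). "Middle toehold" is mapped to
the two sensor bases flanking the junction where core pairing jumps from
the core's 5' arm to its 3' arm (positions 11–12 at P = 23); this mapping
is an interpretation and is confined to preset data.

## The synthetic-data generator

`synth_transcript()` and `synth_background()` make every stage testable
without downloads. Transcripts are sampled at an exact GC composition
(`round(gc · L)` G/C residues, then a permutation), with implants placed
verbatim; decoy backgrounds are rejection-sampled until they share no k-mer
(either strand) with a protected sequence, keeping base composition
unbiased at the cost of a bounded number of resamples. Defaults (trigger
200 nt, decoys 300 nt, GC 0.5, k = 15) are desk-scale stand-ins for a
3' UTR and a transcriptome. The generator emulates sequence composition
only: real transcriptomes have shared repeats, isoforms and biased local
composition that make genuine off-target screening much harder than the
clean-decoy case, and passing screens here say nothing about sensor
performance in cells (expression level, RNA structure in vivo, protein
binding). Those limits are inherent to any sequence-only design step.

## Numerical and testing choices

* All coordinates 1-based inclusive; all sequences 5'→3'; T silently
  transcribed to U on ingest so GenBank DNA records paste in directly.
* All reports (TSV/JSON) embed the effective configuration and are written
  in binary mode with fixed number formatting, so identical inputs give
  byte-identical files.
* The test suite checks the fold DP against explicit enumeration of all
  well-nested structures for 200+ random sequences of length ≤ 12, the
  duplex ΔG against an independent hand-sum over the shipped asset for
  100+ random duplexes, and the k-mer screen against a naive substring
  scan; screen sizes in tests (triggers 100–200 nt, backgrounds of 3–10
  records of 120–300 nt) keep the whole suite well under a minute while
  exercising every code path.
* The worked-example triad (guide 25 nt, sensor 31 nt, core 46 nt) must
  reconstruct byte-for-byte from its base inputs; this is the package's
  primary regression anchor.

## Known limitations

* Equilibrium nearest-neighbor energies only: no ensemble/partition
  function, no kinetics, no temperature or salt dependence. Agreement with
  ensemble predictors (the published protocol used Nupack) is qualitative.
* Off-target screening is exact-match only; no mismatch or gap tolerance.
* No prediction of Dicer cleavage register, RISC loading strand bias, or
  3D structure.
* Modification presets carry illustrative positions, not the exact
  published chemistries.
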