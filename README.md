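# condsirna

Design toolkit for **conditional siRNA (Cond-siRNA) riboswitch constructs**
— three-strand RNA devices whose silencing activity stays OFF until a
chosen trigger mRNA switches them ON by toehold-mediated strand
displacement. The package is aimed at RNA-therapeutics and synthetic-biology
groups designing cell-state-gated silencers, e.g. a sensor for the *Nppa*
3' UTR (a cardiomyocyte stress biomarker) gating an siRNA against
calcineurin A-α (*Ppp3ca*).

## The device and the design rules

A construct is a guide/core/sensor triad (all sequences 5'→3', positions
1-based):

```
guide   1..23 pair core central          + 2-nt 3' overhang (UU)
core    = rc(sensor[1..11]) ∥ rc(guide[1..23]) ∥ rc(sensor[12..23])
sensor  = rc(trigger window);  1..23 clamp the core;  24..end = toehold
```

The sensor's first 23 bases clamp the core's two overhangs (11 + 12 bp),
caging the 23-bp central Dicer substrate; the 8–10 nt toehold stays
single-stranded. The trigger invades at the toehold and displaces the
sensor whenever the net displacement free energy

ΔΔG = ΔG₃₇(trigger:sensor) − [ΔG₃₇(clamp 5') + ΔG₃₇(clamp 3')] < 0,

with duplex energies from the unified RNA/RNA nearest-neighbor model
(ΔG₃₇ = initiation + Σ stacks + terminal A·U penalties; Xia et al. 1998
parameters shipped as a versioned asset). The pipeline:

1. **screen** every 31–33 nt trigger window: GC in [0.45, 0.55], no
   GGGG/MMMM motif (M = A/U) on the derived sensor, Nussinov
   maximum-base-pair fold score, exact strand-agnostic k-mer off-target
   screen (default k = 15) against a background transcriptome;
2. **design**: build sensor/guide/core with the geometry above (GC-rich
   5' guide extension to 23 paired bases, auto-chosen if omitted), verify
   every duplex base by base;
3. **evaluate**: per-duplex ΔG₃₇ and the displacement score;
4. **modify**: apply first-generation / second-generation /
   cholesterol-conjugate chemistry presets (LNA, 2'-O-methyl,
   phosphorothioate, terminal conjugates) and serialize them in a lossless
   vendor-style notation (`mA*+C` = 2'-O-methyl A, PS linkage, LNA C).

## Worked example

The validated 21-nt siRNA guide against calcineurin (19 bp + UU overhang)
plus its published trigger window on the *Nppa* 3' UTR:

```r
library(condsirna)

window <- "UUGGUCGCAUUGCCACUGAGAGGUGGUGAAG"   # 31-nt trigger segment
res <- run_design(window, "UGUUGUUUGGCUUUUCCUGUU", extension = "CGAG",
                  out_prefix = NULL)
print(res$construct); print(res$report); print(res$displacement)
```

```
<cond_sirna construct>
  guide  5'-CGAGUGUUGUUUGGCUUUUCCUGUU-3' (25 nt)
  sensor 5'-CUUCACCACCUCUCAGUGGCAAUGCGACCAA-3' (31 nt)
  core   5'-AGGUGGUGAAGCAGGAAAAGCCAAACAACACUCGAUUGCCACUGAG-3' (46 nt)
  duplexes 11/23/12 bp | toehold GCGACCAA (8 nt) | guide overhang UU
<assembly_report> PASS
  clamp5 core[1..11]:sensor[1..11]  11 bp  dG37  -18.12 kcal/mol
  dicer  core[12..34]:guide[1..23]  23 bp  dG37  -39.89 kcal/mol
  clamp3 core[35..46]:sensor[12..23]  12 bp  dG37  -19.25 kcal/mol
<displacement_score>
  dG trigger:sensor    -63.04 kcal/mol
  dG clamp 5'          -18.12 kcal/mol
  dG clamp 3'          -19.25 kcal/mol
  net ddG              -25.67 kcal/mol (displacement favorable)
```

Reading it: the 4-base GC-rich extension CGAG brings the 21-nt siRNA to a
23-base pairing region (the Dicer substrate, −39.9 kcal/mol); the sensor's
first 23 bases clamp the core as 11 + 12 bp duplexes (−18.1 and −19.2
kcal/mol) with the 8-nt toehold GCGACCAA left single-stranded; the
full-length trigger:sensor duplex (−63.0 kcal/mol) beats the clamps by
−25.7 kcal/mol, so trigger-driven displacement is strongly favorable.

Screening a transcript end-to-end:

```r
cfg <- screen_config()                       # 31-33 nt, GC 0.45-0.55, k = 15
tab <- screen_trigger(trigger, cfg, background)   # rna_seq + list of rna_seq
head(tab[order(tab$rank), ])                 # survivors ranked by |GC-0.5|, fold, start
```

A thin command-line front end (`screen` / `design` / `evaluate` /
`fixtures`) is installed at `inst/cli/condsirna.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/condsirna.R", package="condsirna"))')" \
  design --window UUGGUCGCAUUGCCACUGAGAGGUGGUGAAG \
  --sirna UGUUGUUUGGCUUUUCCUGUU --extension CGAG --preset cholConj --out construct
```

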