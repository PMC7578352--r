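---
title: "Ensemble contact-map perturbation analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble contact-map perturbation analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactdiff)
```

## The model

`contactdiff` asks a simple question of a pair of structural-model
ensembles: *which residue–residue contacts change consistently between
wild type and mutant?* The analysis chain is deliberately elementary —
binary contacts, counting, a threshold — because its value lies in being
applied over an ensemble rather than a single model, where any one
contact's presence is hostage to modelling noise.

**Contact criterion.** Residues $i$ and $j$ of one model are in contact
iff some heavy-atom pair (one atom from each residue) lies strictly
closer than a cutoff $d$:

$$C_{ij} = \mathbb{1}\!\left[\min_{a \in i,\, b \in j} \lVert a - b\rVert < d\right],
\qquad d = 4.5\ \text{Å (default)}.$$

Hydrogens and deuteriums never participate: modelled and crystallographic
coordinates frequently lack them, and a heavy-atom criterion is invariant
to that. The inequality is *strict*; a pair at exactly 4.5 Å is not a
contact, and a test pins this boundary by bisection.

**Ensemble selection.** Comparative-modelling runs score every model with
two lower-is-better quality functions (a statistical potential such as
DOPE and the modelling objective itself). `select_models()` keeps the
union of the top $k$ under each score, $k = 10$ by default, giving the
conventional 20-model ensemble. The two top-$k$ sets can overlap; when
they do, the union is backfilled with the next-best models by the first
score's rank so that the ensemble size stays $2k$ — the selection is then
still purely score-driven, and the backfill is reported. Ranks break ties
by model id, so identical tables always select identical ensembles.

**Frequencies, difference, annotation.** For ensemble $E$ with $n$
models, $f_E(i,j) = \#\{m \in E : C^m_{ij}\}/n$ — always an exact integer
count over $n$. The difference map is

$$\Delta_{ij} = f_{\mathrm{WT}}(i,j) - f_{\mathrm{MUT}}(i,j) \in [-1, 1],$$

so a contact *lost* upon mutation is positive and one *gained* is
negative. A pair is annotated when $|\Delta_{ij}| > t$ strictly, default
$t = 0.40$: with $n = 20$ this is exactly "discordant in more than 8 of
the 20 models", i.e. 9 or more. Both boundaries (8 silent, 9 annotated)
are pinned by tests and by the acceptance sweep.

Because $\sum_{ij} \Delta_{ij} = \bar{c}_{\mathrm{WT}} -
\bar{c}_{\mathrm{MUT}}$ (the difference of mean per-model contact
counts), the all-pairs sum reads directly as a net change in expected
contact count. Whether a headline figure like "about five contacts lost"
should sum over all pairs or only annotated ones is a genuine ambiguity;
`net_contact_change()` computes both, and the run report carries both,
with neither silently preferred. Region filters (chain-interface
restriction) expose the same sum per subunit interface.

**Beads.** Each annotated pair is visualized as a pseudo-atom at the
midpoint of the two residues' heavy-atom centroids in a reference model —
chosen as the best wild-type model under the first score, since the
figure needs one concrete set of coordinates and the wild type is the
common frame. The signed $\Delta$ maps linearly into red–white–blue:
$(1,0,0)$ at $+1$, $(1,1,1)$ at $0$, $(0,0,1)$ at $-1$. The PDB B-factor
column carries $\Delta$ rounded to two decimals (the PDB field's
precision); the exact values and RGB triples go to a companion TSV.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `cutoff` | 4.5 | Å | generous heavy-atom contact radius; strict `<` |
| `min_seq_sep` | 1 | residues | excludes only self-pairs; sequence-adjacent contacts are constant across ensembles and cancel in $\Delta$, so removing them is optional (`2+`) rather than default |
| `include_het` | `FALSE` | — | cofactors/waters are parsed but contact analysis concerns amino-acid residues |
| `k` | 10 | models | per-score retention; $2k = 20$-model ensembles |
| `threshold` | 0.40 | fraction | strict; with $n=20$, ">8 of 20 models" |
| `max_da` | 3.5 | Å | H-bond donor–acceptor heavy-atom distance; no angle term because hydrogens are usually absent |
| bridge cutoff | 4.0 | Å | minimal N–O distance between charged groups, standard literature value |

Histidine counts as basic in salt bridges through both ring nitrogens —
its protonation is ambiguous at physiological pH, and the permissive
reading can be narrowed by the caller but not silently. The backbone atom
set is fixed to N, CA, C, O; everything else is side chain.

## Sequence correspondence

Residue numbering differs between homologs (e.g. position 230 in one
SDHB sequence aligning to 244 in another); `map_position()` converts
through a provided alignment column by column, with per-sequence
numbering offsets, returning `NA` where the target is gapped. Percent
identity/similarity uses the Clustal "strong" groups (STA, NEQK, NHQK,
NDEQ, QHRK, MILV, MILF, HY, FYW) as the default notion of "similar" — a
convention, not a constant, so the grouping and the denominator
(mutually ungapped columns, or the shorter sequence's length) are both
explicit arguments. Published identity/similarity figures rarely state
either convention, so such figures are treated as approximate external
reference points, never as calibration targets.

## What the synthetic generator emulates — and what it does not

`ensemble_spec()` + `make_perturbed_ensembles()` reproduce the
*statistical* structure the analysis assumes: two ensembles sharing one
residue numbering, almost all contacts conserved, and a designated
minority of pairs each broken in exactly $m$ of $n$ mutant models. The
geometry is a coarse lattice — residues are stacks of 1–4 carbon
pseudo-atoms, 10 Å apart within chains, 30 Å between chains — engineered
with wide safety margins around the 4.5 Å boundary: designed contacts sit
at 3.8 Å, broken states at 8 Å, everything else at ≥ 10 Å. With the
default coordinate jitter (sd 0.05 Å) every designed relation stays more
than ten standard deviations from the cutoff, so noise cannot flip a
contact, and the difference map must equal $m/n$ on designed pairs and 0
elsewhere. Which $m$ mutant models break a pair is a seeded draw without
replacement; all generation is reproducible from the spec's seed.

The generator is **not** a protein: no sterics, no realistic packing, no
correlated motions, no partial contact weakening (a pair is either
cleanly made or cleanly broken). A passing parameter-recovery suite
therefore demonstrates that the *pipeline arithmetic and thresholds* are
exact, not that real homology-model ensembles are this clean — in real
ensembles frequencies populate the full $[0,1]$ range and the threshold
genuinely discards weak signals.

## Numerical choices

- Distances are compared in squared form in double precision; the strict
  boundary is exact for representable inputs (4.5² = 20.25 exactly).
- The cell-list acceleration (cell edge = cutoff, 27-neighbour search) is
  required to be *bit-identical* to the all-pairs definition; a
  brute-force oracle written independently of the package verifies this
  on 100 random toy models in the test suite. Correctness is tested, not
  assumed.
- Alternate locations: the highest-occupancy conformer is kept, ties
  broken by altloc letter ('A' first).
- Blank element columns are inferred from the atom-name convention
  (leading digits stripped; `H*` is hydrogen), with a message per file.
- Pair identity is always the author numbering (chain, residue number,
  insertion code), never renumbered; pairs are stored unordered with a
  canonical (chain, number, icode) orientation. Residue *names* may
  differ between ensembles at mutation sites — that is the mutation.
- Degenerate inputs: a residue with no heavy atoms is "not in contact"
  with a warning; an empty annotation set writes a valid, empty bead
  file; an empty pair selection sums to 0 with a warning.
- `min_seq_sep` compares author residue numbers, so insertion-code
  variants of one number (100 vs 100A) count as separation 0.

## Problem sizes

The shipped tests and the acceptance sweep run on deliberately small
instances — toy complexes of 8–20 residues, ensembles of 20 models, 100
random models for the oracle comparison — chosen so the whole suite
completes in well under a minute while still exercising every boundary
(8-vs-9 of 20, 4.499 vs 4.5 Å) exactly. All quantities checked are
scale-free fractions and counts, so nothing about the arithmetic changes
at protein scale; only wall-clock time does.

## Known limitations

- Contacts are binary; no distance-weighted or soft variants, no
  Cβ/centroid definitions.
- No statistical significance is attached to $\Delta$ values — the method
  reports consistency across an ensemble, not a p-value against a null.
- H-bond detection is distance-only by default; with hydrogens present a
  D–H…A angle filter would be the natural extension. Published per-residue
  hydrogen-bond counts from crystal structures are useful *external*
  sanity checks of the default criteria, but they are not calibration
  targets — geometric H-bond definitions vary enough across the
  literature that criterion tuning against one report would overfit.
- mmCIF input, superposition, and model building are out of scope; the
  package consumes PDB-format models produced elsewhere.
- Identity/similarity conventions in the literature are heterogeneous;
  comparisons to published percentages should expect a few points of
  convention-dependent spread.
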