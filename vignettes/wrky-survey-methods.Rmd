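---
title: "Methods: rule-based annotation of the grapevine WRKY family"
author: "wrkykit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based annotation of the grapevine WRKY family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

WRKY transcription factors are defined by a ~60-residue DNA-binding domain:
a near-invariant `WRKYGQK` heptapeptide followed by a zinc-chelating motif,
either Cys2His2 (C2H2) or Cys2HisCys (C2HC). The family partitions into
group I (two WRKY domains), group II (one C2H2 domain, subgroups IIa–IIe)
and group III (one C2HC domain); group II proteins bind the W-box element
`(C/T)TGAC(T/C)` in target promoters, as do the others.

`wrkykit` re-implements a genome-survey workflow for this family as a
deterministic, rule-based pipeline:

1. **Domain detection** (`scan_domains()`): heptapeptide windows within a
   configurable Hamming distance of `WRKYGQK` are paired with the leftmost
   downstream zinc finger matched by the spacing grammar
   `C-X(s1)-C-X(s2)-H-X(s3)-[H|C]`.
2. **Classification** (`classify_proteins()`): group by domain count and
   terminal ligand; group II subgroup by a transparent rule layer plus an
   optional nearest-reference match.
3. **Accessory motifs** (`find_protein_motif()`, `find_wbox()`,
   `predict_leucine_zipper()`): LXXLL coactivator, LXLXLX (EAR-like)
   repressor, the HARF signature of subgroup IId, W-boxes in DNA, and a
   heptad-periodicity heuristic for leucine zippers.
4. **Physical properties** (`protein_properties()`): length, average
   molecular weight, isoelectric point.
5. **Phylogeny** (`neighbor_joining()`, `bootstrap_support()`): NJ trees
   from global-alignment p-distances with column-resampling bootstrap.
6. **Expression** (`relative_quantity()`, `call_panel()`,
   `summarize_panel()`): 2^(−ΔΔCt) relative quantification of replicate Ct
   tables and induced/repressed/unchanged calling.

A packaged catalog (`load_catalog()`) reproduces the published grapevine
family table — 80 proteins across five *Vitis* taxa — as the machine-readable
anchor for count-level validation.

## The zinc-finger grammar and its defaults

The grammar ranges default to the permissive union
`s1 ∈ [4,8]`, `s2 ∈ [22,28]`, `s3 ∈ [1,2]` (`wrky_scan_config()`). The
published catalog itself motivates the union: its group III rows carry
`C-X7-C-X23-HTC` fingers, which narrower textbook C2HC ranges would reject.
All ranges are configuration, not constants.

The heptapeptide tolerance defaults to one mismatch — the family's natural
variants (e.g. `WRKYGKK`) differ by a single substitution — with the
tryptophan at position 1 additionally required to be invariant, since no
reported variant alters it (`require_w = FALSE` relaxes this). The linker
between heptapeptide end and first finger cysteine is capped at 30 residues
(the domain's ~60-residue span minus heptapeptide and finger), and a whole
domain may span at most 80 residues.

Coordinates are 0-based half-open throughout. Among overlapping finger
candidates the scanner prefers the smallest first-Cys position, then the
smallest spacers, which makes detection deterministic; domains fully nested
inside another are removed.

Pattern strings use the catalog's compact notation: C2H2 fingers always
render as `C-Xa-C-Xb-HXH`; C2HC fingers interpolate the observed residue
between His and the terminal Cys (`C-X7-C-X23-HTC`). `parse_pattern()` and
`format_pattern()` are mutually inverse on this convention (the observed
spacer residue of a C2H2 finger is deliberately not serialized).

## Subgroup assignment: a transparent surrogate

The original survey assigned group II subgroups from NJ clades of the real
domain sequences, which are not reproducible from printed material alone.
`assign_subgroup()` substitutes a layered, auditable scheme and records
which layer fired:

1. **HARF override**: the literal `RTGHARFRR(A/G)P` anywhere in the protein
   forces IId — the motif is diagnostic of that subgroup.
2. **Spacer rule**: `s1 = 4` forces IIc; in the packaged catalog every IIc
   member has a `C-X4` finger and every other group II subgroup `C-X5` or
   wider, so the rule is exact on the catalog's own terms.
3. **Nearest reference**: global-alignment identity against a labelled
   reference set of domain sequences, ties broken to the lexicographically
   smallest label.

This is a deliberate substitute, not a re-implementation, of the
phylogenetic subgrouping; its accuracy on real sequences depends entirely on
the reference set supplied. Positional quirks in the published table (the
protein whose two domain labels are printed in swapped order) are carried
through verbatim in `domain_label` and never "corrected".

## Phylogeny

Pairwise distances come from global Needleman–Wunsch alignment (affine
gaps, BLOSUM62, gap open 10, extend 0.5; a gap of length *k* costs
`open + k·extend`), followed by the uncorrected p-distance over gap-free
columns. Neighbor joining is the standard Saitou–Nei agglomeration; equal
Q-criterion candidates resolve to the lexicographically smallest pair of
cluster representatives, so the tree is a pure function of the matrix.
Negative branch-length estimates are clamped to zero with a message.
Trees are unrooted (basal trifurcation); published figure rootings are
presentation choices and out of scope.

Bootstrap support resamples alignment columns with replacement, rebuilds
the NJ tree per replicate, and tallies the reference tree's internal
bipartitions; supports are counts out of `n_boot` (default 1000, matching
the published analysis). The conventional display threshold of 500/1000
applies only at report time. With a fixed seed the procedure is
bit-reproducible, and the caller's RNG state is restored afterwards.

The progressive aligner (`progressive_msa()`) exists to produce domain
alignments without external binaries: an NJ guide tree from pairwise
p-distances, then profile–profile Needleman–Wunsch with average BLOSUM62
column scores. At the profile level the affine penalty is amortized into a
linear per-gap-column cost of `(open + 2·extend)/2`, a simplification
appropriate for the near-equal-length domain sequences this package
aligns; it is not a general-purpose MSA tool.

## Physical properties

Molecular weight is the sum of average residue masses plus one water.
The isoelectric point solves `net_charge(pH) = 0` by bisection on [0, 14]
to |charge| < 1e−4; net charge is the Henderson–Hasselbalch sum over the
termini and the D/E/C/Y (acidic) and H/K/R (basic) side chains, hence
composition-only and permutation-invariant. Two pKa tables ship
(`wrky_pka()`): the EMBOSS-style set (default) and a Bjellqvist-style set
with a flat N-terminal pKa; any named vector can be substituted. Published
pI/MW columns cannot be validated sequence-by-sequence — the survey's
sequences are not printed, and the pKa set behind the published numbers is
unknown — so catalog comparisons are summary-level (min/max targets) only.
The catalog stores printed values verbatim; the one physically implausible
molecular weight (278 residues printed as 3.9 kDa) is flagged
`mw_implausible` rather than repaired.

## Expression calling

Replicates are averaged on the Ct scale before ΔΔCt (a configuration of
the design generator can emulate per-replicate workflows downstream), the
reference gene and the t = 0 calibrator normalize each series, and
`rq = 2^(−ΔΔCt)` with `rq(0) = 1` exactly. The survey gives no numeric
fold-change cutoff for its three-way induced/repressed/unchanged language;
the package adopts the conventional qRT-PCR thresholds — induced at
max rq ≥ 2, repressed at min rq ≤ 0.5 over post-treatment timepoints, the
larger |log2 rq| winning when both are crossed (tie → induced) — and
exposes both thresholds as arguments. Calls annotate the triggering
timepoint.

`summarize_panel()` is exact set algebra. On the packaged 28-gene panel
design it reproduces the published category arithmetic: after pathogen
challenge 3 unchanged + 2 repressed + 23 induced (25 altered), after
salicylic acid 5 unchanged + 23 induced. The published panel is sized 28
but enumerates 26 gene names; `wrky_expression_panel()` supplements two
catalog genes (flagged `supplemented = TRUE`, induced under both
treatments) so the stated size and the category arithmetic cohere. Under
this design 19 genes are induced under both treatments, whereas the
original text claims "16 of 23" and then lists 18 names; the package
exposes the computed intersection and leaves the source's internal
inconsistency as documentation, asserting none of 16, 18 or 19 as a
validation target. Similarly, the source states 19 group I members while
its table lists 18 two-domain entries, and its cross-species count table
totals 72 against the stated 80; the catalog follows the table literally.

## The synthetic-data generators

`make_protein()` emulates the domain architecture the pipeline must
detect: planted heptapeptide + linker + finger elements and literal motif
instances at fixed positions, on a background drawn uniformly from the 19
amino acids excluding tryptophan. Excluding W makes accidental
heptapeptide hits impossible (every hit requires the invariant W), and
spacer fillers inside planted fingers exclude C/H/W so ligand positions
are unambiguous; post-validation re-scans the product and resamples the
background until the scan reports exactly the planted domains (bounded
retries, then error). Generators are pure functions of (spec, seed).

`make_family()` mutates subgroup seed domains at a programmed rate outside
the heptapeptide and ligand positions, keeping every member scannable.
`make_panel_ct()` writes Ct values as
`baseline − log2(fold) + N(0, sd)` against a flat reference gene, with the
programmed folds (default 4× induction, 0.25× repression at 24 h,
technical noise sd 0.15 cycles, 3 replicates, five timepoints 0/9/12/24/48 h,
two treatments) chosen to mirror a defense-response qRT-PCR experiment and
validated for consistency with the calling thresholds at design time.

What passing these tests shows — and does not show: synthetic backgrounds
are compositionally uniform and signal-free by construction, so planted
recovery rates certify the scanner's correctness against its own grammar,
not its sensitivity/specificity on real proteomes; likewise the Ct
generator has no amplification-efficiency, pipetting or melt-curve
artifacts, so call-recovery results certify the ΔΔCt arithmetic, not assay
robustness.

## Problem sizes and numerical choices

The shipped test suite exercises: scanner-vs-oracle agreement on 1,000
random sequences of up to 300 residues; NJ recovery from 100 random
additive matrices of 4–8 taxa; a 1,000-replicate bootstrap checked against
an independently coded 10,000-replicate oracle on a 5-taxon alignment
(agreement within 3 support points); pI bisection against a 0.001-step pH
grid on 100 random peptides; and exhaustive-enumeration alignment scores
for pairs up to 6 residues. These sizes were chosen so the full suite runs
comfortably on a single CPU while keeping each statistical comparison
well-powered.

Tie-breaks are deterministic everywhere (alignment traceback prefers
match over gap-in-A over gap-in-B; NJ joins the lexicographically smallest
pair; nearest-reference ties take the smallest label). Degenerate inputs
are defined rather than undefined: an empty catalog summarizes to zeros,
a pairwise-deletion distance with no comparable columns is 1, an absent
calibrator or malformed pattern is an error naming the offender.

## Known limitations

- Detection is grammar-based by design: no profile HMM, no E-values, and
  no sensitivity to heptapeptide variants more than one substitution away
  (or with a mutated tryptophan, unless relaxed).
- The subgroup assignment is a surrogate for phylogenetic subgrouping and
  inherits the quality of its reference set.
- The leucine-zipper heuristic captures heptad periodicity only and is not
  a coiled-coil predictor; output is labelled `LZ-heuristic` accordingly.
- The progressive aligner targets domain-scale inputs; for serious MSA use
  a dedicated aligner and feed the result to `bootstrap_support()`.
- Published trees for the real grapevine/Arabidopsis/rice/poplar proteins
  are not reproducible from printed material and are out of scope; the
  phylogenetic machinery is validated on synthetic and simulated data.
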