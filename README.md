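# wrkykit

Rule-based annotation and expression analysis of the grapevine (*Vitis*
spp.) WRKY transcription-factor family.

WRKY proteins are plant transcription factors central to defense
signaling: they bind the W-box element `(C/T)TGAC(T/C)` through a
~60-residue domain defined by the near-invariant heptapeptide `WRKYGQK`
followed by a zinc finger, `C-X(s1)-C-X(s2)-H-X(s3)-H` (C2H2) or
`...-H-X(s3)-C` (C2HC). Domain count and finger type partition the family:
group I (two domains, N- and C-terminal), group II (one C2H2 domain,
subgroups IIa–IIe) and group III (one C2HC domain). `wrkykit` turns a
published genome survey of this family in grapevine into a reusable,
tested pipeline:

- **Domain scanning** — heptapeptide matching (configurable mismatch
  tolerance) paired with a zinc-finger spacing grammar, emitting
  catalog-style pattern strings such as `C-X7-C-X23-HTC`.
- **Classification** — group from domain count and terminal ligand;
  group II subgroup from a HARF-motif override, a spacer rule (C-X4 →
  IIc), and an optional nearest-reference layer.
- **Accessory motifs** — LXXLL coactivator, LXLXLX (EAR-like) repressor,
  HARF (`RTGHARFRR(A/G)P`), a leucine-zipper heptad heuristic, and W-box
  scanning on both DNA strands.
- **Physical properties** — length, average molecular weight, and
  isoelectric point by Henderson–Hasselbalch bisection.
- **Phylogenetics** — global affine-gap alignment, p-distances,
  neighbor joining with deterministic tie-breaks, column-resampling
  bootstrap (default 1,000 replicates), newick output.
- **Expression** — 2^(−ΔΔCt) relative quantification of replicate Ct
  tables and induced / repressed / unchanged calling with panel-level set
  algebra.
- **Synthetic data** — seeded generators for proteins with planted
  domains/motifs, mutated domain families, and Ct tables with programmed
  response designs; these power the package's end-to-end validation.

The package ships a machine-readable reproduction of the published
80-protein grapevine WRKY catalog (`inst/extdata/vitis_wrky_catalog.tsv`)
used for count-level validation.

## Worked example

```r
library(wrkykit)

## the packaged family catalog
summarize_catalog(load_catalog())
#> WRKY catalog: 80 proteins
#>   per group: I=18, IIa=7, IIb=8, IIc=22, IId=9, IIe=8, III=8
#>   length 127-798 aa, pI 4.70-9.84

## scan a synthetic protein carrying one planted group III domain
spec <- protein_spec(200, list(
  list(type = "domain", pattern = "C-X7-C-X23-HTC", pos = 50)), seed = 7)
prot <- make_protein(spec)
scan_domains(prot$seq, protein_id = "demo")[
  , c("protein_id", "start", "end", "hepta_seq", "pattern", "finger_class")]
#>   protein_id start end hepta_seq        pattern finger_class
#> 1       demo    50 100   WRKYGQK C-X7-C-X23-HTC         C2HC

classify_proteins(c(demo = prot$seq))[
  , c("protein_id", "group", "n_domains", "spacer1")]
#>   protein_id group n_domains spacer1
#> 1       demo   III         1       7
```

The scanner reports the planted domain at its exact coordinates (0-based
half-open, here residues 50–100), the canonical heptapeptide, and the
C2HC finger that places the protein in group III.

```r
## qRT-PCR panel: synthetic Ct table programmed to the published
## response categories, then called and summarized
design <- panel_design(wrky_expression_panel(), seed = 1)
calls  <- call_panel(make_panel_ct(design))
summarize_panel(calls[calls$treatment == "pathogen", ],
                calls[calls$treatment == "SA", ],
                unique(design$calls$gene))
#> panel of 28 genes
#>   treatment A: 23 induced, 2 repressed, 3 unchanged (25 altered)
#>   treatment B: 23 induced, 0 repressed, 5 unchanged (23 altered)
#>   induced under both: 19
```

Treatment A is the fungal-pathogen challenge (25 of 28 genes altered, 23
induced), treatment B salicylic acid (23 induced) — the category
arithmetic of the published survey, recovered from the generated Ct
values by the ΔΔCt pipeline.

## Package layout

- `R/` — implementation (catalog, domain_scan, classify, motif_scan,
  properties, phylo, expression, synthetic modules).
- `inst/extdata/vitis_wrky_catalog.tsv` — the packaged family catalog.
- `tests/testthat/` — unit, property and acceptance tests, including
  brute-force oracles for every scanner and the alignment/bootstrap
  machinery.
- `vignettes/wrky-survey-methods.Rmd` — the methods vignette: model,
  parameter defaults and rationale, synthetic-data design, numerical
  choices, limitations.
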