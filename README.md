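# immunotrace

Annotation of innate-immunity gene repertoires in arthropod proteomes.

Arthropod innate immunity runs on a handful of recognisable gene families
— peptidoglycan recognition proteins (PGRPs), beta-glucan recognition
proteins (GH16), thioester-containing proteins (TEPs), Toll-like
receptors (TLRs), Relish-type NF-κB factors, and Nimrod-superfamily
receptors. Deciding which predicted peptides of a new proteome belong to
these families, and what each copy can still *do*, takes more than a
similarity search: family calls need several independent evidence lines,
and function is decided by single residues and short motifs. This package
is for comparative immunologists and genome annotators who want that
procedure as a reproducible pipeline rather than a chain of web servers.

## The method

A protein is assigned to a family when it has at least one of three
independent evidence sources, and survives two filters:

* **RBH** — reciprocal best hit against a labelled reference species,
  from all-vs-all Smith–Waterman (BLOSUM62, gap open 11 / extend 1),
  with hits kept only at *e* < 10⁻⁶, identity > 20%, bit score > 80;
* **orthogroup** — co-clustering with a labelled reference query in the
  connected components of the reciprocal-hit graph;
* **profile** — PSSM domain hits and degenerate-motif matches (NIM
  26-mer `CXPXCXXXCXNGXCXXPXXCXCXXGY`, thioester `GCGEQ`, RHIM) to a
  family's diagnostic models;

filtered by the family's **architecture rule** (required/forbidden
domains, motifs, expected localization) and a **reciprocal-hit veto**
(a best reciprocal reference hit outside the assigned family rejects the
candidate).

Functional classification then reads the diagnostic residues through
alignments with annotated references: the PGRP zinc-binding triad
(C + H + H ⇒ amidase-active), the glucanase glutamate pair (E188/E193 on
the reference's numbering), the TEP thioester motif and its critical
cysteine (absent ⇒ MCR-like), TLR ectodomain cysteine clusters (one
juxtamembrane cluster ⇒ scc, two ⇒ mcc, otherwise atypical), and the
Relish RHD + C-terminal ankyrin layout. Copy numbers are tabulated per
species × family, and each family gets a midpoint-rooted, bootstrapped
neighbor-joining gene tree.

A built-in generator emits multi-species synthetic proteomes — gene
families evolved by birth–death duplication/loss and substitution along a
species tree, with implanted domains, motifs, TM helices, signal
peptides, functional-residue ablations, and a machine-readable truth
table — so the whole pipeline is verifiable without downloading genomes.

## Worked example

```r
library(immunotrace)

dir <- tempfile("demo_")
cfg <- default_generator_config(n_background = 50, seed = 42)
ds  <- run_simulate(cfg, dir)                     # 4 proteomes + truth
run <- run_annotate(pipeline_config_for_dataset(dir, seed = 42,
                                                out_dir = tempfile()))
run$copy_number
#>   species PGRP GH16 TEP TLR Relish Nimrod
#> 1   refsp    2    2   2   2      1      2
#> 2     sp1    3    2   2   2      1      4
#> 3     sp2    3    2   2   2      1      2
#> 4     sp3    3    2   2   2      1      2
```

The copy-number matrix is the headline result: at seed 42 the birth–death
process duplicated Nimrod twice on the sp1 branch (4 copies) and dropped
one PGRP on the reference branch (2 copies), and the pipeline recovered
exactly those counts. `tidy(run)` gives one row per accepted protein with
its evidence flags and functional calls:

```r
dplyr::select(tidy(run), protein_id, family, localization, catalytic)[5, ]
#>      protein_id family  localization catalytic
#> 5 refsp_PGRP_a2   PGRP intracellular       yes
```

— an intracellular PGRP that kept its full C/H/H triad, hence an active
amidase. Checking the whole run against the generator's truth:

```r
v <- verify_annotation(run$annotation, ds$truth)
v$overall
#>   precision recall
#> 1         1      1
v$functional
#>            key  n agreement
#> 1 localization 49         1
#> 2    catalytic 19         1
#> 3    tep_class  8         1
#> 4    tlr_class  8         1
#> 5         rhim 11         1
```

All 49 planted family members were found with no false positives, and
every localization, catalytic, thioester-class, cysteine-cluster-class
and RHIM call matched the planted truth. `autoplot(run)` draws the
copy-number heatmap; `run$trees$PGRP` is a midpoint-rooted `phylo` object
with bootstrap supports.

A thin command-line wrapper ships in `exec/`:

```sh
immunotrace simulate --out demo_ds --seed 42
immunotrace annotate --data demo_ds --out demo_run --seed 42
immunotrace verify   --annotation demo_run/annotation.tsv \
                     --truth demo_ds/truth.tsv
```

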