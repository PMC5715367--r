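# phenoplate

High-throughput, plate-based phenotyping of *Arabidopsis thaliana*
seedlings under abiotic stress, as an R package. It is written for
plant-phenomics groups running reverse-genetic screens: dozens of T-DNA
insertion lines sown on agar plates, stressed (150 mM NaCl, 750 µM
arsenate, −8 °C freezing, phosphate limitation), photographed in
visible light and — for salt and arsenic — chlorophyll fluorescence,
and scored *in silico* instead of by eye.

## What it computes

**Segmentation.** Each assay has its own foreground pixel rule on 8-bit
channels (e.g. salt VIS: saturation S > 49 with a mid-gray grid band
excluded; freezing: B < 127 and (R−B)/(R+B) > 0.20; phosphate roots:
local-mean thresholding with embossed-grid removal). Connected
components are filtered by area, normalised circularity 4πA/P² and
distance to the grid-cell centre, and reduced to one object — the
*digital plant* — per seedling (largest per cell; on vertical phosphate
plates, shoot and root objects are merged per grid column).

**Features.** Per plant: area, perimeter (Moore-traced outer contour),
circularity, compactness A/P, major/minor axis (second-moment
equivalent ellipse), eccentricity, and the modal gray intensity
(`hisgreypeak`); plus K-class hue profiles (K = 16, VIS and FLUO
joined, for salt/arsenic; K = 32 for freezing) and the yellowish
damage fraction (hue < 40; damaged iff > 0.5).

**Statistics.** Seedling states (alive/dead, germinated/seed) are
called by cutting an average-linkage tree on the Euclidean distances of
the joined colour profiles into two groups, labeling the greener group
alive. Each line is tested against wild-type Col-0 — Fisher's exact
test on the 2×2 state counts, or one-way ANOVA on the major-axis
root-length proxy for phosphate — and p-values are
Benjamini–Hochberg-adjusted per condition; a line has a phenotype iff
p_adj < 0.05. Genes are then triaged: evidence categories 1–6 from the
number of concordant alleles and affected conditions, and a stringent
filter keeping genes with ≥ 2 lines significant in one stress and
min p_adj < 0.01 there.

**Synthetic plates.** A ground-truth generator renders all four plate
types (36-seed square grids, 60-seedling round plates, 6-seed vertical
plates with embossed grids) with per-line effect parameters, so the
whole pipeline is testable end to end without any raw screen images.

## Worked example

The package ships the screen's published per-line summary (FDR-adjusted
p-values for 35 TE-derived loci under four stresses) and reproduces its
gene-level triage:

```r
library(phenoplate)
res <- ete_screen_results()              # tidy per-line table
sf  <- stringent_filter(res)             # >=2 lines in one stress, min p_adj < 0.01
sum(sf$pass)                             # 25
multi_stress_count(ete_screen_results("multi"))   # 12
summ <- summarize_genes(res)
head(summ[summ$pass, c("locus", "category", "n_sig_lines",
                       "qualifying_stresses", "min_p_adj")], 5)
```

```
     locus category n_sig_lines qualifying_stresses min_p_adj
 At1g06740        6           2                salt  1.34e-03
 At1g10240        6           2           phosphate  6.04e-03
 At1g15300        6           2                salt  1.34e-03
 At1g21260        6           2             arsenic  1.20e-07
 At1g52520        6           2           phosphate  8.31e-04
```

25 genes pass the stringent two-part filter, 12 of them with strong
(p_adj < 0.01) evidence in two or more stresses; every single-line gene
fails, as it must.

A full simulated screen runs through one call:

```r
out <- run_pipeline(list(
  assay = "salt", seed = 12, replicates = 3,
  lines = list(list(id = "Col-0"),
               list(id = "sensitive", survival_prob = 0.15, locus = "G1"),
               list(id = "null", locus = "G2"))))
out$results      # line_id, odds ratio, p_raw, p_adj, significant
```

which generates the plates, segments every seedling, calls states by
colour clustering, and flags `sensitive` (survival 15% vs 66%) while
leaving `null` unflagged. A thin command-line wrapper with
`simulate` / `segment` / `stats` / `multitrait` / `triage` / `run-all`
subcommands lives in `inst/scripts/phenoplate.R`.

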