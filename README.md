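# betascope

Document-oriented storage and track-less SVG visualization of DNA
methylation beta values from Illumina 450k-style arrays.

## The problem

Epigenome-wide association studies produce beta values — per-CpG methylation
fractions in [0, 1] — for hundreds of thousands of probes per sample, across
many projects, tissues and phenotypes. Comparing a finding in one project
against everything else measured at the same CpG requires (i) a store whose
index does not grow with the number of samples, (ii) schema-less sample
metadata so heterogeneous studies can coexist, and (iii) a viewer that
superimposes all samples in one coordinate frame instead of stacking them as
browser tracks, so small between-group differences are directly visible.

`betascope` is a desk-scale library + CLI implementing that workflow for
researchers who want to deposit, navigate, group and render 450k-style beta
values locally, without a database server.

## The model at its core

- **Beta documents.** For a project *p* and probe *j*, the store holds one
  document `(p, j) -> {s_i : beta_ij}` over the samples *s_i* of the
  project. Depositing *S* samples over *K* probes in *P* projects therefore
  creates exactly *P x K* documents — the collection scales with projects,
  never with samples. All betas satisfy 0 <= beta <= 1 (0 = unmethylated,
  1 = methylated); M-values are deliberately out of scope.
- **Schema-less metadata.** A sample is a set of key-value pairs; a key a
  sample does not have is truly absent (no nulls). Grouping stratifies by
  the value tuple of up to three keys within a project, or by the reserved
  keys `project` / `tissuetype` across projects; samples missing a grouping
  key are excluded from display. Spelling-repair utilities
  (`repair_metadata_key`, `repair_metadata_value`) fix `sxe` -> `sex` after
  the fact.
- **Annotation overlays.** A probe re-annotation table supplies CpG island
  density classes (high / intermediate, drawn as deep / light blue
  background), SNP flags (blue squares below the axis for a SNP in the probe
  body, red squares for a SNP at the interrogated CpG — both can make a
  probe report genotype instead of methylation), and a reliability flag.
- **Three render modes**, all sharing one linear transform
  (position -> x, beta -> y): `points` (one circle per measurement, tooltip
  per sample), `distribution` (per-probe, per-group mean + min-max whisker
  or box glyph), `trace` (per-group per-probe means joined by a polyline,
  optional centered moving average; deliberately jagged — never an imputed
  gradient between CpGs).

## Worked example

The bundled generator reproduces the classic X-chromosome-inactivation
validation: one blood project, 46 samples (22 females, 24 males), with an
XIST-like locus whose promoter islands are ~50% methylated in females and
high in males.

```r
library(betascope)

fx <- make_x_inactivation_fixture(seed = 20)
st <- open_store(backend = "memory")
load_fixture(st, fx)
st
#> <beta_store> backend=memory
#>   29 annotated probes, 1 projects, 46 samples, 29 beta documents

region <- resolve_locus(st, "XIST", flank = 500)
data <- query_region(st, region, "xci_blood")
data
#> <region_dataset> chrX:999900-1005300: 12 probes, 46 samples

groups <- group_samples(unname(data$samples),
                        group_spec("within_project", "sex"))
groups
#> <group_assignment> by (sex): 2 groups, 0 excluded
#>   female: 22 samples
#>   male: 24 samples
```

Mean beta over the island probes, recomputed per group:

```r
island <- data$probes$island_class != "none"
for (lab in names(groups$groups)) {
  ids <- groups$groups[[lab]]
  m <- mean(unlist(lapply(which(island), function(i)
    data$betas[[i]][names(data$betas[[i]]) %in% ids])))
  cat(sprintf("mean island beta, %s: %.3f\n", lab, m))
}
#> mean island beta, female: 0.494
#> mean island beta, male: 0.852
```

Females sit at ~0.5 (one X inactive, one active), males above 0.75 — the
expected XIST inversion. Render it:

```r
doc <- render_region(data, groups, plot_config(mode = "distribution"),
                     genes = fx$genes)
doc
#> <svg_document> 900x420 px, 73 top-level elements
write_svg(doc, "xist.svg")
```

## Command line

The same workflow via the installed `exec/betascope` script (or
`Rscript -e 'betascope::cli_main()' --args ...`):

```sh
betascope simulate --preset x_inactivation --seed 20 --out fixture/
betascope init --store db
betascope import-annotation --store db --file fixture/annotation.csv
betascope register-samples  --store db --file fixture/samples.jsonl
betascope import-betas      --store db --project xci_blood \
    --file fixture/xci_blood.betas.csv
betascope query  XIST --store db --projects xci_blood --flank 500
betascope render XIST --store db --projects xci_blood \
    --group-by sex --mode trace --out xist.svg
```

Exit codes: 0 success, 1 user error, 2 internal error. Data on stdout, logs
on stderr.

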