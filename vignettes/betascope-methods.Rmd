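---
title: "betascope: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{betascope: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betascope)
```

## Scope and model

`betascope` stores, groups and visualizes methylation beta values from
450k-style arrays. A beta value is the estimated methylated fraction at one
CpG, bounded in [0, 1]; it is the only measurement unit in the package.
M-values (the logit transform) are intentionally not supported: the package
is a visual-comparison tool and betas are the directly interpretable scale.
Likewise, upstream preprocessing (background subtraction, color correction,
probe-type normalization) is out of scope by design: the store assumes that
deposited values were uniformly and minimally processed, because aggregate
renormalization per project can manufacture or erase apparent cross-project
differences.

### The document model and its scaling assumption

The unit of storage is the *(project, probe)* document: a map from sample id
to beta, covering every sample of one project at one probe. Its purpose is
an index-size invariant: the number of documents equals the number of
(project, probe) pairs with at least one measurement and is independent of
how many samples a project accrues. The invariant is enforced at the API
(deposits merge into the single document; `store_document_count()` and
`store_dump()` expose it) and asserted in the test suite by depositing 1, 5
and 50 samples over the same probes.

The default backend is an embedded, file-backed store: columnar tables for
annotation and betas plus JSON-lines sample records under one directory,
loaded on `open_store()` and persisted by `store_flush()`. The document
remains the logical unit — `store_dump()` emits exactly one JSON line per
(project, probe) — while the columnar representation keeps a full-array
import (485,577 probes) to seconds in R. A server-backed document database
could be slotted in behind the same operation contract; replication and
sharding are deployment properties, not method content, and are not
modeled.

Coordinates are 1-based with inclusive interval ends everywhere (the
Illumina manifest convention). Betas are stored at full float precision:
disk writes round-trip through `%.17g`, so reopen-and-compare is exact.

### Metadata, absence, and repair

Sample metadata is schema-less key-value data. The central rule is that
*absence is real*: a key a sample does not have is not stored as `NULL` or a
placeholder, and retrieval reports it absent. Keys and values compare
exactly and case-sensitively (`"Female" != "female"`); normalization is
deliberately the researcher's job, supported by two repair utilities that
rename a key or rewrite a value across a project. Key repair is
all-or-nothing: if any sample carries both the old and the new key, the
rename would silently destroy one of the two values, so the operation
aborts before touching anything. A sample that carries only the new key is
not a conflict. Both repairs are idempotent.

Two key names are reserved and carry cross-project meaning: `project`
(always present; it is the record's project field) and `tissuetype`.
Within-project grouping stratifies by the exact value tuple of up to three
keys; cross-project grouping is restricted to the two reserved keys.
Samples missing any grouping key are excluded from display, never silently
pooled. Continuous covariates are not binned automatically — an "age"
grouping means the user supplies an `age_bin` key. Two distinct value
tuples can share a display label (numeric `1` vs string `"1"`); labels are
then disambiguated with a ` #` suffix rather than merging the groups.

One identity decision was genuinely open: beta maps are keyed by sample id,
but a query may span several projects. We require sample ids to be unique
across the set of projects queried or grouped together and raise an error
on collision, rather than inventing qualified ids that would leak into
labels and tooltips. Real-world accessions (GSM ids, lab codes) satisfy
this; colliding projects can be queried separately.

### Locus navigation

`resolve_locus()` accepts the three forms a user has in hand: a coordinate
string (`chr7:100,000-200,000`, commas tolerated), a probe id, or a gene
name (case-insensitive match against annotation gene symbols). A string
matching both a probe id and a gene resolves as a probe id. Gene resolution
spans min-to-max probe position plus the flank; if a symbol is annotated on
several chromosomes (paralog mis-annotation), the modal chromosome is used
deterministically instead of failing.

## The renderer

All display happens in a single coordinate frame: an affine map of genomic
position to x and beta to y (0 at the bottom axis, 1 at the top). Nothing
is ever rescaled per group or per dataset — this is the point of the
track-less design, since superimposition makes small shifts between groups
visible that separate tracks would hide. The test suite asserts this as a
property: the union of per-group renders reproduces the glyphs of the
combined render exactly.

Mode-specific choices where the original description left the summary open:

* **distribution** glyphs default to *mean + min-max whisker*; a
  median/IQR box glyph is available via
  `plot_config(distribution_glyph = "box")`. Glyphs of several groups at
  one probe fan out horizontally over a fixed width (`glyph_fan_px`,
  default 12 px) in group label order, so they never overprint.
* **trace** draws straight segments through per-probe group means. Probes
  with no data for a group are skipped, not interpolated — the line is a
  reading aid, and a smooth curve would imply knowledge of methylation
  between CpGs that the array does not have. `trace_window` (odd, default
  1 = off) applies a centered moving average whose edges shrink to the
  available window. A group with data at fewer than two probes degrades to
  a point marker.
* **annotation layers**: maximal runs of consecutive same-class island
  probes merge into one background rectangle (full plot height, default
  deep blue `#1f4e9c` for high-density, light blue `#a8c7e8` for
  intermediate; both configurable — figure captions in the literature
  sometimes show gray, the prose color wins here). Below the x-axis sit
  three marker rows: squares for SNP-in-probe (blue) and SNP-at-CpG (red),
  and ticks for probes flagged unreliable. The three flags are modeled
  independently because the source material is ambiguous about whether
  "unreliable" and "contains a SNP" coincide; keeping them separate loses
  nothing. A BED12-derived gene track (exon boxes, intron line) renders
  beneath the marker rows. Island rectangles get `island_pad_px` (3 px) of
  horizontal padding so single-probe islands remain visible.

Tooltips are static `<title>` children (sample id plus its metadata), so
the SVG needs no scripting. Output is SVG 1.1, well-formed XML with
explicit root dimensions, and byte-deterministic: coordinates are formatted
at fixed 2-decimal precision and nothing depends on time or RNG state. The
tests parse every rendered document with a strict XML parser and compare
glyph geometry against independent recomputation at 0.5 px.

## The synthetic-data generator

The generator is first-class, tested code; it emulates the statistical
shape of real 450k data sufficiently for storage, grouping and rendering
tests:

* **Background**: each probe draws a baseline from a two-component Gaussian
  mixture (means 0.1 / 0.9, sd 0.05, equal weights) — the familiar bimodal
  genome-wide beta landscape — and samples vary around their probe's
  baseline with additive noise (`noise_sd`, default 0.05, a typical
  technical-replicate scale). Draws are clipped to [0, 1]; at these sds the
  clipping bias is negligible, and clipping is simpler and cheaper than
  truncated resampling.
* **Planted effects** override probes of an effect gene with
  group-conditional Gaussians, which makes parameter recovery testable: the
  empirical group mean must land within 4·sd/√n of the planted mean.
* **The X-inactivation fixture** (`make_x_inactivation_fixture()`) encodes
  the canonical sex-chromosome validation: 46 blood samples (22 female, 24
  male) over three loci — an XIST-like gene (islands ~0.50 in females,
  0.85 in males, across one high-density and one intermediate-density
  promoter island), a MAOA-like inactivated gene (islands ~0.50 female /
  0.05 male), and an RPS4X-like escapee (islands low, flanks high in both
  sexes). Two escapee flank probes are flagged `snp_at_cpg` and planted
  with a spurious sex difference, reproducing the caveat that a CpG-site
  SNP masquerades as differential methylation.

What a green test does **not** establish: the generator has no Infinium
I/II chemistry differences, no batch or chip effects, no detection-failure
structure, and no realistic linkage between SNP flags and beta
distributions. It validates the machinery (storage semantics, grouping
algebra, render geometry), not biological inference.

Everything is deterministic given the seed, including the written files, so
fixtures never need to be shipped — `simulate` in the CLI regenerates them
bit-for-bit.

## Numerical and degenerate-input choices

* Beta range violations fail at deposit time, naming the probe and value;
  the range is re-checked when a store is loaded from disk.
* Missing-value tokens in CSV import: empty cell, `NA`, `NaN` — all become
  *absent* measurements, never 0. Detection-p masking in the GenomeStudio
  importer is opt-in (`detection_p = NULL` by default), as quality control
  is treated as an upstream decision.
* Probes deposited without annotation are skipped and counted, not errors:
  partial manifests are routine.
* Probes at identical positions sort by probe id; the region query's order
  is strictly deterministic.
* A single-position region maps to the horizontal midpoint of the plot box
  rather than dividing by zero.
* Quantiles for the box glyph use R's default type-7 definition.
* An empty region renders a valid labeled SVG, not an error.

## Limitations

* Single-writer, embedded store; no concurrency, no authentication, no web
  interface.
* No statistical testing between groups — the display is deliberately
  descriptive.
* Sequencing-based assays (WGBS/RRBS) and ChIP data are out of scope.
* PNG rasterization is out of scope; the SVG is the product.
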