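Package: betascope
Title: Document-Oriented Storage and Track-Less Visualization of DNA
    Methylation Beta Values
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale re-implementation of a database-and-browser workflow
    for Illumina 450k methylation array data. Beta values are held in a
    document-oriented store with one document per (project, probe), so the
    collection scales with projects rather than samples. Schema-less sample
    metadata is stored as key-value records with grouping (up to three keys
    within a project, or the reserved 'project'/'tissuetype' keys across
    projects) and spelling-repair utilities. A probe re-annotation table
    supplies CpG island density classes and SNP flags, which the track-less
    SVG renderer overlays beneath superimposed per-sample data in three modes:
    raw points, per-group distributions, and per-group smoothed traces.
    Includes importers for CSV beta tables, GenomeStudio-style final reports,
    JSON-lines sample metadata and BED12 gene models, a seeded synthetic-data
    generator (including an X-chromosome-inactivation fixture), and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table (>= 1.14.0),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2,
    withr
Config/testthat/edition: 3
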