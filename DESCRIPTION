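Package: rosecomb
Title: Simulation and Detection of the Chicken Rose-Comb Structural Rearrangement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the structural rearrangement behind the chicken
    Rose-comb locus on chromosome 7: exact algebra of rearranged haplotypes
    (inversion allele R1 and the unequal-crossover duplication allele R2),
    junction extraction and breakpoint microhomology scoring, simulation of
    large-insert mate-pair sequencing from allele pools, window-based
    discordant-pair structural variant calling with breakpoint refinement,
    in-silico junction PCR genotyping of the six diploid genotypes, breakpoint
    gene annotation (disrupted, relocated and fusion-candidate transcripts),
    sliding-window heterozygosity scans, two-point linkage LOD under
    recombination suppression, and the sperm-competition breeding equilibrium
    that maintains single-combed chicks in Rose-comb flocks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
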