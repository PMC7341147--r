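Package: ldfusion
Title: Linkage-Disequilibrium Based Inference of Chromosome Fusions and
    Marker-Map Rearrangement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers Robertsonian (centric) chromosome fusions from SNP
    genotypes referenced on a split "ancestral acrocentric" assembly, using
    counts of inter-chromosomal marker pairs in high linkage disequilibrium
    (r2), and rewrites the marker map onto the fused submetacentric
    coordinate system through an exact, invertible rearrangement plan.
    Includes a pairwise r2 engine (EM haplotype-frequency and composite
    estimators), genotype quality control (call rate, minor allele
    frequency, exact Hardy-Weinberg test), Hill-Weir r2 decay fitting,
    windowed LD and haplotype-diversity scans with centromere profiling and
    a fusion-chronology heuristic, misplaced-marker and translocated-segment
    flagging for assembly comparison, an imputation-accuracy evaluation
    harness (marker-masking scenarios, fourfold cross-validation, allelic
    correlation and proportion of correctly imputed alleles), and a seeded
    forward Wright-Fisher simulator of fused-chromosome genotype panels with
    centromeric recombination suppression that drives the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
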