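Package: tagphase
Title: Reconstruction of Haploid DNA Molecules from Tagmentation
    Fragment Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs individual haploid DNA molecules from mapped
    Tn5 tagmentation fragments. Adjacent fragments cut from one double-
    stranded molecule share an 8-, 9- or 10-base duplicated junction;
    chaining fragments through these junctions yields contiguous islands,
    and islands plus loose fragments are packed into discrete molecules
    under exclusivity and greediness rules, giving integer copy-number
    tracks per covered region. Includes paired-read merging with
    reference gap fill, PCR deduplication by unique fragment index,
    archipelago clustering with coverage and GC statistics, repair of
    3-base primer remnants (CAG/CTG) that mask junctions, detection of
    defective-transpososome artifacts via shared fragment ends, and a
    tagmentation simulator that emits libraries with full molecule-level
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
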