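Package: nuctile
Title: Tiled Nucleosome Libraries and Cas9 Accessibility Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs tiled nucleosome sequence libraries in which a
    CRISPR/Cas9 target-plus-PAM motif is substituted at every base-pair
    position of a Widom 601 backbone, indexed by a dyad-centred
    superhelical-location (SHL) coordinate model. Processes paired-end
    amplicon reads (quality trimming, overlap merging, primer removal,
    length filtering, identity-based library assignment) into per-member
    uncleaved read counts, computes the control-normalised log2
    protection-from-Cas9 statistic with Z-score normalisation against
    nonspecific background members, derives per-base-pair MNase protection
    tracks from fragment intervals, simulates digestion read sets from a
    parametric protection model for end-to-end validation and parameter
    recovery, and superimposes nuclease structures onto nucleosomes to
    count van der Waals clashes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
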