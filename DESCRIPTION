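Package: homsite
Title: Homology Inference of Protein-Protein Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Annotates protein-protein binding sites and interaction
    partners on a query protein structure by transferring interfaces
    from homologous structural complexes. Inter-domain contacts are
    detected geometrically (heavy atoms within 4 Angstrom, at least
    five contacting residues), neighbour binding sites are projected
    onto the query through composed pairwise alignments, scored with a
    BLOSUM bit-score similarity, clustered by complete linkage with a
    pseudo-free-energy cutoff, classified as conserved or singleton by
    sequence redundancy, and ranked by a weighted combination of
    Z-scores for conservation, contact number, PSSM match to the query
    and alignment identity. Includes a synthetic fixture generator
    with planted binding modes and crystal-packing-like decoys for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    mclust,
    optparse
Config/testthat/edition: 3
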