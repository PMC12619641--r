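Package: ligsieve
Title: Identification and Extraction of Ligands of Pharmaceutical
    Interest from PDBx/mmCIF Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Enumerates, curates and extracts ligands of pharmaceutical
    interest from macromolecular structures in PDBx/mmCIF format,
    including atypical ligands such as chain-encoded peptides, molecules
    split across ATOM and HETATM records, free oligosaccharides and
    covalent binders. Candidate ligands are reassembled from covalent
    connectivity graphs, gated on binding-pocket proximity to the query
    protein, and selected either by per-structure deduplication (filter
    mode) or by rigid-body superposition and centroid clustering across
    structures (cluster mode). Includes a precision/recall evaluator for
    benchmarking ligand-extraction tools and a deterministic synthetic
    structure generator for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    bio3d,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
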