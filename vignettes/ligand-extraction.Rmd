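---
title: "Identifying ligands of pharmaceutical interest in PDBx/mmCIF structures"
author: "ligsieve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying ligands of pharmaceutical interest in PDBx/mmCIF structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligsieve)
```

## The problem

Macromolecular structures deposit their ligands in wildly inconsistent
ways. A drug-like small molecule usually sits in HETATM records under a
short component code — but peptide ligands may be stored as full polymer
chains (in ATOM records, HETATM records, or both, intercalated), a single
molecule may be split across several "residues" joined only by covalent
connection records, oligosaccharides may be genuine ligands or mere
glycosylation decorations, and solvents and crystallization additives are
annotated exactly like inhibitors. Naive extraction — "take everything in
HETATM" — therefore yields fragments, additives and glycans, and misses
chain-encoded ligands entirely.

`ligsieve` implements a curation workflow that starts from a list of
UniProt accessions, maps them to candidate structures through a
SIFTS-style chain table, and then enumerates, filters and selects ligands
of pharmaceutical interest, with every decision written to an event log.

## The procedure

Per query and per structure, four stages run in order:

1. **Mapping.** Chains are associated to queries through the SIFTS table;
   secondary (outdated) accessions are remediated to their primary forms
   on both sides. Structures with no reported resolution, or with an
   effective resolution (the *worst* of the reported values) above the
   user's cutoff, are excluded with a logged reason.

2. **Enumeration.** A residue-level covalent connectivity graph is built:
   consecutive ATOM residues of a chain are implicitly bonded, HETATM
   residues are connected only by explicit `covale` records from
   `_struct_conn`. Protein residues (standard amino acids of
   UniProt-mapped polymer chains) and waters are removed, and every
   remaining connected component containing a HETATM residue becomes one
   candidate — this is what reassembles split molecules and intercalated
   cyclic peptides into single ligands. Polymer chains are triaged by a
   conservative peptide rule (below); branched entities are checked for
   glycosylation. Candidates with fewer than 3 heavy atoms, or component
   codes instantiated more than 10 times in one structure, are removed;
   codes present in more than 250 PDB entries are flagged as probable
   additives unless on a 15-entry keep list of legitimate common ligands
   (ATP and kin).

3. **Processing.** Single-residue candidates on the exclusion list
   (solvents, additives, salts) are removed — multi-residue reassembled
   ligands never are, since a listed code can be a genuine fragment of a
   larger molecule. Structures whose chain references never remediate to
   the query are dropped. Each surviving candidate is gated on proximity:
   all polymer residues with any heavy atom within 6 Å (inclusive) of any
   ligand heavy atom form its pocket, and candidates with no pocket
   residue on a query chain are discarded — the ligand is present but
   does not bind the protein of interest.

4. **Selection.** Fragments subsumed by larger candidates, or bonded to
   non-protein residues outside themselves, are removed. In *filter*
   mode, equivalent copies (same component code, or same entity for chain
   ligands) are deduplicated to the copy with the most pocket residues,
   ties broken lexicographically. In *cluster* mode all copies are kept:
   structures are superposed onto the first structure in name order
   (Kabsch least squares on CA atoms paired by chain and residue number,
   restricted to chains in the 6 Å vicinity of a ligand), structures
   whose CA RMSD exceeds 3.5 Å are dropped with a warning, ligand
   heavy-atom centroids are computed in the common frame, and
   complete-linkage agglomerative clustering cut at 10 Å groups them into
   candidate binding sites.

## The peptide rule

Whether a polymer chain is a peptide ligand or a protein is the genuinely
hard decision. The rule implemented is deliberately conservative:

* a chain with **no UniProt reference** (self-referenced) is a peptide
  ligand — depositors self-reference synthesized peptides;
* a chain whose one-letter sequence **exactly matches a reference
  dictionary (BIRD) entry** is confirmed as a ligand;
* a UniProt-mapped chain is reclassified as a peptide only when it is
  annotated as synthesized (`_entity.src_method = "syn"`), its resolved
  residues cover at least α = 0.8 of its theoretical sequence, and that
  theoretical sequence is at most β = 0.5 of the full-length UniProt
  sequence. A short construct that was deliberately made, almost fully
  resolved, and much shorter than the parent protein is a peptide; a
  small natural protein whose deposited sequence *is* its full UniProt
  sequence is not.

α and β quantify the qualitative notions "not considerably shorter" and
"much shorter"; both are configurable (`ligsieve_config`). The full-length
comparison needs a UniProt length table (`uniprot_lengths`), an optional
input; without it the third branch cannot fire and mapped chains stay
protein, which only errs on the conservative side. Hirudin-like cases —
a peptide fragment deposited with the parent protein's accession and a
natural source annotation — are indistinguishable from small proteins by
annotation alone and are intentionally left as proteins.

Oligosaccharides attached by a `covale` record to ASN/SER/THR of a mapped
chain are glycosylation, not ligands; free oligosaccharide chains
(heparin-like) are ligands; dictionary-matched branches attached to the
protein are kept as candidates but flagged `covalent`, so downstream users
can separate covalent binders explicitly.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `max_resolution` | user-set (2.5 in examples) | Å | resolution gate at mapping |
| `pocket_cutoff` | 6.0 | Å | pocket residue collection, boundary-inclusive |
| `frequent_threshold` | 250 | PDB entries | frequent-ligand flag |
| `min_heavy_atoms` | 3 | atoms | minimum candidate size |
| `max_copies` | 10 | copies | per-structure copy-count exclusion |
| `rmsd_gate` | 3.5 | Å | superposition quality gate (cluster mode) |
| `cluster_threshold` | 10.0 | Å | centroid clustering cut |
| `alpha`, `beta` | 0.8, 0.5 | ratio | peptide rule |

## Numerical and design choices

* **Distances** are minimum heavy-atom–heavy-atom Euclidean distances;
  hydrogens are retained in the model but ignored by every distance and
  size computation. The 6 Å boundary is inclusive. The vectorized
  implementation is tested for exact equality against a brute-force
  all-pairs oracle.
* **Linkage.** The 10 Å clustering guarantee — no two members of one
  cluster further apart than the threshold — is linkage-dependent; only
  complete linkage makes it literally true, so complete linkage is the
  default (configurable in `cluster_centroids`).
* **Superposition** uses the SVD (Kabsch) solution with the determinant
  correction; tests require agreement with an independent
  quaternion-eigenvalue oracle below 1e-8 Å RMSD. CA pairing is by
  (chain, residue number) identity; a sequence-alignment fallback is out
  of scope. Structures failing the RMSD gate are dropped entirely (with a
  log warning) rather than reported unclustered, so every reported ligand
  has coordinates in the common reference frame.
* **Alternate locations** resolve to the maximum-occupancy atom, ties to
  the lexicographically smallest indicator; the operation is idempotent.
* **Multiple models**: model 1 only (X-ray focus). **Multiple resolution
  values**: the worst is the effective resolution.
* **Identifiers**: auth chain/residue numbering everywhere in user-facing
  output; label identifiers are kept only for entity bookkeeping.
  Multi-residue reassembled HETATM ligands are labelled by their joined
  component codes (e.g. `PHQ-DGL`); polymer and branched chain ligands by
  `chain-X`.
* **Undefined metrics** in the evaluator are explicit `NA`s, never 0, and
  are excluded from means; zero detected + zero true is a perfect match
  (precision = recall = 1). Standard deviations use the sample (n − 1)
  convention.

## What the synthetic generator emulates — and what it does not

The package ships a deterministic generator (`generate_all_scenarios`)
producing twelve annotation scenarios: a plain HETATM ligand, an apo
structure, a covale-linked fragment pair, an ATOM/HETATM-intercalated
cyclic peptide, an unmapped peptide chain plus ATP, a protein-covalent
ligand, a glycosylation-only structure, a free oligosaccharide, an
additive next to a true ligand, a three-copy ligand, a small full-length
natural protein chain, and a five-structure two-site set (16 ligands, 30 Å
apart, 1 Å jitter, random rigid motions) for cluster mode. Protein chains
are ideal-geometry CA-trace helices: the connectivity, classification and
proximity logic under test is purely topological and metric, so chemical
realism (side chains, bond geometry, B-factors) is unnecessary and
deliberately omitted. Accessions use the reserved `P0TEST…` pattern, with
a `Q0OLD1 → P0TEST1` alias exercising remediation.

Passing the scenario suite therefore shows that the annotation logic is
correct on structurally valid inputs; it does not show robustness to the
long tail of real-world deposition quirks (nonconforming categories,
inconsistent numbering, microheterogeneity) or to annotation scenarios
outside the twelve modelled ones — in particular, peptide ligands
deposited with full natural-protein annotation remain undetectable by
design. Problem sizes (30–40-residue chains, ≤ 16 ligands per set) were
chosen so the whole suite runs in seconds while still exercising every
code path.

## Known limitations

* No bond-order or chemistry perception, no protonation, no interaction
  typing — proximity only.
* No mmCIF writing, no NMR ensembles, no assembly/symmetry expansion.
* Obsolete or superseded PDB ids are treated as absent from the SIFTS
  table; no live database access anywhere in the package.
* Covalent ligands are extracted with their covalent structure as
  deposited; restoring the pre-reaction form is the user's task, guided
  by the `COVALENT_LINK`/`COVALENT_LIGAND` log events.
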