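# Independent oracles and small in-code fixtures shared across tests.

# Brute-force union-find over residue keys; the oracle for connected
# components, independent of igraph.
uf_components <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (nrow(edges) > 0L) {
    for (i in seq_len(nrow(edges))) {
      ra <- find(edges$a[i])
      rb <- find(edges$b[i])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(nodes, find, "")
  split(nodes, roots)
}

# Horn's quaternion method for minimal RMSD after optimal rotation; the
# oracle for the SVD-based superposition.
quaternion_rmsd <- function(mobile, fixed) {
  n <- nrow(mobile)
  m0 <- sweep(mobile, 2L, colMeans(mobile))
  f0 <- sweep(fixed, 2L, colMeans(fixed))
  M <- t(m0) %*% f0
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  g <- sum(m0^2) + sum(f0^2)
  sqrt(max(0, (g - 2 * lam) / n))
}

# Brute-force all-pairs residue proximity: residue keys of `env_keys` whose
# minimum heavy-atom distance to any ligand heavy atom is <= cutoff.
brute_force_pocket <- function(structure, lig_keys, cutoff) {
  a <- structure$atoms
  akey <- paste(a$auth_chain, a$auth_seq,
                ifelse(is.na(a$ins_code), "", a$ins_code), sep = "|")
  heavy <- a$element != "H"
  lig <- which(heavy & akey %in% lig_keys)
  out <- character(0)
  for (k in setdiff(unique(akey), lig_keys)) {
    rows <- which(heavy & akey == k)
    found <- FALSE
    for (i in rows) {
      for (j in lig) {
        d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                    (a$z[i] - a$z[j])^2)
        if (d <= cutoff) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) out <- c(out, k)
  }
  out
}

# Write a minimal mmCIF file from an atom spec for hand-built structures.
# atoms: data frame record, name, element, comp, chain, seq, entity, x, y,
# z, occ (opt), alt (opt). entities: data frame id, type, src.
write_test_cif <- function(path, pdb_id, atoms, entities,
                           resolution = 1.8, conn = NULL, refs = NULL,
                           entity_poly = NULL) {
  q <- function(x) ifelse(is.na(x), ".", as.character(x))
  lines <- c(paste0("data_", toupper(pdb_id)),
             paste0("_entry.id ", toupper(pdb_id)))
  if (length(resolution) == 1L) {
    lines <- c(lines, paste0("_refine.ls_d_res_high ", resolution))
  } else if (length(resolution) > 1L) {
    lines <- c(lines, "loop_", "_refine.ls_d_res_high",
               as.character(resolution))
  }
  lines <- c(lines, "loop_", "_entity.id", "_entity.type",
             "_entity.src_method",
             paste(entities$id, entities$type, entities$src))
  if (!is.null(entity_poly)) {
    lines <- c(lines, "loop_", "_entity_poly.entity_id",
               "_entity_poly.pdbx_seq_one_letter_code_can",
               "_entity_poly.pdbx_strand_id",
               paste(entity_poly$entity, entity_poly$seq,
                     entity_poly$chain))
  }
  if (!is.null(refs)) {
    lines <- c(lines, "loop_", "_struct_ref.id", "_struct_ref.db_name",
               "_struct_ref.pdbx_db_accession", "_struct_ref.entity_id",
               paste(seq_len(nrow(refs)), refs$db, refs$acc, refs$entity),
               "loop_", "_struct_ref_seq.ref_id",
               "_struct_ref_seq.pdbx_strand_id",
               "_struct_ref_seq.pdbx_db_accession",
               paste(seq_len(nrow(refs)), refs$chain, refs$acc))
  }
  if (!is.null(conn)) {
    lines <- c(lines, "loop_", "_struct_conn.conn_type_id",
               "_struct_conn.ptnr1_auth_asym_id",
               "_struct_conn.ptnr1_auth_seq_id",
               "_struct_conn.ptnr1_label_comp_id",
               "_struct_conn.ptnr1_label_atom_id",
               "_struct_conn.ptnr2_auth_asym_id",
               "_struct_conn.ptnr2_auth_seq_id",
               "_struct_conn.ptnr2_label_comp_id",
               "_struct_conn.ptnr2_label_atom_id",
               paste(conn$type, conn$chain1, conn$seq1, conn$comp1,
                     conn$atom1, conn$chain2, conn$seq2, conn$comp2,
                     conn$atom2))
  }
  occ <- if ("occ" %in% names(atoms)) atoms$occ else rep(1, nrow(atoms))
  alt <- if ("alt" %in% names(atoms)) q(atoms$alt) else
    rep(".", nrow(atoms))
  lines <- c(lines, "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_alt_id", "label_comp_id", "label_asym_id",
                      "label_entity_id", "pdbx_PDB_ins_code", "Cartn_x",
                      "Cartn_y", "Cartn_z", "occupancy", "auth_seq_id",
                      "auth_comp_id", "auth_asym_id",
                      "pdbx_PDB_model_num")),
             paste(atoms$record, seq_len(nrow(atoms)), atoms$element,
                   atoms$name, alt, atoms$comp, atoms$chain, atoms$entity,
                   "?", atoms$x, atoms$y, atoms$z, occ, atoms$seq,
                   atoms$comp, atoms$chain, 1))
  writeLines(lines, path)
  path
}

# Hand-built ligand candidate for filter/selection unit tests.
make_cand <- function(code, n_res = 1L, heavy = 10L,
                      kind = "small_molecule", chain = "A",
                      seq0 = 100L) {
  resd <- data.frame(
    res_key = paste0(chain, "|", seq0 + seq_len(n_res) - 1L, "|"),
    chain = chain, auth_seq = seq0 + seq_len(n_res) - 1L,
    ins_code = NA_character_, comp_id = code,
    record_kind = "HETATM", stringsAsFactors = FALSE)
  list(ligand_uid = paste(code, chain, seq0, sep = "_"),
       label = code, kind = kind, residues = resd,
       heavy_atom_count = heavy, covalent_to_protein = FALSE,
       prd_id = NA_character_, flags = character(0), chain = chain,
       entity_id = "9")
}

# Empty reference-table set for unit tests that do not need tables.
empty_refs <- function(...) {
  refs <- list(
    sifts = data.frame(pdb_id = character(0), chain = character(0),
                       uniprot = character(0), stringsAsFactors = FALSE),
    aliases = character(0),
    bird = data.frame(prd_id = character(0), sequence = character(0),
                      stringsAsFactors = FALSE),
    counts = integer(0), keep = character(0), exclusion = character(0),
    uniprot_lengths = integer(0))
  over <- list(...)
  for (nm in names(over)) refs[[nm]] <- over[[nm]]
  refs
}

# Generate the full scenario bed once per test session.
fixture_bed <- local({
  bed <- NULL
  function() {
    if (is.null(bed)) {
      dir <- file.path(tempdir(), "ligsieve-fixture-bed")
      bed <<- generate_all_scenarios(dir, seed = 42L)
    }
    bed
  }
})

# Run the pipeline over the scenario bed for one query and mode.
run_bed_pipeline <- function(bed, query, mode, out_dir = tempfile()) {
  t <- bed$tables
  cfg <- ligsieve_config(
    queries = query, cif_dir = bed$cif_dir, out_dir = out_dir,
    max_resolution = 2.5, mode = mode, sifts = t$sifts,
    aliases = t$aliases, bird = t$bird, counts = t$counts, keep = t$keep,
    exclusion = t$exclusion, uniprot_lengths = t$uniprot_lengths)
  run_pipeline(cfg)
}
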