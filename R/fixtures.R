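# Synthetic structure generator: small, valid PDBx/mmCIF files and matching
# reference tables covering every annotation scenario the pipeline handles,
# so the full workflow is testable offline. Protein chains are ideal-geometry
# CA-trace helices; chemistry realism is unnecessary for the proximity and
# connectivity logic under test.

FX_QUERY1 <- "P0TEST1"   # main query accession used by scenarios S1-S11
FX_QUERY2 <- "P0TEST2"   # small natural protein in S11
FX_QUERY3 <- "P0TEST3"   # cluster-set query (S12)
FX_ALIAS1 <- "Q0OLD1"    # secondary accession remediating to FX_QUERY1

# CA coordinates of an ideal alpha-helix (rise 1.5 A, radius 2.3 A,
# 100 degrees per residue), translated by `origin`.
.fx_helix <- function(n, origin = c(0, 0, 0)) {
  i <- seq_len(n) - 1L
  th <- i * 100 * pi / 180
  cbind(2.3 * cos(th) + origin[1],
        2.3 * sin(th) + origin[2],
        1.5 * i + origin[3])
}

# Deterministic near-spherical atom layout around a center (golden spiral).
.fx_blob <- function(n, center, radius = 0.9) {
  i <- seq_len(n)
  phi <- acos(1 - 2 * (i - 0.5) / n)
  th <- pi * (1 + sqrt(5)) * i
  cbind(center[1] + radius * sin(phi) * cos(th),
        center[2] + radius * sin(phi) * sin(th),
        center[3] + radius * cos(phi))
}

.fx_new <- function(pdb_id, resolution = 1.8) {
  env <- new.env(parent = emptyenv())
  env$pdb_id <- pdb_id
  env$resolution <- resolution
  env$atoms <- list()
  env$entities <- list()
  env$entity_poly <- list()
  env$struct_ref <- list()
  env$struct_ref_seq <- list()
  env$struct_conn <- list()
  env$branch <- list()
  env
}

.fx_add_entity <- function(fx, id, type, src = "man", desc = "synthetic") {
  fx$entities[[length(fx$entities) + 1L]] <-
    list(id = id, type = type, src = src, desc = desc)
}

.fx_add_atom <- function(fx, record, name, element, comp, chain, seq,
                         entity, xyz, occ = 1, alt = NA) {
  fx$atoms[[length(fx$atoms) + 1L]] <- list(
    record = record, name = name, element = element, comp = comp,
    chain = chain, seq = seq, entity = entity,
    x = xyz[1], y = xyz[2], z = xyz[3], occ = occ, alt = alt)
}

# Protein (or peptide) chain as a CA trace. `accession = NULL` gives a
# self-referenced chain (database reference is the entry itself).
.fx_add_chain <- function(fx, chain, n, entity, origin = c(0, 0, 0),
                          accession = NULL, src = "man",
                          comps = NULL, records = NULL,
                          theoretical = NULL, start_seq = 1L,
                          coords = NULL) {
  if (is.null(comps)) comps <- rep("ALA", n)
  if (is.null(records)) records <- rep("ATOM", n)
  if (is.null(coords)) coords <- .fx_helix(n, origin)
  one <- AA_321[comps]
  one[is.na(one)] <- "X"
  resolved <- paste(one, collapse = "")
  if (is.null(theoretical)) theoretical <- resolved
  .fx_add_entity(fx, entity, "polymer", src,
                 if (is.null(accession)) "synthetic peptide"
                 else "query protein")
  fx$entity_poly[[length(fx$entity_poly) + 1L]] <-
    list(entity = entity, seq = theoretical, chain = chain)
  ref_id <- as.character(length(fx$struct_ref) + 1L)
  if (is.null(accession)) {
    fx$struct_ref[[length(fx$struct_ref) + 1L]] <-
      list(id = ref_id, db = "PDB", acc = toupper(fx$pdb_id),
           entity = entity)
    fx$struct_ref_seq[[length(fx$struct_ref_seq) + 1L]] <-
      list(ref = ref_id, chain = chain, acc = toupper(fx$pdb_id),
           beg = start_seq, end = start_seq + n - 1L)
  } else {
    fx$struct_ref[[length(fx$struct_ref) + 1L]] <-
      list(id = ref_id, db = "UNP", acc = accession, entity = entity)
    fx$struct_ref_seq[[length(fx$struct_ref_seq) + 1L]] <-
      list(ref = ref_id, chain = chain, acc = accession,
           beg = 1L, end = n)
  }
  for (i in seq_len(n)) {
    .fx_add_atom(fx, records[i], "CA", "C", comps[i], chain,
                 start_seq + i - 1L, entity, coords[i, ])
  }
  invisible(coords)
}

.fx_add_ligand <- function(fx, code, chain, seq, entity, center,
                           n_atoms = 8L, record = "HETATM",
                           entity_type = "non-polymer",
                           add_entity = TRUE) {
  if (add_entity) .fx_add_entity(fx, entity, entity_type, "syn", code)
  xyz <- .fx_blob(n_atoms, center)
  for (i in seq_len(n_atoms)) {
    .fx_add_atom(fx, record, paste0("C", i), "C", code, chain, seq,
                 entity, xyz[i, ])
  }
  invisible(xyz)
}

.fx_add_covale <- function(fx, chain1, seq1, comp1, atom1,
                           chain2, seq2, comp2, atom2, type = "covale") {
  fx$struct_conn[[length(fx$struct_conn) + 1L]] <- list(
    type = type, chain1 = chain1, seq1 = seq1, comp1 = comp1, atom1 = atom1,
    chain2 = chain2, seq2 = seq2, comp2 = comp2, atom2 = atom2)
}

.fx_add_branch <- function(fx, entity, chain, comps, centers,
                           start_seq = 1L) {
  .fx_add_entity(fx, entity, "branched", "man", "oligosaccharide")
  for (i in seq_along(comps)) {
    fx$branch[[length(fx$branch) + 1L]] <- list(
      entity = entity, comp = comps[i], num = i, chain = chain,
      seq = start_seq + i - 1L)
    .fx_add_ligand(fx, comps[i], chain, start_seq + i - 1L, entity,
                   centers[i, ], n_atoms = 6L, add_entity = FALSE)
  }
  for (i in seq_len(length(comps) - 1L)) {
    .fx_add_covale(fx, chain, start_seq + i - 1L, comps[i], "C1",
                   chain, start_seq + i, comps[i + 1L], "O4")
  }
}

.fx_q <- function(x) {
  x <- as.character(x)
  ifelse(is.na(x), ".", ifelse(grepl("[ '\"]", x) | nchar(x) == 0L,
                               paste0('"', x, '"'), x))
}

.fx_loop <- function(cat, items, rows) {
  if (length(rows) == 0L) return(character(0))
  mat <- vapply(rows, function(r) .fx_q(unlist(r, use.names = FALSE)),
                character(length(items)))
  if (length(items) == 1L) mat <- matrix(mat, nrow = 1L)
  c("loop_", paste0("_", cat, ".", items),
    apply(mat, 2L, paste, collapse = " "), "#")
}

# Serialize a fixture to PDBx/mmCIF.
.fx_write <- function(fx, path) {
  lines <- c(
    paste0("data_", toupper(fx$pdb_id)),
    paste0("_entry.id ", toupper(fx$pdb_id)),
    paste0("_refine.ls_d_res_high ",
           paste(format(fx$resolution, nsmall = 2), collapse = " ")),
    "#"
  )
  if (length(fx$resolution) > 1L) {
    # multiple resolution values: emit as a loop instead
    lines <- c(
      paste0("data_", toupper(fx$pdb_id)),
      paste0("_entry.id ", toupper(fx$pdb_id)),
      "loop_", "_refine.ls_d_res_high",
      format(fx$resolution, nsmall = 2), "#")
  }
  lines <- c(lines,
    .fx_loop("entity", c("id", "type", "src_method", "pdbx_description"),
             fx$entities),
    .fx_loop("entity_poly",
             c("entity_id", "pdbx_seq_one_letter_code_can",
               "pdbx_strand_id"),
             fx$entity_poly),
    .fx_loop("struct_ref", c("id", "db_name", "pdbx_db_accession",
                             "entity_id"),
             fx$struct_ref),
    .fx_loop("struct_ref_seq",
             c("ref_id", "pdbx_strand_id", "pdbx_db_accession",
               "db_align_beg", "db_align_end"),
             fx$struct_ref_seq),
    .fx_loop("struct_conn",
             c("conn_type_id", "ptnr1_auth_asym_id", "ptnr1_auth_seq_id",
               "ptnr1_label_comp_id", "ptnr1_label_atom_id",
               "ptnr2_auth_asym_id", "ptnr2_auth_seq_id",
               "ptnr2_label_comp_id", "ptnr2_label_atom_id"),
             fx$struct_conn))
  if (length(fx$branch) > 0L) {
    ents <- unique(vapply(fx$branch, `[[`, "", "entity"))
    lines <- c(lines,
      .fx_loop("pdbx_entity_branch", c("entity_id", "type"),
               lapply(ents, function(e) list(e, "oligosaccharide"))),
      .fx_loop("pdbx_branch_scheme",
               c("entity_id", "mon_id", "num", "pdb_asym_id",
                 "pdb_seq_num"),
               fx$branch))
  }
  atom_rows <- lapply(seq_along(fx$atoms), function(i) {
    a <- fx$atoms[[i]]
    list(a$record, i, a$element, a$name,
         if (is.na(a$alt)) "." else a$alt,
         a$comp, a$chain, a$entity, "?",
         sprintf("%.3f", a$x), sprintf("%.3f", a$y), sprintf("%.3f", a$z),
         sprintf("%.2f", a$occ), a$seq, a$comp, a$chain, 1)
  })
  lines <- c(lines,
    .fx_loop("atom_site",
             c("group_PDB", "id", "type_symbol", "label_atom_id",
               "label_alt_id", "label_comp_id", "label_asym_id",
               "label_entity_id", "pdbx_PDB_ins_code",
               "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
               "auth_seq_id", "auth_comp_id", "auth_asym_id",
               "pdbx_PDB_model_num"),
             atom_rows))
  writeLines(lines, path)
  invisible(path)
}

# Standard query-protein helix: chain A, 30 ALA residues mapped to the main
# query accession. Returns the CA coordinate matrix.
.fx_query_protein <- function(fx, chain = "A", n = 30L, entity = "1",
                              origin = c(0, 0, 0), comps = NULL) {
  .fx_add_chain(fx, chain, n, entity, origin, accession = FX_QUERY1,
                src = "man", comps = comps)
}

#' Scenario identifiers understood by the generator
#' @export
fixture_scenarios <- function() paste0("S", 1:12)

# --- individual scenarios ---------------------------------------------------

.fx_scenario <- function(scenario_id) {
  switch(scenario_id,
    S1 = {
      fx <- .fx_new("s001")
      ca <- .fx_query_protein(fx)
      .fx_add_ligand(fx, "LIG", "A", 201L, "2", ca[15, ] + c(3, 0, 0))
      list(fx = list(fx), expected = "LIG")
    },
    S2 = {
      fx <- .fx_new("s002")
      .fx_query_protein(fx)
      list(fx = list(fx), expected = character(0))
    },
    S3 = {
      fx <- .fx_new("s003")
      ca <- .fx_query_protein(fx)
      .fx_add_ligand(fx, "PHQ", "A", 301L, "2", ca[15, ] + c(3, 0, 0),
                     n_atoms = 7L)
      .fx_add_ligand(fx, "DGL", "A", 302L, "3", ca[15, ] + c(5, 0, 0),
                     n_atoms = 8L)
      .fx_add_covale(fx, "A", 301L, "PHQ", "C1", "A", 302L, "DGL", "N")
      list(fx = list(fx), expected = "PHQ-DGL")
    },
    S4 = {
      fx <- .fx_new("s004")
      ca <- .fx_query_protein(fx)
      # 11-residue cyclic peptide, ATOM/HETATM intercalated, on chain B
      comps <- c("ALA", "ABA", "ALA", "MLE", "ALA", "ABA", "ALA", "MLE",
                 "ALA", "ABA", "ALA")
      records <- rep(c("ATOM", "HETATM"), length.out = 11L)
      th <- seq(0, 2 * pi, length.out = 12L)[1:11]
      ring <- cbind(4 * cos(th) + ca[15, 1] + 6,
                    4 * sin(th) + ca[15, 2],
                    rep(ca[15, 3], 11L))
      .fx_add_chain(fx, "B", 11L, "2", accession = NULL, src = "syn",
                    comps = comps, records = records, coords = ring)
      for (i in 1:10) {
        .fx_add_covale(fx, "B", i, comps[i], "C", "B", i + 1L,
                       comps[i + 1L], "N")
      }
      list(fx = list(fx), expected = "chain-B")
    },
    S5 = {
      fx <- .fx_new("s005")
      ca <- .fx_query_protein(fx)
      .fx_add_ligand(fx, "ATP", "A", 401L, "2", ca[10, ] + c(3, 0, 0),
                     n_atoms = 10L)
      .fx_add_chain(fx, "E", 7L, "3", origin = ca[22, ] + c(4, 0, -4),
                    accession = NULL, src = "syn",
                    comps = c("GLY", "LEU", "SER", "THR", "PHE", "ALA",
                              "VAL"))
      list(fx = list(fx), expected = c("ATP", "chain-E"))
    },
    S6 = {
      fx <- .fx_new("s006")
      ca <- .fx_query_protein(fx, comps = c(rep("ALA", 9), "LYS",
                                            rep("ALA", 20)))
      .fx_add_ligand(fx, "CVX", "A", 501L, "2", ca[10, ] + c(3, 0, 0),
                     n_atoms = 9L)
      .fx_add_covale(fx, "A", 501L, "CVX", "C1", "A", 10L, "LYS", "NZ")
      list(fx = list(fx), expected = "CVX")
    },
    S7 = {
      fx <- .fx_new("s007")
      ca <- .fx_query_protein(fx, comps = c(rep("ALA", 11), "ASN",
                                            rep("ALA", 18)))
      centers <- rbind(ca[12, ] + c(3.5, 0, 0),
                       ca[12, ] + c(5.5, 0, 0),
                       ca[12, ] + c(7.5, 0, 0))
      .fx_add_branch(fx, "2", "G", c("NAG", "NAG", "BMA"), centers)
      .fx_add_covale(fx, "G", 1L, "NAG", "C1", "A", 12L, "ASN", "ND2")
      list(fx = list(fx), expected = character(0))
    },
    S8 = {
      fx <- .fx_new("s008")
      ca <- .fx_query_protein(fx)
      centers <- rbind(ca[18, ] + c(3.5, 0, 0),
                       ca[18, ] + c(5.5, 0, 0),
                       ca[18, ] + c(7.5, 0, 0),
                       ca[18, ] + c(9.5, 0, 0))
      .fx_add_branch(fx, "2", "C", c("IDS", "SGN", "IDS", "SGN"), centers)
      list(fx = list(fx), expected = "chain-C")
    },
    S9 = {
      fx <- .fx_new("s009")
      ca <- .fx_query_protein(fx)
      .fx_add_ligand(fx, "GOL", "A", 601L, "2", ca[8, ] + c(3, 0, 0),
                     n_atoms = 6L)
      .fx_add_ligand(fx, "LIG", "A", 602L, "3", ca[20, ] + c(3, 0, 0))
      list(fx = list(fx), expected = "LIG")
    },
    S10 = {
      fx <- .fx_new("s010")
      ca_a <- .fx_query_protein(fx, "A", entity = "1")
      ca_b <- .fx_add_chain(fx, "B", 30L, "1b", origin = c(25, 0, 0),
                            accession = FX_QUERY1)
      ca_c <- .fx_add_chain(fx, "C", 30L, "1c", origin = c(50, 0, 0),
                            accession = FX_QUERY1)
      # copy near the helix end sees fewer residues than one mid-helix
      .fx_add_ligand(fx, "5U6", "A", 701L, "2", ca_a[29, ] + c(3, 0, 2),
                     n_atoms = 8L)
      .fx_add_ligand(fx, "5U6", "B", 701L, "3", ca_b[15, ] + c(3, 0, 0),
                     n_atoms = 8L)
      .fx_add_ligand(fx, "5U6", "C", 701L, "4", ca_c[26, ] + c(3, 0, 0),
                     n_atoms = 8L)
      list(fx = list(fx), expected = "5U6")
    },
    S11 = {
      fx <- .fx_new("s011")
      ca <- .fx_query_protein(fx)
      # small natural protein, 36 residues, full-length UniProt match
      .fx_add_chain(fx, "L", 36L, "2", origin = c(-20, 0, 0),
                    accession = FX_QUERY2, src = "nat")
      .fx_add_ligand(fx, "T42", "A", 801L, "3", ca[25, ] + c(3, 0, 0),
                     n_atoms = 9L)
      list(fx = list(fx), expected = "T42")
    },
    stop("unknown scenario id: ", scenario_id, call. = FALSE)
  )
}

#' Generate the structures of a cluster-mode scenario
#'
#' Builds `n_structures` copies of one synthetic two-chain query protein,
#' each carrying ligand copies at one or both of two binding sites separated
#' by `d` Angstrom, with isotropic Gaussian jitter `sigma` on the ligand
#' positions and a random rigid motion applied to every structure. The
#' default geometry places 16 ligands over 5 structures at two sites 30 A
#' apart, which clusters into exactly two groups at the 10 A threshold.
#'
#' @param out_dir Directory receiving the mmCIF files.
#' @param n_structures Number of structures (default 5).
#' @param d Site separation in Angstrom (default 30).
#' @param sigma Ligand-position jitter SD in Angstrom (default 1).
#' @param seed Integer seed; identical seeds give identical bytes.
#' @return Data frame `pdb_id`, `file`, `n_ligands`, plus attribute
#'   `expected_clusters`.
#' @export
generate_cluster_set <- function(out_dir, n_structures = 5L, d = 30,
                                 sigma = 1, seed = 1L) {
  stopifnot(d > 0, sigma >= 0)
  set.seed(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_lig <- rep(16L %/% n_structures, n_structures)
  extra <- 16L %% n_structures
  if (extra > 0L) n_lig[seq_len(extra)] <- n_lig[seq_len(extra)] + 1L
  site1 <- .fx_helix(40L)[20, ] + c(4, 0, 0)
  site2 <- site1 + c(d, 0, 0)
  rows <- list()
  for (k in seq_len(n_structures)) {
    pdb_id <- paste0("s12", letters[k])
    fx <- .fx_new(pdb_id)
    .fx_add_chain(fx, "A", 40L, "1", accession = FX_QUERY3)
    .fx_add_chain(fx, "B", 40L, "2", origin = c(d, 0, 0),
                  accession = FX_QUERY3)
    for (j in seq_len(n_lig[k])) {
      site <- if (j %% 2L == 1L) site1 else site2
      center <- site + stats::rnorm(3, 0, sigma)
      .fx_add_ligand(fx, "LGX", if (j %% 2L == 1L) "A" else "B",
                     900L + j, as.character(10L + j), center,
                     n_atoms = 8L)
    }
    # random rigid motion of the whole structure
    ax <- stats::rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    ang <- stats::runif(1, 0, pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
    tr <- stats::rnorm(3, 0, 20)
    for (i in seq_along(fx$atoms)) {
      a <- fx$atoms[[i]]
      v <- as.vector(R %*% c(a$x, a$y, a$z)) + tr
      fx$atoms[[i]]$x <- v[1]
      fx$atoms[[i]]$y <- v[2]
      fx$atoms[[i]]$z <- v[3]
    }
    f <- file.path(out_dir, paste0(pdb_id, ".cif"))
    .fx_write(fx, f)
    rows[[k]] <- data.frame(pdb_id = pdb_id, file = f,
                            n_ligands = n_lig[k], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "expected_clusters") <- if (d > 10) 2L else 1L
  out
}

#' Generate one synthetic scenario
#'
#' Writes the scenario's mmCIF file(s) into `out_dir` and returns the
#' expected ligand labels (the test oracle). Scenario S12 delegates to
#' [generate_cluster_set()].
#'
#' @param scenario_id One of `fixture_scenarios()`.
#' @param out_dir Output directory.
#' @param seed Integer seed (only S12 draws random numbers).
#' @return List `pdb_ids`, `files`, `expected` (character vector of labels;
#'   empty = ligand-free), `query`.
#' @export
generate_scenario <- function(scenario_id, out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (scenario_id == "S12") {
    info <- generate_cluster_set(out_dir, seed = seed)
    return(list(pdb_ids = info$pdb_id, files = info$file,
                expected = rep("LGX", nrow(info)), query = FX_QUERY3,
                expected_clusters = attr(info, "expected_clusters")))
  }
  sc <- .fx_scenario(scenario_id)
  files <- vapply(sc$fx, function(fx) {
    f <- file.path(out_dir, paste0(fx$pdb_id, ".cif"))
    .fx_write(fx, f)
    f
  }, "")
  list(pdb_ids = vapply(sc$fx, function(fx) fx$pdb_id, ""),
       files = files, expected = sc$expected,
       query = if (scenario_id == "S12") FX_QUERY3 else FX_QUERY1)
}

#' Generate every scenario plus matching reference tables and manifest
#'
#' Produces a complete offline test bed: one mmCIF per structure under
#' `out_dir/cif`, the SIFTS / alias / BIRD / counts / keep / exclusion /
#' UniProt-length tables the pipeline needs, a truth table for the
#' evaluator, and a manifest of expected ligand labels per scenario.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @return List `cif_dir`, `tables` (named file paths), `manifest` (data
#'   frame `scenario`, `pdb_id`, `query`, `expected_labels`,
#'   `expected_clusters`).
#' @export
generate_all_scenarios <- function(out_dir, seed = 1L) {
  cif_dir <- file.path(out_dir, "cif")
  dir.create(cif_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  sifts <- list()
  for (sid in fixture_scenarios()) {
    sc <- generate_scenario(sid, cif_dir, seed = seed)
    if (sid == "S12") {
      for (p in sc$pdb_ids) {
        manifest[[length(manifest) + 1L]] <- data.frame(
          scenario = sid, pdb_id = p, query = sc$query,
          expected_labels = "LGX",
          expected_clusters = sc$expected_clusters,
          stringsAsFactors = FALSE)
        sifts[[length(sifts) + 1L]] <- data.frame(
          pdb_id = p, chain = c("A", "B"), uniprot = FX_QUERY3,
          stringsAsFactors = FALSE)
      }
      next
    }
    manifest[[length(manifest) + 1L]] <- data.frame(
      scenario = sid, pdb_id = sc$pdb_ids[1], query = sc$query,
      expected_labels = paste(sc$expected, collapse = ","),
      expected_clusters = NA_integer_, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, manifest)
  # SIFTS rows for the mapped protein chains (S1 exercises alias remediation
  # through a secondary accession)
  sifts[[length(sifts) + 1L]] <- data.frame(
    pdb_id = "s001", chain = "A", uniprot = FX_ALIAS1,
    stringsAsFactors = FALSE)
  for (p in sprintf("s%03d", 2:11)) {
    sifts[[length(sifts) + 1L]] <- data.frame(
      pdb_id = p, chain = "A", uniprot = FX_QUERY1,
      stringsAsFactors = FALSE)
  }
  sifts[[length(sifts) + 1L]] <- data.frame(
    pdb_id = "s010", chain = c("B", "C"), uniprot = FX_QUERY1,
    stringsAsFactors = FALSE)
  sifts[[length(sifts) + 1L]] <- data.frame(
    pdb_id = "s011", chain = "L", uniprot = FX_QUERY2,
    stringsAsFactors = FALSE)
  sifts <- do.call(rbind, sifts)

  tdir <- file.path(out_dir, "tables")
  dir.create(tdir, showWarnings = FALSE)
  wtab <- function(df, name) {
    f <- file.path(tdir, name)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }
  tables <- list(
    sifts = wtab(sifts, "sifts.tsv"),
    aliases = wtab(data.frame(secondary = FX_ALIAS1, primary = FX_QUERY1),
                   "aliases.tsv"),
    bird = wtab(data.frame(prd_id = "PRD_000001",
                           sequence = "AXAXAXAXAXA",
                           pdb_ids = "s004"), "bird.tsv"),
    counts = wtab(data.frame(
      code = c("HOH", "GOL", "EDO", "ATP", "BEN", "LIG", "PHQ", "DGL",
               "CVX", "T42", "5U6", "LGX"),
      n_pdbs = c(180000L, 10000L, 8000L, 5000L, 3000L, 12L, 12L, 5L, 3L,
                 4L, 40L, 2L)), "counts.tsv"),
    uniprot_lengths = wtab(data.frame(
      uniprot = c(FX_QUERY1, FX_QUERY2, FX_QUERY3),
      length = c(300L, 36L, 400L)), "uniprot_lengths.tsv")
  )
  keep_f <- file.path(tdir, "keep.txt")
  writeLines(c("# common but legitimate ligands",
               c("ATP", "ADP", "AMP", "GTP", "GDP", "NAD", "NAI", "NAP",
                 "FAD", "FMN", "SAM", "SAH", "HEM", "COA", "UDP")), keep_f)
  excl_f <- file.path(tdir, "exclusion.txt")
  writeLines(c("# solvents, additives, salts",
               c("HOH", "GOL", "EDO", "BEN", "SO4", "PO4", "PEG", "DMS",
                 "ACT", "FMT", "MPD", "TRS", "IMD", "CL", "NA")), excl_f)
  tables$keep <- keep_f
  tables$exclusion <- excl_f
  truth <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
    labs <- strsplit(manifest$expected_labels[i], ",")[[1]]
    labs <- labs[nchar(labs) > 0L]
    if (length(labs) == 0L) return(NULL)
    data.frame(pdb_id = manifest$pdb_id[i], label = labs,
               is_true_ligand = 1L, stringsAsFactors = FALSE)
  }))
  tables$truth <- wtab(truth, "truth.tsv")
  tables$manifest <- wtab(manifest, "manifest.tsv")
  list(cif_dir = cif_dir, tables = tables, manifest = manifest)
}
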