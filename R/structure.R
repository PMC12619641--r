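# Canonical amino acids + selenomethionine; residues with these codes inside a
# UniProt-mapped polymer chain are treated as protein, never as ligand.
STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE"
)

.num <- function(x) suppressWarnings(as.numeric(x))
.int <- function(x) suppressWarnings(as.integer(x))
.col <- function(df, nm, default = NA_character_) {
  if (!is.null(df) && nm %in% names(df)) df[[nm]] else
    rep(default, if (is.null(df)) 0L else nrow(df))
}

#' Parse a PDBx/mmCIF file into a structure model
#'
#' Builds the in-memory model used throughout the pipeline: the atom table,
#' entity descriptions, chain-to-database references, covalent connection
#' records, branched-entity (oligosaccharide) composition, per-entity
#' theoretical one-letter sequences and the reported resolution(s). Only the
#' first model of multi-model files is retained. Alternate locations are NOT
#' resolved here; call [resolve_altlocs()] before any downstream analysis.
#'
#' @param path Path to a `.cif` file with at least one `_atom_site` row.
#' @return An object of class `cif_structure` with elements `pdb_id`,
#'   `resolutions` (numeric, possibly empty), `atoms`, `entities`,
#'   `chain_refs`, `connections`, `branches` (data frames) and
#'   `theoretical_seqs` (named character, by entity id).
#' @export
parse_mmcif <- function(path) {
  cats <- read_mmcif_categories(path)
  as_ <- cats[["atom_site"]]
  if (is.null(as_) || nrow(as_) == 0L) {
    stop("no _atom_site records in ", path, call. = FALSE)
  }

  pdb_id <- tolower(.col(cats[["entry"]], "id", NA_character_)[1])
  if (is.na(pdb_id)) pdb_id <- tolower(sub("\\.cif$", "", basename(path)))

  atoms <- data.frame(
    record_kind = .col(as_, "group_PDB"),
    atom_name   = .col(as_, "label_atom_id"),
    element     = toupper(.col(as_, "type_symbol")),
    comp_id     = .col(as_, "label_comp_id"),
    auth_chain  = .col(as_, "auth_asym_id"),
    label_chain = .col(as_, "label_asym_id"),
    auth_seq    = .int(.col(as_, "auth_seq_id")),
    ins_code    = .col(as_, "pdbx_PDB_ins_code"),
    alt_loc     = .col(as_, "label_alt_id"),
    occupancy   = .num(.col(as_, "occupancy", "1")),
    x = .num(.col(as_, "Cartn_x")),
    y = .num(.col(as_, "Cartn_y")),
    z = .num(.col(as_, "Cartn_z")),
    entity_id   = .col(as_, "label_entity_id"),
    model_num   = .int(.col(as_, "pdbx_PDB_model_num", "1")),
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$auth_chain)) {
    atoms$auth_chain[is.na(atoms$auth_chain)] <-
      atoms$label_chain[is.na(atoms$auth_chain)]
  }
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  if (anyNA(atoms$model_num)) atoms$model_num[is.na(atoms$model_num)] <- 1L
  atoms <- atoms[atoms$model_num == min(atoms$model_num), , drop = FALSE]
  rownames(atoms) <- NULL

  ent <- cats[["entity"]]
  entities <- data.frame(
    entity_id   = .col(ent, "id"),
    entity_type = .col(ent, "type"),
    src_method  = .col(ent, "src_method"),
    description = .col(ent, "pdbx_description"),
    stringsAsFactors = FALSE
  )

  # chain -> database reference (via _struct_ref / _struct_ref_seq)
  sr <- cats[["struct_ref"]]
  srs <- cats[["struct_ref_seq"]]
  chain_refs <- data.frame(
    chain = character(0), db_name = character(0), accession = character(0),
    seq_begin = integer(0), seq_end = integer(0), stringsAsFactors = FALSE
  )
  if (!is.null(srs) && nrow(srs) > 0L) {
    ref_ids <- .col(srs, "ref_id")
    db_name <- rep(NA_character_, nrow(srs))
    acc <- .col(srs, "pdbx_db_accession")
    if (!is.null(sr) && nrow(sr) > 0L) {
      mi <- match(ref_ids, .col(sr, "id"))
      db_name <- .col(sr, "db_name")[mi]
      sr_acc <- .col(sr, "pdbx_db_accession")[mi]
      acc[is.na(acc)] <- sr_acc[is.na(acc)]
    }
    chain_refs <- data.frame(
      chain = .col(srs, "pdbx_strand_id"),
      db_name = db_name,
      accession = acc,
      seq_begin = .int(.col(srs, "db_align_beg")),
      seq_end = .int(.col(srs, "db_align_end")),
      stringsAsFactors = FALSE
    )
    # self-referenced chains: db reference is the PDB entry itself
    self_ref <- !is.na(chain_refs$db_name) &
      toupper(chain_refs$db_name) == "PDB"
    chain_refs$db_name[self_ref] <- "PDB"
  }

  sc <- cats[["struct_conn"]]
  connections <- data.frame(
    conn_type = .col(sc, "conn_type_id"),
    chain1 = .col(sc, "ptnr1_auth_asym_id"),
    seq1   = .int(.col(sc, "ptnr1_auth_seq_id")),
    comp1  = .col(sc, "ptnr1_label_comp_id"),
    atom1  = .col(sc, "ptnr1_label_atom_id"),
    chain2 = .col(sc, "ptnr2_auth_asym_id"),
    seq2   = .int(.col(sc, "ptnr2_auth_seq_id")),
    comp2  = .col(sc, "ptnr2_label_comp_id"),
    atom2  = .col(sc, "ptnr2_label_atom_id"),
    distance = .num(.col(sc, "pdbx_dist_value")),
    stringsAsFactors = FALSE
  )

  br <- cats[["pdbx_branch_scheme"]]
  branches <- data.frame(
    entity_id = .col(br, "entity_id"),
    comp_id = .col(br, "mon_id"),
    branch_pos = .int(.col(br, "num")),
    chain = .col(br, "pdb_asym_id"),
    auth_seq = .int(.col(br, "pdb_seq_num")),
    stringsAsFactors = FALSE
  )

  ep <- cats[["entity_poly"]]
  theoretical_seqs <- character(0)
  if (!is.null(ep) && nrow(ep) > 0L) {
    seqs <- .col(ep, "pdbx_seq_one_letter_code_can")
    if (all(is.na(seqs))) seqs <- .col(ep, "pdbx_seq_one_letter_code")
    seqs <- gsub("[\n ]", "", seqs)
    theoretical_seqs <- stats::setNames(seqs, .col(ep, "entity_id"))
  }
  poly_chains <- character(0)
  if (!is.null(ep) && nrow(ep) > 0L) {
    poly_chains <- stats::setNames(.col(ep, "pdbx_strand_id"),
                                   .col(ep, "entity_id"))
  }

  resolutions <- c(
    .num(.col(cats[["refine"]], "ls_d_res_high")),
    .num(.col(cats[["reflns"]], "d_resolution_high"))
  )
  resolutions <- resolutions[!is.na(resolutions)]

  structure(
    list(
      pdb_id = pdb_id,
      resolutions = resolutions,
      atoms = atoms,
      entities = entities,
      chain_refs = chain_refs,
      connections = connections,
      branches = branches,
      theoretical_seqs = theoretical_seqs,
      poly_chains = poly_chains
    ),
    class = "cif_structure"
  )
}

#' @export
print.cif_structure <- function(x, ...) {
  cat("<cif_structure> ", x$pdb_id, ": ", nrow(x$atoms), " atoms, ",
      nrow(x$entities), " entities, ", nrow(x$connections), " connections",
      if (length(x$resolutions)) paste0(", resolution ",
                                        max(x$resolutions), " A"), "\n",
      sep = "")
  invisible(x)
}

#' Effective resolution of a structure
#'
#' When several resolution values are reported in one entry, the highest
#' (numerically largest, i.e. worst) value is taken as the effective
#' resolution used for the resolution gate.
#'
#' @param structure A `cif_structure`.
#' @return Numeric scalar in Angstrom, or `NA` when no resolution is reported.
#' @export
effective_resolution <- function(structure) {
  if (length(structure$resolutions) == 0L) return(NA_real_)
  max(structure$resolutions)
}

#' Resolve alternate-location atoms
#'
#' Per (chain, residue number, atom name) group, keeps exactly one atom: the
#' one with maximal occupancy, ties broken by the lexicographically smallest
#' alternate-location indicator. Structures without alternate locations pass
#' through unchanged. Idempotent.
#'
#' @param structure A `cif_structure`.
#' @return The structure with a deduplicated atom table.
#' @export
resolve_altlocs <- function(structure) {
  a <- structure$atoms
  if (nrow(a) == 0L) return(structure)
  key <- paste(a$auth_chain, a$auth_seq, a$ins_code, a$atom_name, sep = "\r")
  if (!anyDuplicated(key)) return(structure)
  alt <- ifelse(is.na(a$alt_loc), "", a$alt_loc)
  ord <- order(key, -a$occupancy, alt)
  keep <- ord[!duplicated(key[ord])]
  structure$atoms <- a[sort(keep), , drop = FALSE]
  rownames(structure$atoms) <- NULL
  structure
}

#' Replace 5-character component codes with short codes
#'
#' Long (5-character) chemical component codes cannot be represented in
#' fixed-column PDB output; this applies a user-supplied mapping to short
#' codes consistently across atoms, connection records and branch schemes.
#'
#' @param structure A `cif_structure`.
#' @param code_map Named character vector, `names` = 5-char codes,
#'   values = short replacement codes (max 3 characters).
#' @return The structure with codes replaced.
#' @export
shorten_ligand_codes <- function(structure, code_map = character(0)) {
  long <- unique(structure$atoms$comp_id[nchar(structure$atoms$comp_id) == 5L])
  missing <- setdiff(long, names(code_map))
  if (length(missing) > 0L) {
    stop("no short code mapping for 5-character component code(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(long) == 0L) return(structure)
  remap <- function(x) {
    hit <- x %in% names(code_map)
    x[hit] <- unname(code_map[x[hit]])
    x
  }
  structure$atoms$comp_id <- remap(structure$atoms$comp_id)
  if (nrow(structure$connections) > 0L) {
    structure$connections$comp1 <- remap(structure$connections$comp1)
    structure$connections$comp2 <- remap(structure$connections$comp2)
  }
  if (nrow(structure$branches) > 0L) {
    structure$branches$comp_id <- remap(structure$branches$comp_id)
  }
  structure
}

#' Write a subset of atoms in fixed-column PDB format
#'
#' Emits v3.3-style ATOM/HETATM records (plus TER and END) with the original
#' coordinates unchanged and auth numbering for chain and residue identifiers.
#' The original ATOM/HETATM record kind of every atom is preserved, so chain
#' ligands spanning both record groups round-trip faithfully.
#'
#' @param structure A `cif_structure`.
#' @param selection Logical vector over rows of `structure$atoms` (or integer
#'   row indices) naming the atoms to write.
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
write_pdb_subset <- function(structure, selection, path) {
  a <- structure$atoms[selection, , drop = FALSE]
  if (nrow(a) == 0L) stop("empty atom selection", call. = FALSE)
  fmt_name <- function(nm, el) {
    # columns 13-16: element right-justified in 13-14 for 1-char elements
    ifelse(nchar(nm) >= 4L, substr(nm, 1L, 4L),
           ifelse(nchar(el) == 1L, sprintf(" %-3s", nm), sprintf("%-4s", nm)))
  }
  lines <- sprintf(
    "%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(a$record_kind == "ATOM", "ATOM", "HETATM"),
    seq_len(nrow(a)) %% 100000L,
    fmt_name(a$atom_name, a$element),
    "",
    substr(a$comp_id, 1L, 3L),
    substr(a$auth_chain, 1L, 1L),
    a$auth_seq %% 10000L,
    ifelse(is.na(a$ins_code), " ", a$ins_code),
    a$x, a$y, a$z,
    a$occupancy, 0,
    a$element
  )
  # TER between chains
  chains <- a$auth_chain
  breaks <- which(chains[-1] != chains[-length(chains)])
  out <- character(0)
  prev <- 1L
  for (b in c(breaks, length(lines))) {
    out <- c(out, lines[prev:b], "TER")
    prev <- b + 1L
  }
  out[length(out)] <- "TER"
  writeLines(c(out, "END"), path)
  invisible(path)
}

# Residue-level view of the atom table: one row per distinct residue, in
# first-appearance order. Hydrogens never define a residue on their own.
residue_table <- function(structure) {
  a <- structure$atoms
  key <- paste(a$auth_chain, a$auth_seq,
               ifelse(is.na(a$ins_code), "", a$ins_code), sep = "|")
  first <- !duplicated(key)
  heavy <- a$element != "H" & a$element != "D"
  counts <- tapply(heavy, key, sum)
  res <- data.frame(
    res_key = key[first],
    chain = a$auth_chain[first],
    auth_seq = a$auth_seq[first],
    ins_code = a$ins_code[first],
    comp_id = a$comp_id[first],
    record_kind = a$record_kind[first],
    entity_id = a$entity_id[first],
    heavy_atoms = as.integer(counts[key[first]]),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  res
}

res_key <- function(chain, auth_seq, ins_code = NA_character_) {
  paste(chain, auth_seq, ifelse(is.na(ins_code), "", ins_code), sep = "|")
}
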