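# Ligand enumeration: covalent connectivity graph assembly, peptide-chain
# classification, oligosaccharide/glycosylation triage, candidate assembly
# and the enumeration-stage size/frequency filters.

# Three-letter -> one-letter amino acid codes (MSE read as M).
AA_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M"
)

#' Build the residue-level covalent connectivity graph
#'
#' Nodes are all residues of the structure. Edges come from two sources:
#' explicit `covale` connection records (added verbatim, one edge per
#' record), and implicit sequential-polymer links between residues with
#' consecutive residue numbers on the same chain when both are in the ATOM
#' record group. HETATM residues gain edges only from explicit covale
#' records, which is what allows molecules split across ATOM and HETATM
#' records to be reassembled.
#'
#' @param structure A `cif_structure` with alternate locations resolved.
#' @return An [igraph::graph] whose vertex names are residue keys
#'   (`chain|seq|ins`), with vertex attributes `comp_id`, `record_kind`,
#'   `chain` and an edge attribute `bond` (`"covale"` or `"seq"`).
#' @export
build_connectivity_graph <- function(structure) {
  res <- residue_table(structure)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(res), name = res$res_key,
                            comp_id = res$comp_id,
                            record_kind = res$record_kind,
                            chain = res$chain)
  edges <- character(0)
  bonds <- character(0)
  # implicit sequential links between consecutive ATOM residues of one chain
  for (ch in unique(res$chain)) {
    r <- res[res$chain == ch, , drop = FALSE]
    r <- r[order(r$auth_seq), , drop = FALSE]
    if (nrow(r) < 2L) next
    consec <- which(diff(r$auth_seq) == 1L &
                    r$record_kind[-nrow(r)] == "ATOM" &
                    r$record_kind[-1L] == "ATOM")
    if (length(consec)) {
      edges <- c(edges, rbind(r$res_key[consec], r$res_key[consec + 1L]))
      bonds <- c(bonds, rep("seq", length(consec)))
    }
  }
  # explicit covalent links
  conn <- structure$connections
  if (nrow(conn) > 0L) {
    cov <- conn[!is.na(conn$conn_type) & conn$conn_type == "covale", ,
                drop = FALSE]
    if (nrow(cov) > 0L) {
      k1 <- res_key(cov$chain1, cov$seq1)
      k2 <- res_key(cov$chain2, cov$seq2)
      ok <- k1 %in% res$res_key & k2 %in% res$res_key & k1 != k2
      if (any(!ok)) {
        warning(sum(!ok), " covale record(s) reference residues absent from ",
                "the structure; skipped", call. = FALSE)
      }
      if (any(ok)) {
        edges <- c(edges, rbind(k1[ok], k2[ok]))
        bonds <- c(bonds, rep("covale", sum(ok)))
      }
    }
  }
  if (length(edges)) {
    g <- igraph::add_edges(g, edges, bond = bonds)
    g <- igraph::simplify(g, edge.attr.comb = "first")
  }
  g
}

# Chains carrying a UniProt reference (after alias remediation), as a named
# character vector chain -> primary accession. Chimeric chains keep every
# accession (one element per mapping).
uniprot_chain_map <- function(structure, aliases = character(0)) {
  cr <- structure$chain_refs
  cr <- cr[!is.na(cr$db_name) & toupper(cr$db_name) == "UNP" &
             !is.na(cr$accession), , drop = FALSE]
  if (nrow(cr) == 0L) return(character(0))
  stats::setNames(remediate_accession(cr$accession, aliases), cr$chain)
}

# Entity type per residue key, "" when unknown.
.entity_type_by_residue <- function(structure) {
  res <- residue_table(structure)
  type <- structure$entities$entity_type[
    match(res$entity_id, structure$entities$entity_id)]
  type[is.na(type)] <- ""
  stats::setNames(type, res$res_key)
}

# Residue keys that belong to branched (oligosaccharide) entities.
.branched_residue_keys <- function(structure) {
  br <- structure$branches
  if (nrow(br) == 0L) return(character(0))
  res_key(br$chain, br$auth_seq)
}

#' Detect covalent links between protein chains and non-protein residues
#'
#' Scans every `covale` connection record and reports those joining a
#' standard amino-acid residue of a UniProt-mapped polymer chain to any
#' residue that is not one, together with the precise atoms involved. These
#' links flag covalent ligands and glycosylation attachments.
#'
#' @param structure A `cif_structure`.
#' @param aliases Accession alias map (secondary to primary).
#' @return Data frame `ligand_res`, `ligand_comp`, `protein_res`,
#'   `protein_comp`, `ligand_atom`, `protein_atom` (one row per link).
#' @export
detect_protein_covalent_links <- function(structure,
                                          aliases = character(0)) {
  out <- data.frame(ligand_res = character(0), ligand_comp = character(0),
                    protein_res = character(0), protein_comp = character(0),
                    ligand_atom = character(0), protein_atom = character(0),
                    stringsAsFactors = FALSE)
  conn <- structure$connections
  if (nrow(conn) == 0L) return(out)
  cov <- conn[!is.na(conn$conn_type) & conn$conn_type == "covale", ,
              drop = FALSE]
  if (nrow(cov) == 0L) return(out)
  mapped <- names(uniprot_chain_map(structure, aliases))
  is_protein_side <- function(chain, comp) {
    chain %in% mapped & comp %in% STANDARD_AA
  }
  p1 <- is_protein_side(cov$chain1, cov$comp1)
  p2 <- is_protein_side(cov$chain2, cov$comp2)
  pick <- function(rows, prot, lig) {
    sub <- cov[rows, , drop = FALSE]
    if (nrow(sub) == 0L) return(out)
    data.frame(
      ligand_res = res_key(sub[[paste0("chain", lig)]],
                           sub[[paste0("seq", lig)]]),
      ligand_comp = sub[[paste0("comp", lig)]],
      protein_res = res_key(sub[[paste0("chain", prot)]],
                            sub[[paste0("seq", prot)]]),
      protein_comp = sub[[paste0("comp", prot)]],
      ligand_atom = sub[[paste0("atom", lig)]],
      protein_atom = sub[[paste0("atom", prot)]],
      stringsAsFactors = FALSE
    )
  }
  res <- rbind(pick(p1 & !p2, prot = 1, lig = 2),
               pick(p2 & !p1, prot = 2, lig = 1))
  rownames(res) <- NULL
  res
}

# One-letter sequence actually resolved for a chain (polymer residues in
# residue-number order; non-standard residues become X).
resolved_chain_sequence <- function(structure, chain) {
  res <- residue_table(structure)
  r <- res[res$chain == chain, , drop = FALSE]
  et <- .entity_type_by_residue(structure)
  r <- r[et[r$res_key] == "polymer", , drop = FALSE]
  r <- r[order(r$auth_seq), , drop = FALSE]
  one <- AA_321[r$comp_id]
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

#' Classify a polymer chain as peptide ligand or protein
#'
#' A chain is a peptide ligand when (a) it has no UniProt reference (a
#' self-referenced chain, i.e. a synthesized peptide or an unmapped protein),
#' or (b) its one-letter sequence exactly matches a reference-dictionary
#' (BIRD) sequence, or (c) it is UniProt-mapped but was synthesized
#' (`_entity.src_method = "syn"`), its resolved residues cover at least
#' `alpha` of the theoretical sequence, and the theoretical sequence is at
#' most `beta` of the full-length UniProt sequence. Mapped chains failing
#' these tests stay protein: a small natural protein whose deposited sequence
#' matches its full UniProt length is never called a peptide.
#'
#' @param chain Chain identifier.
#' @param structure A `cif_structure`.
#' @param refs Reference tables from [load_reference_tables()].
#' @param alpha Minimum resolved/theoretical length ratio (default 0.8).
#' @param beta Maximum theoretical/full-length ratio (default 0.5).
#' @return List `is_ligand` (logical), `reason` (string), `prd_id`
#'   (string or `NA`).
#' @export
classify_chain_as_peptide_ligand <- function(chain, structure, refs,
                                             alpha = 0.8, beta = 0.5) {
  res <- residue_table(structure)
  if (!chain %in% res$chain) {
    stop("chain '", chain, "' not present in structure ", structure$pdb_id,
         call. = FALSE)
  }
  seq1 <- resolved_chain_sequence(structure, chain)
  # (b) BIRD full-sequence match confirms a chain as a ligand
  if (nrow(refs$bird) > 0L && nchar(seq1) > 0L) {
    hit <- match(seq1, refs$bird$sequence)
    if (!is.na(hit)) {
      return(list(is_ligand = TRUE, reason = "bird-match",
                  prd_id = refs$bird$prd_id[hit]))
    }
  }
  mapped <- uniprot_chain_map(structure, refs$aliases)
  if (!chain %in% names(mapped)) {
    return(list(is_ligand = TRUE, reason = "unmapped-chain", prd_id = NA))
  }
  # (c) mapped synthetic construct, near-fully resolved, much shorter than
  # the full-length UniProt sequence
  ent_id <- res$entity_id[match(chain, res$chain)]
  src <- structure$entities$src_method[
    match(ent_id, structure$entities$entity_id)]
  theo <- structure$theoretical_seqs[ent_id]
  theo_len <- if (is.na(theo)) NA_integer_ else nchar(theo)
  full_len <- refs$uniprot_lengths[mapped[[chain]]]
  if (!is.na(src) && src == "syn" && !is.na(theo_len) &&
      length(full_len) == 1L && !is.na(full_len) &&
      nchar(seq1) >= alpha * theo_len && theo_len <= beta * full_len) {
    return(list(is_ligand = TRUE, reason = "synthetic-short-construct",
                prd_id = NA))
  }
  if (length(full_len) == 1L && !is.na(full_len) && !is.na(theo_len) &&
      theo_len > beta * full_len) {
    return(list(is_ligand = FALSE, reason = "full-length-protein",
                prd_id = NA))
  }
  list(is_ligand = FALSE, reason = "mapped-chain", prd_id = NA)
}

#' Decide whether a branched (oligosaccharide) entity is a ligand
#'
#' Branched entities covalently attached to a standard glycosylation
#' acceptor residue (ASN, SER or THR) of a UniProt-mapped chain are
#' glycosylation groups, not ligands — unless their monomer sequence matches
#' a reference-dictionary (BIRD) entry, in which case they are kept as
#' candidates but flagged covalent. Free oligosaccharides (heparin-like
#' chains) are ligands.
#'
#' @param entity_id Branched entity id.
#' @param structure A `cif_structure`.
#' @param refs Reference tables.
#' @return List `is_ligand`, `reason`, `prd_id`, `covalent` (logical).
#' @export
classify_oligosaccharide <- function(entity_id, structure, refs) {
  br <- structure$branches[structure$branches$entity_id == entity_id, ,
                           drop = FALSE]
  if (nrow(br) == 0L) {
    stop("entity '", entity_id, "' has no branch scheme", call. = FALSE)
  }
  keys <- res_key(br$chain, br$auth_seq)
  links <- detect_protein_covalent_links(structure, refs$aliases)
  att <- links[links$ligand_res %in% keys, , drop = FALSE]
  glyco <- any(att$protein_comp %in% c("ASN", "SER", "THR"))
  covalent <- nrow(att) > 0L
  # BIRD matching for branched entities: hyphen-joined monomer codes in
  # branch order stand in for a sequence
  mono <- paste(br$comp_id[order(br$branch_pos)], collapse = "-")
  prd <- NA_character_
  if (nrow(refs$bird) > 0L) {
    hit <- match(mono, refs$bird$sequence)
    if (!is.na(hit)) prd <- refs$bird$prd_id[hit]
  }
  if (!is.na(prd)) {
    return(list(is_ligand = TRUE,
                reason = if (covalent) "bird-match-covalent" else "bird-match",
                prd_id = prd, covalent = covalent))
  }
  if (glyco) {
    acceptor <- att$protein_comp[att$protein_comp %in%
                                   c("ASN", "SER", "THR")][1]
    reason <- switch(acceptor, ASN = "N-glycosylation", "O-glycosylation")
    return(list(is_ligand = FALSE, reason = reason, prd_id = NA,
                covalent = TRUE))
  }
  list(is_ligand = TRUE, reason = "free-oligosaccharide", prd_id = NA,
       covalent = covalent)
}

.new_candidate <- function(structure, keys, kind, prd_id = NA_character_,
                           covalent = FALSE, flags = character(0),
                           chain = NULL) {
  res <- residue_table(structure)
  r <- res[match(keys, res$res_key), , drop = FALSE]
  r <- r[order(r$chain, r$auth_seq), , drop = FALSE]
  comps <- r$comp_id
  uid <- if (kind %in% c("chain_peptide", "bird_matched", "oligosaccharide") &&
             !is.null(chain)) {
    paste0("chain-", chain)
  } else if (nrow(r) == 1L) {
    paste(comps, r$chain, r$auth_seq, sep = "_")
  } else {
    paste(paste(comps, collapse = "-"), r$chain[1], r$auth_seq[1], sep = "_")
  }
  label <- if (startsWith(uid, "chain-")) uid
           else if (nrow(r) == 1L) comps
           else paste(comps, collapse = "-")
  if (nrow(r) > 1L && !startsWith(uid, "chain-")) {
    flags <- union(flags, "reassembled_multi_residue")
  }
  if (covalent) flags <- union(flags, "covalent")
  list(
    ligand_uid = uid,
    label = toupper(label),
    kind = kind,
    residues = r[, c("res_key", "chain", "auth_seq", "ins_code", "comp_id",
                     "record_kind")],
    heavy_atom_count = sum(r$heavy_atoms),
    covalent_to_protein = covalent,
    prd_id = prd_id,
    flags = flags,
    chain = if (is.null(chain)) r$chain[1] else chain,
    entity_id = r$entity_id[1]
  )
}

#' Enumerate every candidate ligand in a structure
#'
#' Protein residues (standard amino acids of UniProt-mapped polymer chains
#' not reclassified as peptide ligands) and waters are removed from the
#' connectivity graph; every remaining connected component containing at
#' least one HETATM residue, or belonging to a peptide-classified chain,
#' becomes one candidate. Components spanning several residues are thereby
#' reassembled into single ligands (fragments are never reported alone).
#' Branched entities are triaged by [classify_oligosaccharide()];
#' glycosylation groups yield no candidate.
#'
#' @param structure A `cif_structure` (altlocs resolved).
#' @param graph Connectivity graph from [build_connectivity_graph()].
#' @param refs Reference tables from [load_reference_tables()].
#' @param alpha,beta Peptide-rule thresholds, see
#'   [classify_chain_as_peptide_ligand()].
#' @return List with `candidates` (list of candidate records) and `log`
#'   (character vector of `EVENT\tdetail` lines).
#' @export
enumerate_candidates <- function(structure, graph, refs,
                                 alpha = 0.8, beta = 0.5) {
  res <- residue_table(structure)
  etype <- .entity_type_by_residue(structure)
  log <- character(0)
  ev <- function(event, detail) sprintf("%s\t%s\t%s", structure$pdb_id,
                                        event, detail)

  water <- res$res_key[etype[res$res_key] == "water" |
                         res$comp_id %in% c("HOH", "DOD")]
  branched_keys <- .branched_residue_keys(structure)
  links <- detect_protein_covalent_links(structure, refs$aliases)
  for (i in seq_len(nrow(links))) {
    log <- c(log, ev("COVALENT_LINK",
                     sprintf("%s(%s) %s-%s %s(%s)", links$ligand_comp[i],
                             links$ligand_res[i], links$ligand_atom[i],
                             links$protein_atom[i], links$protein_comp[i],
                             links$protein_res[i])))
  }

  # classify polymer chains
  mapped <- uniprot_chain_map(structure, refs$aliases)
  poly_chains <- unique(res$chain[etype[res$res_key] == "polymer"])
  peptide_info <- list()
  protein_chains <- character(0)
  for (ch in poly_chains) {
    cls <- classify_chain_as_peptide_ligand(ch, structure, refs,
                                            alpha = alpha, beta = beta)
    log <- c(log, ev("PEPTIDE_DECISION",
                     sprintf("chain %s: %s (%s)", ch,
                             if (cls$is_ligand) "ligand" else "protein",
                             cls$reason)))
    if (cls$is_ligand) peptide_info[[ch]] <- cls
    else protein_chains <- c(protein_chains, ch)
  }
  protein_keys <- res$res_key[res$chain %in% protein_chains &
                                etype[res$res_key] == "polymer"]

  # branched entities
  branch_cands <- list()
  glyco_keys <- character(0)
  for (eid in unique(structure$branches$entity_id)) {
    cls <- classify_oligosaccharide(eid, structure, refs)
    br <- structure$branches[structure$branches$entity_id == eid, ,
                             drop = FALSE]
    keys <- res_key(br$chain, br$auth_seq)
    if (cls$is_ligand) {
      branch_cands[[length(branch_cands) + 1L]] <- .new_candidate(
        structure, keys,
        kind = if (!is.na(cls$prd_id)) "bird_matched" else "oligosaccharide",
        prd_id = cls$prd_id, covalent = cls$covalent, chain = br$chain[1])
      if (cls$covalent) {
        log <- c(log, ev("COVALENT_LIGAND",
                         sprintf("branched entity %s (%s) bound to protein",
                                 eid, cls$reason)))
      }
    } else {
      glyco_keys <- c(glyco_keys, keys)
      log <- c(log, ev("GLYCOSYLATION_EXCLUDED",
                       sprintf("branched entity %s: %s", eid, cls$reason)))
    }
  }

  # components of the graph restricted to candidate-eligible residues
  drop <- unique(c(protein_keys, water, branched_keys, glyco_keys))
  keep_keys <- setdiff(res$res_key, drop)
  cands <- list()
  if (length(keep_keys) > 0L) {
    sub <- igraph::induced_subgraph(graph,
                                    igraph::V(graph)$name %in% keep_keys)
    comp <- igraph::components(sub)
    vnames <- igraph::V(sub)$name
    cov_lig_keys <- unique(links$ligand_res)
    for (ci in seq_len(comp$no)) {
      keys <- vnames[comp$membership == ci]
      rsub <- res[match(keys, res$res_key), , drop = FALSE]
      pep_ch <- intersect(unique(rsub$chain[etype[keys] == "polymer"]),
                          names(peptide_info))
      has_het <- any(rsub$record_kind == "HETATM")
      if (length(pep_ch) == 0L && !has_het) next
      covalent <- any(keys %in% cov_lig_keys)
      if (length(pep_ch) > 0L) {
        ch <- pep_ch[1]
        info <- peptide_info[[ch]]
        kind <- if (!is.na(info$prd_id)) "bird_matched" else "chain_peptide"
        cand <- .new_candidate(structure, keys, kind, prd_id = info$prd_id,
                               covalent = covalent, chain = ch)
      } else {
        cand <- .new_candidate(structure, keys, "small_molecule",
                               covalent = covalent)
        if (length(keys) > 1L) {
          log <- c(log, ev("REASSEMBLED",
                           sprintf("%s assembled from %d residues",
                                   cand$ligand_uid, length(keys))))
        }
      }
      if (covalent) {
        log <- c(log, ev("COVALENT_LIGAND",
                         sprintf("%s covalently bound to protein",
                                 cand$ligand_uid)))
      }
      cands[[length(cands) + 1L]] <- cand
    }
  }
  cands <- c(cands, branch_cands)
  list(candidates = cands, log = log, protein_keys = protein_keys)
}

#' Apply the enumeration-stage filters
#'
#' Flags frequent ligands (component codes occurring in more than
#' `frequent_threshold` PDB entries and not on the keep list) without
#' removing them; removes candidates with fewer than `min_heavy_atoms` heavy
#' atoms; removes every copy of a component code instantiated more than
#' `max_copies` times within one structure.
#'
#' @param candidates Candidate list from [enumerate_candidates()].
#' @param counts Named integer vector from [read_ligand_counts()].
#' @param keep Character vector of codes exempt from the frequent-ligand
#'   rule.
#' @param frequent_threshold,min_heavy_atoms,max_copies Numeric thresholds
#'   (defaults 250, 3, 10).
#' @param pdb_id Used only for log lines.
#' @return List `candidates` (kept, possibly flagged) and `log`.
#' @export
apply_enumeration_filters <- function(candidates, counts, keep,
                                      frequent_threshold = 250,
                                      min_heavy_atoms = 3,
                                      max_copies = 10,
                                      pdb_id = "") {
  log <- character(0)
  ev <- function(event, detail) sprintf("%s\t%s\t%s", pdb_id, event, detail)
  if (length(candidates) == 0L) return(list(candidates = candidates,
                                            log = log))
  single_code <- vapply(candidates, function(cn) {
    if (cn$kind == "small_molecule" && nrow(cn$residues) == 1L)
      cn$residues$comp_id[1] else NA_character_
  }, "")
  # frequent-ligand rule: flag only
  for (i in seq_along(candidates)) {
    code <- single_code[i]
    if (!is.na(code) && code %in% names(counts) &&
        counts[[code]] > frequent_threshold && !(code %in% keep)) {
      candidates[[i]]$flags <- union(candidates[[i]]$flags, "frequent_ligand")
      log <- c(log, ev("FREQUENT_LIGAND",
                       sprintf("%s occurs in %d PDB entries", code,
                               counts[[code]])))
    }
  }
  # size filter
  heavy <- vapply(candidates, function(cn) cn$heavy_atom_count, 0L)
  small <- heavy < min_heavy_atoms
  for (i in which(small)) {
    log <- c(log, ev("EXCLUDED_SIZE",
                     sprintf("%s has %d heavy atoms (< %d)",
                             candidates[[i]]$ligand_uid, heavy[i],
                             min_heavy_atoms)))
  }
  candidates <- candidates[!small]
  single_code <- single_code[!small]
  # copy-count filter
  tab <- table(single_code[!is.na(single_code)])
  over <- names(tab)[tab > max_copies]
  drop <- !is.na(single_code) & single_code %in% over
  for (code in over) {
    log <- c(log, ev("EXCLUDED_COPIES",
                     sprintf("%s instantiated %d times (> %d)", code,
                             tab[[code]], max_copies)))
  }
  list(candidates = candidates[!drop], log = log)
}
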