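# Ligand processing: exclusion-list removal, query-chain presence check and
# the 6 A binding-pocket proximity gate.

#' Remove exclusion-list molecules
#'
#' Drops single-residue small-molecule candidates whose component code is on
#' the exclusion list (solvents, crystallization additives, salts).
#' Multi-residue candidates are never removed by this filter: a listed code
#' that is part of a larger reassembled ligand stays.
#'
#' @param candidates Candidate list from [enumerate_candidates()].
#' @param exclusion Character vector of excluded component codes.
#' @param pdb_id Used only for log lines.
#' @return List `candidates` (kept) and `log`.
#' @export
filter_exclusion_list <- function(candidates, exclusion, pdb_id = "") {
  log <- character(0)
  if (length(candidates) == 0L || length(exclusion) == 0L) {
    return(list(candidates = candidates, log = log))
  }
  drop <- vapply(candidates, function(cn) {
    cn$kind == "small_molecule" && nrow(cn$residues) == 1L &&
      toupper(cn$residues$comp_id[1]) %in% exclusion
  }, NA)
  for (i in which(drop)) {
    log <- c(log, sprintf("%s\tEXCLUSION_LIST\t%s removed (code %s)",
                          pdb_id, candidates[[i]]$ligand_uid,
                          candidates[[i]]$residues$comp_id[1]))
  }
  list(candidates = candidates[!drop], log = log)
}

#' Does the structure contain the query protein?
#'
#' True iff at least one chain database reference remediates to the query's
#' primary accession (secondary accessions recorded in older depositions are
#' therefore honored). Structures failing this check are dropped: the query
#' protein is absent, so none of the ligands can be its ligands.
#'
#' @param structure A `cif_structure`.
#' @param query A UniProt accession.
#' @param aliases Accession alias map.
#' @return Logical scalar.
#' @export
require_query_chain <- function(structure, query, aliases = character(0)) {
  mapped <- uniprot_chain_map(structure, aliases)
  remediate_accession(query, aliases) %in% mapped
}

# Chains of the structure whose reference remediates to the query accession.
query_chains <- function(structure, query, aliases = character(0)) {
  mapped <- uniprot_chain_map(structure, aliases)
  unique(names(mapped)[mapped == remediate_accession(query, aliases)])
}

#' Gate candidates on binding-pocket proximity to the query chains
#'
#' For each candidate, collects every polymer residue with at least one
#' heavy atom within `cutoff` of at least one ligand heavy atom (the
#' ligand's own residues excluded; boundary inclusive). Candidates without a
#' single nearby residue on a query chain are discarded — the ligand is
#' present but does not contact the protein of interest. Survivors yield
#' pocket records.
#'
#' @param candidates Candidate list.
#' @param structure A `cif_structure`.
#' @param qchains Character vector of query chain identifiers.
#' @param cutoff Distance cutoff in Angstrom (default 6.0).
#' @return List `pockets` (list of pocket records: candidate fields plus
#'   `nearby` data frame, `residue_count`, `contact_chains`,
#'   `query_contact`) and `log`.
#' @export
pocket_gate <- function(candidates, structure, qchains, cutoff = 6.0) {
  stopifnot(cutoff > 0)
  log <- character(0)
  pockets <- list()
  if (length(candidates) == 0L) return(list(pockets = pockets, log = log))
  a <- structure$atoms
  heavy <- a$element != "H" & a$element != "D"
  akey <- res_key(a$auth_chain, a$auth_seq, a$ins_code)
  etype <- .entity_type_by_residue(structure)
  poly_atom <- etype[akey] == "polymer" & !is.na(etype[akey])
  for (cand in candidates) {
    lig_rows <- heavy & akey %in% cand$residues$res_key
    env_rows <- heavy & poly_atom & !(akey %in% cand$residues$res_key)
    if (!any(lig_rows) || !any(env_rows)) {
      log <- c(log, sprintf("%s\tNO_QUERY_CONTACT\t%s", structure$pdb_id,
                            cand$ligand_uid))
      next
    }
    lx <- as.matrix(a[lig_rows, c("x", "y", "z")])
    ex <- as.matrix(a[env_rows, c("x", "y", "z")])
    # all-pairs min distance per environment atom
    d2 <- outer(rowSums(ex^2), rowSums(lx^2), "+") - 2 * ex %*% t(lx)
    near_atom <- apply(d2, 1L, min) <= cutoff^2 + 1e-9
    near_keys <- unique(akey[env_rows][near_atom])
    if (length(near_keys) == 0L ||
        !any(sub("\\|.*$", "", near_keys) %in% qchains)) {
      log <- c(log, sprintf("%s\tNO_QUERY_CONTACT\t%s", structure$pdb_id,
                            cand$ligand_uid))
      next
    }
    res <- residue_table(structure)
    nearby <- res[match(near_keys, res$res_key),
                  c("chain", "auth_seq", "comp_id"), drop = FALSE]
    nearby <- nearby[order(nearby$chain, nearby$auth_seq), , drop = FALSE]
    rownames(nearby) <- NULL
    cand$nearby <- nearby
    cand$residue_count <- nrow(nearby)
    cand$contact_chains <- sort(unique(nearby$chain))
    cand$query_contact <- TRUE
    pockets[[length(pockets) + 1L]] <- cand
  }
  list(pockets = pockets, log = log)
}

#' Write the pocket information file
#'
#' One row per surviving ligand: its file name, source structure, ligand
#' identifier, nearby-residue count and the nearby residues themselves as
#' `chain:resnum:comp` triplets.
#'
#' @param pockets Pocket records from [pocket_gate()].
#' @param pdb_id Source structure id.
#' @param path Output TSV path.
#' @param files Optional named character vector mapping ligand uid to the
#'   ligand PDB file name.
#' @return Invisibly, the path.
#' @export
write_pocket_file <- function(pockets, pdb_id, path, files = character(0)) {
  rows <- vapply(pockets, function(p) {
    resstr <- paste(sprintf("%s:%d:%s", p$nearby$chain, p$nearby$auth_seq,
                            p$nearby$comp_id), collapse = ";")
    fn <- if (p$ligand_uid %in% names(files)) files[[p$ligand_uid]] else
      paste0(pdb_id, "_", gsub("[^A-Za-z0-9_-]", "_", p$ligand_uid), ".pdb")
    paste(fn, pdb_id, p$ligand_uid, p$residue_count, resstr, sep = "\t")
  }, "")
  writeLines(c("ligand_file\tpdb_id\tligand_uid\tresidue_count\tresidues",
               rows), path)
  invisible(path)
}
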