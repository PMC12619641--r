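# Ligand selection: subsumed-fragment removal, filter-mode deduplication,
# rigid-body superposition with an RMSD gate, ligand centroids and
# agglomerative centroid clustering.

#' Remove ligands subsumed by larger ligands
#'
#' A candidate is removed when its residue set is a strict subset of another
#' candidate's residues, or when it is covalently bonded (in the
#' connectivity graph) to non-protein residues outside itself — the
#' signature of an "apparent ligand" that is really a fragment of a larger,
#' incompletely enumerated molecule.
#'
#' @param pockets Pocket records (or candidates) to screen.
#' @param graph Connectivity graph of the source structure.
#' @param protein_keys Residue keys regarded as protein (bonds to these do
#'   not make a fragment).
#' @param pdb_id Used only for log lines.
#' @return List `pockets` (kept) and `log`.
#' @export
remove_subsumed_fragments <- function(pockets, graph,
                                      protein_keys = character(0),
                                      pdb_id = "") {
  log <- character(0)
  if (length(pockets) < 1L) return(list(pockets = pockets, log = log))
  sets <- lapply(pockets, function(p) p$residues$res_key)
  vnames <- igraph::V(graph)$name
  drop <- logical(length(pockets))
  for (i in seq_along(pockets)) {
    for (j in seq_along(pockets)) {
      if (i != j && all(sets[[i]] %in% sets[[j]]) &&
          length(sets[[i]]) < length(sets[[j]])) {
        drop[i] <- TRUE
        log <- c(log, sprintf("%s\tSUBSUMED\t%s is part of %s", pdb_id,
                              pockets[[i]]$ligand_uid,
                              pockets[[j]]$ligand_uid))
        break
      }
    }
    if (drop[i]) next
    # bonded to additional non-protein residues outside the candidate?
    own <- intersect(sets[[i]], vnames)
    if (length(own) > 0L) {
      nb <- igraph::V(graph)$name[unlist(igraph::adjacent_vertices(graph,
                                                                   own))]
      outside <- setdiff(nb, c(sets[[i]], protein_keys))
      if (length(outside) > 0L) {
        drop[i] <- TRUE
        log <- c(log, sprintf(
          "%s\tINCOMPLETE\t%s bonded to non-protein residue(s) %s", pdb_id,
          pockets[[i]]$ligand_uid, paste(outside, collapse = ",")))
      }
    }
  }
  list(pockets = pockets[!drop], log = log)
}

#' Deduplicate equivalent ligands (filter mode)
#'
#' Groups small-molecule copies by component code and chain ligands by
#' entity id; within each group the pocket record with the highest
#' nearby-residue count survives, ties broken by lexicographic
#' (chain, residue number) order. Surviving records are returned unchanged.
#'
#' @param pockets Pocket records from [pocket_gate()].
#' @return The selected pocket records.
#' @export
deduplicate_filter_mode <- function(pockets) {
  if (length(pockets) <= 1L) return(pockets)
  group <- vapply(pockets, function(p) {
    if (p$kind == "small_molecule") paste0("code:", p$label)
    else paste0("entity:", p$entity_id)
  }, "")
  counts <- vapply(pockets, function(p) p$residue_count, 0L)
  chain1 <- vapply(pockets, function(p) p$residues$chain[1], "")
  seq1 <- vapply(pockets, function(p) p$residues$auth_seq[1], 0L)
  keep <- logical(length(pockets))
  for (g in unique(group)) {
    idx <- which(group == g)
    ord <- idx[order(-counts[idx], chain1[idx], seq1[idx])]
    keep[ord[1]] <- TRUE
  }
  pockets[keep]
}

#' Rigid-body (Kabsch) superposition of paired coordinates
#'
#' Least-squares rotation and translation mapping `mobile` onto `fixed`
#' using singular value decomposition, with the determinant correction that
#' forbids reflections.
#'
#' @param mobile,fixed n x 3 coordinate matrices with matched rows.
#' @return List `rotation` (3 x 3, det +1), `translation` (length 3),
#'   `rmsd`, `n_matched`. Applying `x %*% t(rotation) + translation`
#'   superposes mobile coordinates onto the fixed frame.
#' @export
kabsch_superpose <- function(mobile, fixed) {
  stopifnot(ncol(mobile) == 3L, ncol(fixed) == 3L,
            nrow(mobile) == nrow(fixed))
  n <- nrow(mobile)
  if (n < 3L) stop("need at least 3 paired atoms", call. = FALSE)
  mc <- colMeans(mobile)
  fc <- colMeans(fixed)
  m0 <- sweep(mobile, 2L, mc)
  f0 <- sweep(fixed, 2L, fc)
  h <- t(m0) %*% f0
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- m0 %*% t(rot)
  rmsd <- sqrt(mean(rowSums((moved - f0)^2)))
  translation <- fc - as.vector(rot %*% mc)
  list(rotation = rot, translation = translation, rmsd = rmsd, n_matched = n)
}

# Apply a superposition to an n x 3 coordinate matrix.
apply_superposition <- function(xyz, sup) {
  sweep(xyz %*% t(sup$rotation), 2L, sup$translation, "+")
}

#' Superpose a structure onto a reference via shared CA atoms
#'
#' Pairs CA atoms by (chain, residue number) identity between the two
#' structures, optionally restricted to chains in the vicinity of at least
#' one ligand, and computes the Kabsch superposition. Structures whose CA
#' RMSD exceeds `rmsd_gate` are flagged for exclusion from cluster mode.
#'
#' @param mobile,reference `cif_structure` objects of the same query
#'   protein.
#' @param chains Optional character vector restricting the CA pairing to
#'   these chains (the pocket-retention rule); `NULL` uses all chains.
#' @param rmsd_gate RMSD threshold in Angstrom (default 3.5).
#' @return List as [kabsch_superpose()] plus `excluded` (logical) and
#'   `reason` (`NA`, `"rmsd-gate"` or `"too-few-paired-atoms"`).
#' @export
superpose_to_reference <- function(mobile, reference, chains = NULL,
                                   rmsd_gate = 3.5) {
  ca <- function(s) {
    a <- s$atoms
    sel <- a$atom_name == "CA" & a$element == "C"
    if (!is.null(chains)) sel <- sel & a$auth_chain %in% chains
    a <- a[sel, , drop = FALSE]
    key <- paste(a$auth_chain, a$auth_seq)
    a[!duplicated(key), , drop = FALSE]
  }
  am <- ca(mobile)
  ar <- ca(reference)
  shared <- intersect(paste(am$auth_chain, am$auth_seq),
                      paste(ar$auth_chain, ar$auth_seq))
  if (length(shared) < 3L) {
    return(list(rotation = diag(3), translation = c(0, 0, 0),
                rmsd = NA_real_, n_matched = length(shared),
                excluded = TRUE, reason = "too-few-paired-atoms"))
  }
  mm <- as.matrix(am[match(shared, paste(am$auth_chain, am$auth_seq)),
                     c("x", "y", "z")])
  rr <- as.matrix(ar[match(shared, paste(ar$auth_chain, ar$auth_seq)),
                     c("x", "y", "z")])
  sup <- kabsch_superpose(mm, rr)
  sup$excluded <- sup$rmsd > rmsd_gate
  sup$reason <- if (sup$excluded) "rmsd-gate" else NA_character_
  sup
}

#' Heavy-atom centroid of a ligand
#'
#' Unweighted mean of the heavy-atom coordinates of a candidate's residues,
#' optionally after a superposition transform.
#'
#' @param pocket A pocket/candidate record.
#' @param structure Its source `cif_structure`.
#' @param sup Optional superposition from [superpose_to_reference()].
#' @return Numeric length-3 vector (Angstrom).
#' @export
ligand_centroid <- function(pocket, structure, sup = NULL) {
  a <- structure$atoms
  akey <- res_key(a$auth_chain, a$auth_seq, a$ins_code)
  sel <- akey %in% pocket$residues$res_key & a$element != "H" &
    a$element != "D"
  xyz <- as.matrix(a[sel, c("x", "y", "z")])
  if (nrow(xyz) == 0L) stop("ligand has no heavy atoms", call. = FALSE)
  if (!is.null(sup)) xyz <- apply_superposition(xyz, sup)
  colMeans(xyz)
}

#' Cluster ligand centroids
#'
#' Complete-linkage agglomerative clustering on Euclidean centroid
#' distances, cut so that no two members of one cluster are further apart
#' than `threshold`. Cluster ids are assigned in ascending order of each
#' cluster's first member in the input.
#'
#' @param centroids n x 3 matrix of centroid coordinates (rownames are used
#'   as member labels when present).
#' @param threshold Linkage distance threshold in Angstrom (default 10).
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"complete"`).
#' @return Data frame `member`, `cluster_id`, `x`, `y`, `z`.
#' @export
cluster_centroids <- function(centroids, threshold = 10.0,
                              linkage = "complete") {
  centroids <- as.matrix(centroids)
  stopifnot(nrow(centroids) >= 1L, ncol(centroids) == 3L)
  labels <- rownames(centroids)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(centroids)))
  if (nrow(centroids) == 1L) {
    memb <- 1L
  } else {
    hc <- stats::hclust(stats::dist(centroids), method = linkage)
    memb <- stats::cutree(hc, h = threshold)
  }
  # relabel clusters by first appearance
  first <- tapply(seq_along(memb), memb, min)
  relabel <- rank(first)
  memb <- as.integer(relabel[as.character(memb)])
  data.frame(member = labels, cluster_id = memb,
             x = centroids[, 1], y = centroids[, 2], z = centroids[, 3],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write the run summary table
#'
#' One row per selected ligand with its source structure, file, identifier,
#' kind, resolution, query accession, query-matching chains, contacting
#' chains, nearby-residue count, flags and (in cluster mode) cluster id.
#'
#' @param rows Data frame with columns `pdb_id`, `ligand_file`,
#'   `ligand_uid`, `ligand_kind`, `resolution`, `uniprot`, `query_chains`,
#'   `contact_chains`, `n_nearby_residues`, `flags`, `cluster_id`.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_summary <- function(rows, path) {
  cols <- c("pdb_id", "ligand_file", "ligand_uid", "ligand_kind",
            "resolution", "uniprot", "query_chains", "contact_chains",
            "n_nearby_residues", "flags", "cluster_id")
  if (nrow(rows) == 0L) {
    rows <- as.data.frame(stats::setNames(rep(list(character(0)),
                                              length(cols)), cols))
  }
  missing <- setdiff(cols, names(rows))
  for (m in missing) rows[[m]] <- ""
  utils::write.table(rows[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
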