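# End-to-end orchestration: query mapping -> enumeration -> processing ->
# selection, with per-structure accounting logs and re-run skipping.

#' Build a pipeline run configuration
#'
#' Collects every tunable of the workflow with its default: the 6 A pocket
#' cutoff, the 250-entry frequent-ligand threshold, the 3-heavy-atom and
#' 10-copy size filters, the 3.5 A superposition RMSD gate, the 10 A
#' centroid clustering threshold and the peptide-rule ratios.
#'
#' @param queries Character vector of UniProt accessions.
#' @param cif_dir Directory of input `.cif` files (lowercase
#'   `<pdbid>.cif`).
#' @param out_dir Output directory (created if needed).
#' @param max_resolution Maximum acceptable resolution, Angstrom.
#' @param mode `"filter"` (one ligand per unique structure) or `"cluster"`
#'   (all ligands, grouped by superposed centroid clusters).
#' @param sifts,aliases,bird,counts,keep,exclusion,uniprot_lengths Reference
#'   table paths (see [load_reference_tables()]); optional except `sifts`.
#' @param code_map Optional TSV `long<TAB>short` mapping 5-character
#'   component codes to short codes.
#' @param pocket_cutoff,frequent_threshold,min_heavy_atoms,max_copies,
#'   rmsd_gate,cluster_threshold,alpha,beta Numeric thresholds.
#' @param seed Integer seed (recorded; the pipeline itself is
#'   deterministic).
#' @return A `ligsieve_config` list.
#' @export
ligsieve_config <- function(queries, cif_dir, out_dir,
                            max_resolution = 2.5,
                            mode = c("filter", "cluster"),
                            sifts = NULL, aliases = NULL, bird = NULL,
                            counts = NULL, keep = NULL, exclusion = NULL,
                            uniprot_lengths = NULL, code_map = NULL,
                            pocket_cutoff = 6.0, frequent_threshold = 250,
                            min_heavy_atoms = 3, max_copies = 10,
                            rmsd_gate = 3.5, cluster_threshold = 10.0,
                            alpha = 0.8, beta = 0.5, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(queries) > 0L, max_resolution > 0, pocket_cutoff > 0,
            frequent_threshold > 0, min_heavy_atoms > 0, max_copies > 0,
            rmsd_gate > 0, cluster_threshold > 0, alpha > 0, beta > 0)
  structure(list(
    queries = toupper(queries), cif_dir = cif_dir, out_dir = out_dir,
    max_resolution = max_resolution, mode = mode, sifts = sifts,
    aliases = aliases, bird = bird, counts = counts, keep = keep,
    exclusion = exclusion, uniprot_lengths = uniprot_lengths,
    code_map = code_map, pocket_cutoff = pocket_cutoff,
    frequent_threshold = frequent_threshold,
    min_heavy_atoms = min_heavy_atoms, max_copies = max_copies,
    rmsd_gate = rmsd_gate, cluster_threshold = cluster_threshold,
    alpha = alpha, beta = beta, seed = as.integer(seed)
  ), class = "ligsieve_config")
}

.log_event <- function(log, pdb_id, stage, event, detail) {
  rbind(log, data.frame(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    pdb_id = pdb_id, stage = stage, event = event, detail = detail,
    stringsAsFactors = FALSE))
}

.parse_stage_lines <- function(log, stage, lines) {
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    log <- .log_event(log, parts[1], stage, parts[2],
                      paste(parts[-(1:2)], collapse = " "))
  }
  log
}

#' Run the full ligand-extraction pipeline
#'
#' Executes, per query and per mapped structure: resolution-gated query
#' mapping, alternate-location resolution, connectivity-graph assembly,
#' candidate enumeration, the enumeration and exclusion filters, the
#' query-chain and pocket gates, subsumed-fragment removal, and the
#' selected mode's endpoint (deduplication, or superposition + centroid
#' clustering). Writes per-ligand PDB files, per-structure pocket files,
#' the summary TSV, cluster reports (cluster mode) and a TSV event log.
#' Structures already processed in `out_dir` are skipped on re-runs; an
#' error in one structure is logged and skips that structure only.
#'
#' @param config A [ligsieve_config()].
#' @return List `summary` (data frame), `log` (data frame), `clusters`
#'   (data frame or `NULL`), `mapping` (query-to-structure map), invisibly
#'   also written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ligsieve_config"))
  out <- config$out_dir
  dir.create(file.path(out, "ligands"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out, "pockets"), showWarnings = FALSE)
  dir.create(file.path(out, "processed"), showWarnings = FALSE)
  refs <- load_reference_tables(
    sifts = config$sifts, aliases = config$aliases, bird = config$bird,
    counts = config$counts, keep = config$keep,
    exclusion = config$exclusion,
    uniprot_lengths = config$uniprot_lengths)
  code_map <- character(0)
  if (!is.null(config$code_map)) {
    cm <- .read_tsv(config$code_map, c("long", "short"))
    code_map <- stats::setNames(cm$short, cm$long)
  }
  cache <- new.env(parent = emptyenv())
  resolver <- function(id) {
    if (!is.null(cache[[id]])) return(cache[[id]])
    f <- file.path(config$cif_dir, paste0(id, ".cif"))
    if (!file.exists(f)) return(NULL)
    s <- resolve_altlocs(parse_mmcif(f))
    s <- shorten_ligand_codes(s, code_map)
    cache[[id]] <- s
    s
  }
  log <- data.frame(timestamp = character(0), pdb_id = character(0),
                    stage = character(0), event = character(0),
                    detail = character(0), stringsAsFactors = FALSE)
  qm <- map_queries(config$queries, refs$sifts, refs$aliases, resolver,
                    config$max_resolution)
  for (i in seq_len(nrow(qm$log))) {
    log <- .log_event(log, qm$log$pdb_id[i], "mapping", qm$log$event[i],
                      paste(qm$log$query[i], qm$log$detail[i]))
  }

  summary_rows <- list()
  structure_meta <- list()   # per (query, pdb): pockets + contact chains
  for (ri in seq_len(nrow(qm$mapping))) {
    query <- qm$mapping$query[ri]
    pdb <- qm$mapping$pdb_id[ri]
    marker <- file.path(out, "processed", paste0(query, "_", pdb, ".done"))
    if (file.exists(marker)) {
      log <- .log_event(log, pdb, "workflow", "SKIPPED",
                        paste("already processed for", query))
      next
    }
    result <- tryCatch({
      s <- resolver(pdb)
      if (!require_query_chain(s, query, refs$aliases)) {
        log <- .log_event(log, pdb, "processing", "NO_QUERY_REF",
                          paste("query", query,
                                "absent from chain references"))
        NULL
      } else {
        graph <- build_connectivity_graph(s)
        en <- enumerate_candidates(s, graph, refs, alpha = config$alpha,
                                   beta = config$beta)
        log <- .parse_stage_lines(log, "enumeration", en$log)
        fl <- apply_enumeration_filters(
          en$candidates, refs$counts, refs$keep,
          frequent_threshold = config$frequent_threshold,
          min_heavy_atoms = config$min_heavy_atoms,
          max_copies = config$max_copies, pdb_id = pdb)
        log <- .parse_stage_lines(log, "enumeration", fl$log)
        ex <- filter_exclusion_list(fl$candidates, refs$exclusion, pdb)
        log <- .parse_stage_lines(log, "processing", ex$log)
        qch <- query_chains(s, query, refs$aliases)
        pg <- pocket_gate(ex$candidates, s, qch,
                          cutoff = config$pocket_cutoff)
        log <- .parse_stage_lines(log, "processing", pg$log)
        sb <- remove_subsumed_fragments(pg$pockets, graph,
                                        protein_keys = en$protein_keys,
                                        pdb_id = pdb)
        log <- .parse_stage_lines(log, "selection", sb$log)
        pockets <- if (config$mode == "filter") {
          deduplicate_filter_mode(sb$pockets)
        } else {
          sb$pockets
        }
        list(s = s, pockets = pockets, query = query, qch = qch)
      }
    }, error = function(e) {
      log <<- .log_event(log, pdb, "workflow", "ERROR",
                         conditionMessage(e))
      NULL
    })
    if (is.null(result)) next
    s <- result$s
    pockets <- result$pockets
    files <- character(0)
    akey <- res_key(s$atoms$auth_chain, s$atoms$auth_seq, s$atoms$ins_code)
    for (p in pockets) {
      fn <- paste0(pdb, "_", gsub("[^A-Za-z0-9_-]", "_", p$ligand_uid),
                   ".pdb")
      write_pdb_subset(s, akey %in% p$residues$res_key,
                       file.path(out, "ligands", fn))
      files[p$ligand_uid] <- fn
    }
    write_pocket_file(pockets, pdb,
                      file.path(out, "pockets", paste0(pdb, "_pockets.tsv")),
                      files)
    if (length(pockets) == 0L) {
      log <- .log_event(log, pdb, "selection", "LIGAND_FREE",
                        "no ligand survived the filters")
    }
    for (p in pockets) {
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        pdb_id = pdb,
        ligand_file = files[[p$ligand_uid]],
        ligand_uid = p$ligand_uid,
        label = p$label,
        ligand_kind = p$kind,
        resolution = effective_resolution(s),
        uniprot = result$query,
        query_chains = paste(result$qch, collapse = ","),
        contact_chains = paste(p$contact_chains, collapse = ","),
        n_nearby_residues = p$residue_count,
        flags = paste(sort(p$flags), collapse = ";"),
        cluster_id = NA_integer_,
        stringsAsFactors = FALSE)
    }
    structure_meta[[paste(query, pdb, sep = "\r")]] <-
      list(query = query, pdb = pdb, pockets = pockets,
           contact_chains = unique(unlist(lapply(pockets, function(p)
             p$contact_chains))))
    writeLines(format(Sys.time()), marker)
  }
  summary <- if (length(summary_rows)) do.call(rbind, summary_rows) else
    data.frame(pdb_id = character(0), ligand_file = character(0),
               ligand_uid = character(0), label = character(0),
               ligand_kind = character(0), resolution = numeric(0),
               uniprot = character(0), query_chains = character(0),
               contact_chains = character(0),
               n_nearby_residues = integer(0), flags = character(0),
               cluster_id = integer(0), stringsAsFactors = FALSE)

  clusters <- NULL
  if (config$mode == "cluster" && length(structure_meta) > 0L) {
    cl_rows <- list()
    for (query in unique(vapply(structure_meta, `[[`, "", "query"))) {
      metas <- Filter(function(m) m$query == query && length(m$pockets) > 0L,
                      structure_meta)
      if (length(metas) == 0L) next
      # reference = first structure in case-insensitive name order
      ord <- order(tolower(vapply(metas, `[[`, "", "pdb")))
      metas <- metas[ord]
      ref_s <- resolver(metas[[1]]$pdb)
      cents <- list()
      for (m in metas) {
        s <- resolver(m$pdb)
        sup <- if (m$pdb == metas[[1]]$pdb) {
          list(rotation = diag(3), translation = c(0, 0, 0), rmsd = 0,
               n_matched = 0L, excluded = FALSE, reason = NA_character_)
        } else {
          superpose_to_reference(s, ref_s, chains = m$contact_chains,
                                 rmsd_gate = config$rmsd_gate)
        }
        if (isTRUE(sup$excluded)) {
          log <- .log_event(log, m$pdb, "selection", "ALIGN_EXCLUDED",
                            paste0(sup$reason,
                                   if (!is.na(sup$rmsd))
                                     sprintf(" (RMSD %.2f A)", sup$rmsd)))
          drop_uids <- vapply(m$pockets, function(p) p$ligand_uid, "")
          keep_row <- !(summary$pdb_id == m$pdb &
                          summary$ligand_uid %in% drop_uids &
                          summary$uniprot == query)
          summary <- summary[keep_row, , drop = FALSE]
          next
        }
        for (p in m$pockets) {
          cents[[paste(m$pdb, p$ligand_uid, sep = "/")]] <-
            ligand_centroid(p, s, sup)
        }
      }
      if (length(cents) == 0L) next
      cmat <- do.call(rbind, cents)
      cl <- cluster_centroids(cmat, threshold = config$cluster_threshold)
      cl$query <- query
      cl_rows[[length(cl_rows) + 1L]] <- cl
      for (k in seq_len(nrow(cl))) {
        parts <- strsplit(cl$member[k], "/", fixed = TRUE)[[1]]
        hit <- summary$pdb_id == parts[1] & summary$ligand_uid == parts[2] &
          summary$uniprot == query
        summary$cluster_id[hit] <- cl$cluster_id[k]
      }
    }
    if (length(cl_rows) > 0L) {
      clusters <- do.call(rbind, cl_rows)
      utils::write.table(
        clusters[, c("query", "cluster_id", "member", "x", "y", "z")],
        file.path(out, "clusters.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    }
  }

  write_summary(summary, file.path(out, "summary.tsv"))
  utils::write.table(log, file.path(out, "log.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(summary = summary, log = log, clusters = clusters,
                 mapping = qm$mapping))
}
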