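# Reference tables: SIFTS chain-to-UniProt mapping, accession alias
# remediation, BIRD dictionary extract, per-code PDB occurrence counts,
# keep/exclusion code lists and optional UniProt sequence lengths.

.read_tsv <- function(path, cols) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          colClasses = "character")
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop("table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a SIFTS-style chain-to-UniProt table
#'
#' @param path TSV with header `pdb_id`, `chain`, `uniprot`. One row per
#'   (PDB, chain, accession) association; a chain may map to several
#'   accessions (chimeric constructs).
#' @return Data frame with lowercase `pdb_id` and uppercase `uniprot`.
#' @export
read_sifts_table <- function(path) {
  df <- .read_tsv(path, c("pdb_id", "chain", "uniprot"))
  df$pdb_id <- tolower(trimws(df$pdb_id))
  df$uniprot <- toupper(trimws(df$uniprot))
  df
}

#' Read a secondary-to-primary accession alias table
#'
#' @param path TSV with header `secondary`, `primary`.
#' @return Named character vector mapping secondary to primary accessions.
#' @export
read_alias_table <- function(path) {
  df <- .read_tsv(path, c("secondary", "primary"))
  stats::setNames(toupper(trimws(df$primary)), toupper(trimws(df$secondary)))
}

#' Remediate an accession to its primary form
#'
#' Maps outdated (secondary) accessions to their current primary accession;
#' accessions absent from the alias table are returned unchanged, so the
#' operation is idempotent.
#'
#' @param accession Character vector of accessions.
#' @param aliases Named character vector from [read_alias_table()].
#' @return Character vector of primary accessions.
#' @export
remediate_accession <- function(accession, aliases = character(0)) {
  accession <- toupper(trimws(accession))
  hit <- accession %in% names(aliases)
  accession[hit] <- unname(aliases[accession[hit]])
  accession
}

#' Read a BIRD dictionary extract
#'
#' @param path TSV with header `prd_id`, `sequence`, `pdb_ids` (comma
#'   separated). The sequence is the one-letter sequence of peptide-like
#'   reference molecules; exact matches against chain sequences confirm a
#'   chain as a ligand.
#' @return Data frame `prd_id`, `sequence`, `pdb_ids` (list column).
#' @export
read_bird_table <- function(path) {
  df <- .read_tsv(path, c("prd_id", "sequence", "pdb_ids"))
  df$sequence <- toupper(gsub("\\s", "", df$sequence))
  df$pdb_ids <- lapply(strsplit(df$pdb_ids, ","), function(x)
    tolower(trimws(x)))
  df
}

#' Read a ligand-occurrence count table
#'
#' @param path TSV with header `code`, `n_pdbs`: for every chemical component
#'   code, the number of PDB entries in which it occurs. Feeds the
#'   frequent-ligand rule.
#' @return Named integer vector keyed by uppercase code.
#' @export
read_ligand_counts <- function(path) {
  df <- .read_tsv(path, c("code", "n_pdbs"))
  stats::setNames(as.integer(df$n_pdbs), toupper(trimws(df$code)))
}

#' Read a one-code-per-line ligand code list
#'
#' Blank lines and `#` comments are ignored; codes are uppercased, trimmed
#' and deduplicated.
#'
#' @param path Plain-text file, one component code per line.
#' @return Character vector of codes.
#' @export
read_code_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  codes <- toupper(trimws(lines))
  unique(codes[nchar(codes) > 0L])
}

#' Read a UniProt sequence-length table
#'
#' @param path TSV with header `uniprot`, `length`. Used by the peptide
#'   classification rule to compare a chain's theoretical sequence against
#'   the full-length reference sequence.
#' @return Named integer vector keyed by accession.
#' @export
read_uniprot_lengths <- function(path) {
  df <- .read_tsv(path, c("uniprot", "length"))
  stats::setNames(as.integer(df$length), toupper(trimws(df$uniprot)))
}

#' Load every reference table used by the pipeline
#'
#' @param sifts,aliases,bird,counts,keep,exclusion,uniprot_lengths File
#'   paths; `aliases`, `bird`, `counts`, `keep`, `exclusion` and
#'   `uniprot_lengths` may be `NULL` for empty defaults.
#' @return List with elements `sifts`, `aliases`, `bird`, `counts`, `keep`,
#'   `exclusion`, `uniprot_lengths`. The keep and exclusion sets must be
#'   disjoint; overlap is a configuration error.
#' @export
load_reference_tables <- function(sifts = NULL, aliases = NULL, bird = NULL,
                                  counts = NULL, keep = NULL,
                                  exclusion = NULL, uniprot_lengths = NULL) {
  refs <- list(
    sifts = if (is.null(sifts)) {
      data.frame(pdb_id = character(0), chain = character(0),
                 uniprot = character(0), stringsAsFactors = FALSE)
    } else read_sifts_table(sifts),
    aliases = if (is.null(aliases)) character(0) else read_alias_table(aliases),
    bird = if (is.null(bird)) {
      data.frame(prd_id = character(0), sequence = character(0),
                 stringsAsFactors = FALSE)
    } else read_bird_table(bird),
    counts = if (is.null(counts)) integer(0) else read_ligand_counts(counts),
    keep = if (is.null(keep)) character(0) else read_code_list(keep),
    exclusion = if (is.null(exclusion)) character(0) else
      read_code_list(exclusion),
    uniprot_lengths = if (is.null(uniprot_lengths)) integer(0) else
      read_uniprot_lengths(uniprot_lengths)
  )
  overlap <- intersect(refs$keep, refs$exclusion)
  if (length(overlap) > 0L) {
    stop("code(s) present in both keep and exclusion lists: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  refs
}

#' Map UniProt queries to candidate PDB entries
#'
#' Associates each query accession with every PDB entry in which at least one
#' chain maps (after remediating secondary accessions on both sides) to the
#' query's primary accession, then applies the resolution gate: entries whose
#' effective resolution exceeds `max_resolution`, or which report no
#' resolution at all, are excluded with a logged reason. Chains of chimeric
#' constructs count as matches if any of their mapped accessions matches.
#'
#' @param queries Character vector of UniProt accessions.
#' @param sifts SIFTS table from [read_sifts_table()].
#' @param aliases Alias map from [read_alias_table()].
#' @param structures Named list of `cif_structure` objects keyed by lowercase
#'   PDB id (used for the resolution gate), or a function `pdb_id ->
#'   cif_structure`.
#' @param max_resolution Maximum acceptable resolution in Angstrom.
#' @return List with `mapping` (data frame `query`, `pdb_id`, `chains`
#'   (comma separated), `resolution`) and `log` (data frame `query`,
#'   `pdb_id`, `event`, `detail`).
#' @export
map_queries <- function(queries, sifts, aliases = character(0),
                        structures, max_resolution) {
  stopifnot(length(queries) > 0L, max_resolution > 0)
  get_structure <- if (is.function(structures)) structures else
    function(id) structures[[id]]
  queries_raw <- queries
  queries <- remediate_accession(queries, aliases)
  bad <- !grepl("^[A-Z][0-9][A-Z0-9]{4,9}$", queries)
  log <- data.frame(query = character(0), pdb_id = character(0),
                    event = character(0), detail = character(0),
                    stringsAsFactors = FALSE)
  add_log <- function(q, p, ev, det) {
    rbind(log, data.frame(query = q, pdb_id = p, event = ev, detail = det,
                          stringsAsFactors = FALSE))
  }
  for (q in queries_raw[bad]) {
    warning("accession '", q, "' does not look like a UniProt accession",
            call. = FALSE)
    log <- add_log(q, "", "ACCESSION_FORMAT", "unrecognized accession format")
  }
  sifts$uniprot_primary <- remediate_accession(sifts$uniprot, aliases)
  rows <- list()
  res_cache <- list()
  for (q in queries) {
    hit <- sifts[sifts$uniprot_primary == q, , drop = FALSE]
    for (pdb in unique(hit$pdb_id)) {
      chains <- sort(unique(hit$chain[hit$pdb_id == pdb]))
      if (is.null(res_cache[[pdb]])) {
        s <- get_structure(pdb)
        res_cache[[pdb]] <- if (is.null(s)) NA_real_ else
          effective_resolution(s)
      }
      res <- res_cache[[pdb]]
      if (is.na(res)) {
        log <- add_log(q, pdb, "EXCLUDED", "no resolution data")
      } else if (res > max_resolution) {
        log <- add_log(q, pdb, "EXCLUDED",
                       sprintf("resolution above cutoff (%.2f > %.2f)",
                               res, max_resolution))
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          query = q, pdb_id = pdb, chains = paste(chains, collapse = ","),
          resolution = res, stringsAsFactors = FALSE)
        log <- add_log(q, pdb, "MAPPED",
                       paste("chains", paste(chains, collapse = ",")))
      }
    }
  }
  mapping <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query = character(0), pdb_id = character(0),
               chains = character(0), resolution = numeric(0),
               stringsAsFactors = FALSE)
  list(mapping = mapping, log = log)
}
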