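# Precision/recall evaluation of detected vs true ligand sets, with the
# undefined-value conventions and comparator-tool label normalization.

#' Score one structure's detected ligands against the truth
#'
#' Precision is the fraction of detected ligands that are true ligands;
#' recall is the fraction of true ligands that were detected. When there are
#' no true ligands, recall is undefined (`NA`) — there is nothing to
#' retrieve; when nothing is detected, precision is undefined — reporting 0
#' would mistake a recall failure for misidentification. The one exception:
#' zero detected and zero true ligands is a perfect match, reported as
#' precision = 1 and recall = 1.
#'
#' @param detected,truth Character vectors of normalized ligand labels for
#'   the same structure (case-insensitive; duplicates ignored).
#' @return List `precision`, `recall` (each in `[0, 1]` or `NA`).
#' @export
score_pdb <- function(detected, truth) {
  d <- unique(toupper(detected))
  t_ <- unique(toupper(truth))
  inter <- length(intersect(d, t_))
  if (length(d) == 0L && length(t_) == 0L) {
    return(list(precision = 1, recall = 1))
  }
  list(
    precision = if (length(d) > 0L) inter / length(d) else NA_real_,
    recall = if (length(t_) > 0L) inter / length(t_) else NA_real_
  )
}

#' Aggregate per-structure scores
#'
#' Means are computed over defined (non-`NA`) per-structure values only;
#' counts of undefined entries are reported alongside. Standard deviations
#' use the sample (n - 1) convention. Balanced accuracy is the average of
#' mean precision and mean recall.
#'
#' @param scores Data frame with columns `pdb_id`, `precision`, `recall`
#'   (one row per structure; `NA` marks undefined values).
#' @return List `mean_precision`, `mean_recall`, `sd_precision`,
#'   `sd_recall`, `balanced_accuracy`, `n_pdbs`, `n_undefined_precision`,
#'   `n_undefined_recall`.
#' @export
aggregate_scores <- function(scores) {
  stopifnot(nrow(scores) >= 1L)
  p <- scores$precision
  r <- scores$recall
  mp <- if (all(is.na(p))) NA_real_ else mean(p, na.rm = TRUE)
  mr <- if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE)
  list(
    mean_precision = mp,
    mean_recall = mr,
    sd_precision = if (sum(!is.na(p)) > 1L) stats::sd(p, na.rm = TRUE)
                   else NA_real_,
    sd_recall = if (sum(!is.na(r)) > 1L) stats::sd(r, na.rm = TRUE)
                else NA_real_,
    balanced_accuracy = if (is.na(mp) || is.na(mr)) NA_real_
                        else (mp + mr) / 2,
    n_pdbs = nrow(scores),
    n_undefined_precision = sum(is.na(p)),
    n_undefined_recall = sum(is.na(r))
  )
}

#' Normalize a comparator tool's ligand label
#'
#' Converts tool-specific ligand naming into the common scheme used by the
#' evaluator: a bare component code for small molecules and `chain-X` for
#' chain ligands.
#'
#' * `proteinsplus`: `residueCode_chain_residueNumber`; multi-residue
#'   ligands concatenate triplets with `_`, so a label with more than three
#'   `_` is a chain ligand on the chain named by the second token.
#' * `moad`: `residueCode:chain:residueNumber`; multi-residue ligands join
#'   codes with spaces before the first `:`, so more than four characters
#'   before the first `:` marks a chain ligand.
#' * `biolip2`: small-molecule codes pass through; peptide/nucleic ligands
#'   are already named `chain-X`.
#' * `ligsieve`: this package's own labels; passed through.
#'
#' @param label Character vector of raw labels.
#' @param dialect One of `"proteinsplus"`, `"moad"`, `"biolip2"`,
#'   `"ligsieve"`.
#' @return Character vector of normalized labels.
#' @export
normalize_tool_labels <- function(label,
                                  dialect = c("ligsieve", "proteinsplus",
                                              "moad", "biolip2")) {
  dialect <- match.arg(dialect)
  one <- function(lb) {
    raw <- lb
    lb <- trimws(lb)
    if (nchar(lb) == 0L) stop("unparseable ligand label: '", raw, "'",
                              call. = FALSE)
    switch(dialect,
      ligsieve = toupper(lb),
      proteinsplus = {
        parts <- strsplit(lb, "_", fixed = TRUE)[[1]]
        n_us <- length(parts) - 1L
        if (length(parts) < 3L) {
          stop("unparseable ligand label: '", raw, "'", call. = FALSE)
        }
        if (n_us > 3L) paste0("chain-", parts[2]) else toupper(parts[1])
      },
      moad = {
        parts <- strsplit(lb, ":", fixed = TRUE)[[1]]
        if (length(parts) < 3L) {
          stop("unparseable ligand label: '", raw, "'", call. = FALSE)
        }
        if (nchar(parts[1]) > 4L) paste0("chain-", parts[2])
        else toupper(parts[1])
      },
      biolip2 = {
        if (grepl("^chain-", lb, ignore.case = TRUE)) {
          paste0("chain-", sub("^chain-", "", lb, ignore.case = TRUE))
        } else {
          toupper(lb)
        }
      }
    )
  }
  vapply(label, one, "", USE.NAMES = FALSE)
}

#' Read a ligand truth table
#'
#' @param path TSV with header `pdb_id`, `label`, `is_true_ligand` (0/1).
#'   Rows with `is_true_ligand = 0` record annotated non-ligands; only rows
#'   with 1 enter the true set. Structures with no rows (or only 0 rows) are
#'   ligand-free.
#' @return Data frame with lowercase `pdb_id`, uppercase `label`, integer
#'   `is_true_ligand`.
#' @export
read_truth_table <- function(path) {
  df <- .read_tsv(path, c("pdb_id", "label", "is_true_ligand"))
  df$pdb_id <- tolower(trimws(df$pdb_id))
  df$label <- toupper(trimws(df$label))
  df$is_true_ligand <- as.integer(df$is_true_ligand)
  df
}

#' Evaluate a prediction table against a truth table
#'
#' @param pred Data frame with columns `pdb_id` and `label` (one detected
#'   ligand per row), e.g. read from a run summary; labels are normalized
#'   via [normalize_tool_labels()].
#' @param truth Truth table from [read_truth_table()].
#' @param dialect Label dialect of `pred`.
#' @param pdb_ids Optional vector of structures to score; defaults to the
#'   union of structures in `pred` and `truth`, so structures detected as
#'   ligand-free still count.
#' @return List `per_pdb` (data frame `pdb_id`, `precision`, `recall`) and
#'   `summary` (from [aggregate_scores()]).
#' @export
evaluate_extraction <- function(pred, truth, dialect = "ligsieve",
                                pdb_ids = NULL) {
  pred$pdb_id <- tolower(pred$pdb_id)
  pred$label <- normalize_tool_labels(pred$label, dialect)
  if (is.null(pdb_ids)) {
    pdb_ids <- sort(union(unique(pred$pdb_id), unique(truth$pdb_id)))
  }
  rows <- lapply(pdb_ids, function(id) {
    d <- pred$label[pred$pdb_id == id]
    t_ <- truth$label[truth$pdb_id == id & truth$is_true_ligand == 1L]
    sc <- score_pdb(d, t_)
    data.frame(pdb_id = id, precision = sc$precision, recall = sc$recall,
               stringsAsFactors = FALSE)
  })
  per_pdb <- do.call(rbind, rows)
  list(per_pdb = per_pdb, summary = aggregate_scores(per_pdb))
}
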