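#' Read PDBx/mmCIF categories from a file
#'
#' Low-level reader returning every data category of the first data block as a
#' character data frame (one column per item, one row per loop row; key-value
#' categories yield a single row). Handles `loop_` constructs, single- and
#' double-quoted values, semicolon-delimited multi-line text fields and `#`
#' comment lines. Values `.` and `?` (mmCIF null / unknown) are converted to
#' `NA`.
#'
#' @param path Path to a PDBx/mmCIF file.
#' @return Named list of data frames, one per category, names without the
#'   leading underscore (e.g. `"atom_site"`). Column names are the item names
#'   after the dot.
#' @export
read_mmcif_categories <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read mmCIF file: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  toks <- .cif_tokenize(lines)
  .cif_assemble(toks)
}

# Tokenize mmCIF lines into a character vector of data tokens.
# Semicolon text blocks become one token; quotes are stripped.
.cif_tokenize <- function(lines) {
  tokens <- character(0)
  i <- 1L
  n <- length(lines)
  tok_re <- "('[^']*')|(\"[^\"]*\")|(\\S+)"
  while (i <= n) {
    line <- lines[[i]]
    if (startsWith(line, ";")) {
      # multi-line text field: runs until a line starting with ';'
      buf <- substring(line, 2L)
      i <- i + 1L
      while (i <= n && !startsWith(lines[[i]], ";")) {
        buf <- paste(buf, lines[[i]], sep = "\n")
        i <- i + 1L
      }
      tokens <- c(tokens, buf)
      i <- i + 1L
      next
    }
    line <- sub("^\\s+", "", line)
    if (nchar(line) == 0L || startsWith(line, "#")) {
      i <- i + 1L
      next
    }
    m <- gregexpr(tok_re, line, perl = TRUE)[[1]]
    raw <- regmatches(line, list(m))[[1]]
    for (tk in raw) {
      if (startsWith(tk, "#")) break  # trailing comment
      if ((startsWith(tk, "'") && endsWith(tk, "'") && nchar(tk) >= 2L) ||
          (startsWith(tk, "\"") && endsWith(tk, "\"") && nchar(tk) >= 2L)) {
        tk <- substring(tk, 2L, nchar(tk) - 1L)
        attr(tk, "quoted") <- TRUE
      }
      tokens <- c(tokens, tk)
    }
    i <- i + 1L
  }
  tokens
}

.cif_is_keyword <- function(tok) {
  grepl("^(data_|loop_$|stop_$|global_$|save_)", tok, ignore.case = TRUE)
}

.cif_null <- function(x) {
  x[x %in% c(".", "?")] <- NA_character_
  x
}

# Assemble tokens into per-category data frames (first data block only).
.cif_assemble <- function(tokens) {
  cats <- list()
  n <- length(tokens)
  i <- 1L
  seen_data <- FALSE
  while (i <= n) {
    tok <- tokens[[i]]
    if (grepl("^data_", tok, ignore.case = TRUE)) {
      if (seen_data) break  # first block only
      seen_data <- TRUE
      i <- i + 1L
    } else if (tolower(tok) == "loop_") {
      i <- i + 1L
      items <- character(0)
      while (i <= n && startsWith(tokens[[i]], "_")) {
        items <- c(items, tokens[[i]])
        i <- i + 1L
      }
      vals <- character(0)
      while (i <= n && !startsWith(tokens[[i]], "_") &&
             !.cif_is_keyword(tokens[[i]])) {
        vals <- c(vals, tokens[[i]])
        i <- i + 1L
      }
      if (length(items) > 0L && length(vals) %% length(items) == 0L) {
        mat <- matrix(.cif_null(vals), ncol = length(items), byrow = TRUE)
        cats <- .cif_store(cats, items, mat)
      } else if (length(items) > 0L) {
        warning("mmCIF loop for ", items[[1]],
                " has a ragged row count; category skipped")
      }
    } else if (startsWith(tok, "_")) {
      if (i + 1L <= n) {
        val <- tokens[[i + 1L]]
        cats <- .cif_store(cats, tok, matrix(.cif_null(val), ncol = 1L))
        i <- i + 2L
      } else {
        i <- i + 1L
      }
    } else {
      i <- i + 1L
    }
  }
  lapply(cats, function(df) as.data.frame(df, stringsAsFactors = FALSE))
}

# Merge a matrix of values into the category list, keyed by "_cat.item" names.
.cif_store <- function(cats, items, mat) {
  parts <- strsplit(sub("^_", "", items), ".", fixed = TRUE)
  cat_names <- vapply(parts, `[[`, "", 1L)
  item_names <- vapply(parts, function(p) {
    if (length(p) > 1L) paste(p[-1L], collapse = ".") else p[[1L]]
  }, "")
  for (cn in unique(cat_names)) {
    idx <- which(cat_names == cn)
    sub <- mat[, idx, drop = FALSE]
    colnames(sub) <- item_names[idx]
    sub <- as.data.frame(sub, stringsAsFactors = FALSE)
    if (is.null(cats[[cn]])) {
      cats[[cn]] <- sub
    } else if (nrow(cats[[cn]]) == nrow(sub)) {
      for (cl in colnames(sub)) cats[[cn]][[cl]] <- sub[[cl]]
    } else if (nrow(cats[[cn]]) == 1L && nrow(sub) == 1L) {
      cats[[cn]] <- cbind(cats[[cn]], sub)
    } else {
      cats[[cn]] <- rbind(
        cats[[cn]][intersect(colnames(cats[[cn]]), colnames(sub))],
        sub[intersect(colnames(cats[[cn]]), colnames(sub))]
      )
    }
  }
  cats
}
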