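# Position-specific scoring matrices: logistic normalization and the
# PSI-BLAST ASCII dialect.

#' Logistic normalization of PSSM scores
#'
#' Maps a raw PSI-BLAST log-odds score `x` to `1 / (1 + 2^-x)`, a value
#' strictly inside (0, 1) and strictly increasing in `x`.  A raw score of 0
#' maps to 0.5, which is also the padding value used for window positions
#' outside the sequence.
#'
#' @param raw Numeric vector of raw PSSM scores (finite).
#' @return Numeric vector of the same length, in (0, 1).
#' @export
#' @examples
#' normalize_pssm(c(-2, 0, 1))
normalize_pssm <- function(raw) {
  if (!is.numeric(raw) || any(!is.finite(raw))) {
    stop_ligbind("raw PSSM scores must be finite numbers")
  }
  1 / (1 + 2^(-raw))
}

#' Construct a PSSM object
#'
#' @param raw Numeric matrix, one row per residue, 20 columns in the
#'   canonical alphabetical residue order ([aa_alphabet()]).
#' @param sequence Residue string of the chain (same length as `nrow(raw)`),
#'   or `NULL`.
#' @param chain_id Chain identifier.
#' @return An object of class `"pssm"` with elements `chain_id`, `sequence`,
#'   `raw` and `normalized` (the logistic transform of `raw`).
#' @export
pssm <- function(raw, sequence = NULL, chain_id = "chain") {
  raw <- as.matrix(raw)
  if (ncol(raw) != 20L) {
    stop_ligbind("a PSSM must have 20 score columns, got %d", ncol(raw))
  }
  if (!is.null(sequence) && nchar(sequence) != nrow(raw)) {
    stop_ligbind("PSSM has %d rows but sequence '%s' has %d residues",
                 nrow(raw), chain_id, nchar(sequence))
  }
  colnames(raw) <- aa_alphabet()
  structure(list(chain_id = chain_id, sequence = sequence, raw = raw,
                 normalized = normalize_pssm(raw)),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM for chain '%s': %d residues x 20 scores\n",
              x$chain_id, nrow(x$raw)))
  invisible(x)
}

#' Read a PSI-BLAST ASCII scoring matrix
#'
#' Parses the matrix file PSI-BLAST emits with `-out_ascii_pssm` / `-Q`:
#' header lines, a residue-order line, then one row per residue whose first
#' 20 numeric columns are the log-odds scores.  The residue order declared in
#' the header (normally `ARNDCQEGHILKMFPSTWYV`) is respected and the columns
#' are remapped to the canonical alphabetical order.
#'
#' @param path File path.
#' @param sequence Optional chain sequence; if given, the row count must match.
#' @param chain_id Chain identifier attached to the result.
#' @return A [pssm()] object.
#' @export
read_pssm <- function(path, sequence = NULL, chain_id = NULL) {
  if (!file.exists(path)) stop_ligbind("PSSM file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (is.null(chain_id)) {
    chain_id <- sub("\\.[^.]*$", "", basename(path))
  }
  header_i <- NA_integer_
  order20 <- NULL
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) >= 20L && all(nchar(tok) == 1L) &&
        all(tok[1:20] %in% aa_alphabet())) {
      header_i <- i
      order20 <- tok[1:20]
      break
    }
  }
  if (is.na(header_i)) {
    stop_ligbind("no residue-order header line found in '%s'", path)
  }
  if (anyDuplicated(order20)) {
    stop_ligbind("residue-order header of '%s' repeats a residue", path)
  }
  rows <- list()
  res <- character()
  for (i in seq(header_i + 1L, length(lines))) {
    ln <- trimws(lines[i])
    if (ln == "") {
      if (length(rows)) break else next
    }
    tok <- strsplit(ln, "\\s+")[[1]]
    if (!grepl("^[0-9]+$", tok[1])) {
      if (length(rows)) break
      stop_ligbind("line %d of '%s' is not a PSSM data row", i, path)
    }
    vals <- suppressWarnings(as.numeric(tok[-(1:2)]))
    vals <- vals[!is.na(vals)]
    if (length(vals) < 20L) {
      stop_ligbind("line %d of '%s' has %d score columns, need 20",
                   i, path, length(vals))
    }
    rows[[length(rows) + 1L]] <- vals[1:20]
    res <- c(res, tok[2])
  }
  if (!length(rows)) stop_ligbind("no PSSM data rows in '%s'", path)
  raw <- do.call(rbind, rows)
  # remap from the file's declared order to canonical alphabetical order
  raw <- raw[, match(aa_alphabet(), order20), drop = FALSE]
  file_seq <- paste(res, collapse = "")
  if (!is.null(sequence)) {
    if (nchar(sequence) != nrow(raw)) {
      stop_ligbind("PSSM '%s' has %d rows but the sequence has %d residues",
                   path, nrow(raw), nchar(sequence))
    }
  } else {
    sequence <- file_seq
  }
  pssm(raw, sequence = sequence, chain_id = chain_id)
}

#' Write a PSSM in the PSI-BLAST ASCII dialect
#'
#' The writer emits the classic layout (two header lines, residue order
#' `ARNDCQEGHILKMFPSTWYV`, integer-formatted scores) so that files round-trip
#' through [read_pssm()].
#'
#' @param x A [pssm()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(x, path) {
  stopifnot(inherits(x, "pssm"))
  ord <- psiblast_order()
  m <- x$raw[, ord, drop = FALSE]
  res <- if (!is.null(x$sequence)) split_residues(x$sequence)
         else rep("X", nrow(m))
  out <- c(
    "",
    "Last position-specific scoring matrix computed, weighted, and scaled",
    paste0("           ", paste(sprintf("%3s", ord), collapse = " ")),
    vapply(seq_len(nrow(m)), function(i) {
      paste0(sprintf("%5d %s ", i, res[i]),
             paste(sprintf("%3d", as.integer(round(m[i, ]))), collapse = " "))
    }, character(1)),
    "")
  writeLines(out, path)
  invisible(path)
}
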