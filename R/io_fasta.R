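# FASTA / aligned-FASTA ingestion (Biostrings does the parsing; this layer
# enforces the package's contracts: unique ids, legal symbols, uppercase).

#' Read protein sequences from FASTA
#'
#' Sequences are uppercased on ingestion.  Duplicate record ids and symbols
#' outside the 21-letter alphabet are errors.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences (names are record ids, order
#'   preserved).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_ligbind("FASTA file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_ligbind(
                    "cannot parse FASTA '%s': %s", path, conditionMessage(e)))
  seqs <- toupper(as.character(set))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop_ligbind("duplicate record id '%s' in '%s'",
                 ids[duplicated(ids)][1], path)
  }
  bad <- grepl(sprintf("[^%s]", paste(aa_alphabet21(), collapse = "")), seqs)
  if (any(bad)) {
    stop_ligbind("record '%s' in '%s' contains illegal residue characters",
                 ids[bad][1], path)
  }
  names(seqs) <- ids
  seqs
}

#' Read a multiple sequence alignment (aligned FASTA)
#'
#' Like [read_fasta()] but gap characters `-` and `.` are allowed (dots are
#' normalized to dashes) and all records must have equal aligned length; a
#' ragged file is a parse error.
#'
#' @param path Aligned FASTA file path.
#' @return Named character vector of aligned sequences.
#' @export
read_msa <- function(path) {
  if (!file.exists(path)) stop_ligbind("MSA file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_ligbind(
                    "cannot parse MSA '%s': %s", path, conditionMessage(e)))
  seqs <- chartr(".", "-", toupper(as.character(set)))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop_ligbind("duplicate record id '%s' in '%s'",
                 ids[duplicated(ids)][1], path)
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) > 1L) {
    stop_ligbind("alignment '%s' is ragged: record '%s' has width %d, expected %d",
                 path, ids[widths != widths[1]][1],
                 widths[widths != widths[1]][1], widths[1])
  }
  bad <- grepl(sprintf("[^-%s]", paste(aa_alphabet21(), collapse = "")), seqs)
  if (any(bad)) {
    stop_ligbind("record '%s' in '%s' contains illegal characters",
                 ids[bad][1], path)
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
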