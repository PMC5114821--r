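# Residue alphabets and small shared utilities.

#' Amino-acid alphabets
#'
#' `aa_alphabet()` returns the 20 standard one-letter amino-acid codes in the
#' package's canonical (alphabetical) order; `aa_alphabet21()` appends `"X"`,
#' the 21st symbol used for unknown residues and for window positions that
#' fall outside the sequence.
#'
#' All file dialects (e.g. the PSI-BLAST residue order) are remapped to this
#' canonical order on ingestion.
#'
#' @return Character vector of length 20 (or 21).
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname aa_alphabet
#' @export
aa_alphabet21 <- function() c(aa_alphabet(), "X")

# column order of a PSI-BLAST ASCII matrix
psiblast_order <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Default sliding-window lengths per ligand
#'
#' Window lengths (in residues) used by the sequence-based predictor for the
#' nine ligand types it ships with, as selected by cross-validation: small
#' ligands get short windows, large ligands long ones.  `HEME` covers the
#' `HEM` and `HEC` chemical components.
#'
#' @param ligand_id Optional ligand identifier; if supplied the single window
#'   length for that ligand is returned (error if unknown).
#' @return Named integer vector, or a single integer when `ligand_id` is given.
#' @export
#' @examples
#' ligand_windows("ZN")
ligand_windows <- function(ligand_id = NULL) {
  w <- c(CU = 15L, FE = 9L, FE2 = 9L, ZN = 11L, SO4 = 13L,
         PO4 = 7L, ATP = 19L, FMN = 17L, HEME = 17L)
  if (is.null(ligand_id)) return(w)
  ligand_id <- toupper(ligand_id)
  if (!ligand_id %in% names(w)) {
    stop_ligbind(sprintf(
      "no default window length for ligand '%s'; supply one explicitly",
      ligand_id))
  }
  w[[ligand_id]]
}

# condition helpers: data/format problems signal a 'ligbind_error' so the CLI
# can map them to a dedicated exit code
stop_ligbind <- function(msg, ..., class = "ligbind_error") {
  stop(structure(class = c(class, "ligbind_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

check_window <- function(L) {
  if (length(L) != 1L || !is.finite(L) || L < 1 || L != as.integer(L) ||
      as.integer(L) %% 2L == 0L) {
    stop_ligbind("window length must be a single odd positive integer, got %s",
                 deparse(L))
  }
  as.integer(L)
}

# evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so library functions stay polite
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a stream-specific child seed, kept below 2^31
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483587)
}

split_residues <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]
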