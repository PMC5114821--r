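# Predicted structure properties: 3-state secondary structure, relative
# solvent accessibility, and backbone torsion angles.

#' Construct / validate a structure-properties table
#'
#' One record per residue: secondary-structure class (`"H"`, `"E"` or `"C"`),
#' relative solvent accessibility as a fraction in \[0, 1\], and the phi/psi
#' backbone torsions in degrees.
#'
#' @param ss Character vector of per-residue classes in `{"H","E","C"}`.
#' @param rsa Numeric vector in \[0, 1\].
#' @param phi,psi Numeric vectors in \[-180, 180\] degrees.
#' @return A `data.frame` with columns `ss`, `rsa`, `phi`, `psi`.
#' @export
structure_props <- function(ss, rsa, phi, psi) {
  n <- length(ss)
  if (length(rsa) != n || length(phi) != n || length(psi) != n) {
    stop_ligbind("structure property columns have unequal lengths")
  }
  ss <- toupper(as.character(ss))
  if (!all(ss %in% c("H", "E", "C"))) {
    stop_ligbind("secondary structure classes must be H, E or C")
  }
  if (any(!is.finite(rsa)) || any(rsa < 0 | rsa > 1)) {
    stop_ligbind("rsa values must lie in [0, 1]")
  }
  if (any(!is.finite(phi)) || any(abs(phi) > 180) ||
      any(!is.finite(psi)) || any(abs(psi) > 180)) {
    stop_ligbind("torsion angles must lie in [-180, 180] degrees")
  }
  data.frame(ss = ss, rsa = as.numeric(rsa),
             phi = as.numeric(phi), psi = as.numeric(psi))
}

#' Read a structure-properties TSV
#'
#' Expected columns: `chain_id`, `residue_index`, `ss` (H/E/C), `rsa` (0-1),
#' `phi`, `psi` (degrees).  Rows are returned sorted by residue index; for a
#' multi-chain file pass `chain_id` to select one chain.
#'
#' @param path TSV path.
#' @param chain_id Optional chain to extract.
#' @return A validated structure-properties `data.frame`.
#' @export
read_structure_props <- function(path, chain_id = NULL) {
  if (!file.exists(path)) stop_ligbind("properties file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chain_id", "residue_index", "ss", "rsa", "phi", "psi")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_ligbind("properties file '%s' lacks column(s): %s",
                 path, paste(miss, collapse = ", "))
  }
  if (!is.null(chain_id)) tab <- tab[tab$chain_id == chain_id, , drop = FALSE]
  if (!nrow(tab)) stop_ligbind("no property records%s in '%s'",
                               if (is.null(chain_id)) "" else
                                 sprintf(" for chain '%s'", chain_id), path)
  tab <- tab[order(tab$residue_index), , drop = FALSE]
  if (!identical(as.integer(tab$residue_index), seq_len(nrow(tab)))) {
    stop_ligbind("properties in '%s' do not cover residues 1..%d contiguously",
                 path, nrow(tab))
  }
  structure_props(tab$ss, tab$rsa, tab$phi, tab$psi)
}

#' Import PSIPRED .ss2 secondary structure
#'
#' Reads the PSIPRED VFORMAT `.ss2` file and returns the 3-state class per
#' residue (the `.ss2` file carries no accessibility or torsions; merge with
#' another source to build a full properties table).
#'
#' @param path `.ss2` file path.
#' @return Character vector of per-residue classes in `{"H","E","C"}`.
#' @export
read_ss2 <- function(path) {
  if (!file.exists(path)) stop_ligbind("ss2 file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & trimws(lines) != ""]
  tok <- strsplit(trimws(lines), "\\s+")
  ss <- vapply(tok, function(t) {
    if (length(t) < 3L) stop_ligbind("malformed .ss2 record: %s",
                                     paste(t, collapse = " "))
    t[3]
  }, character(1))
  ss <- toupper(ss)
  if (!all(ss %in% c("H", "E", "C", "G", "I", "B", "T", "S"))) {
    stop_ligbind("unexpected secondary structure code in '%s'", path)
  }
  # map any DSSP-style extras onto the 3 states
  ss[ss %in% c("G", "I")] <- "H"
  ss[ss == "B"] <- "E"
  ss[ss %in% c("T", "S")] <- "C"
  ss
}

# per-residue 6-slot encoding used inside the sliding window:
# one-hot secondary structure, buried/exposed flag (exposed iff rsa >= 0.25;
# the boundary value counts as exposed), torsions scaled to [-1, 1]
props_base_matrix <- function(props) {
  n <- nrow(props)
  m <- matrix(0, n, 6L,
              dimnames = list(NULL, c("ss_H", "ss_E", "ss_C",
                                      "exposed", "phi", "psi")))
  m[cbind(seq_len(n), match(props$ss, c("H", "E", "C")))] <- 1
  m[, "exposed"] <- as.numeric(props$rsa >= 0.25)
  m[, "phi"] <- props$phi / 180
  m[, "psi"] <- props$psi / 180
  m
}

#' Encode structure properties over a sliding window
#'
#' Returns the `6 * L` feature slots for the window centred at
#' `residue_index`: per window position a one-hot secondary-structure triple,
#' an exposure flag (1 iff RSA >= 0.25) and the two torsions scaled by 1/180.
#' Window positions beyond either terminus are all-zero.
#'
#' @param props Structure-properties `data.frame` (one row per residue).
#' @param residue_index 1-based residue position.
#' @param L Odd window length.
#' @return Numeric vector of length `6 * L`.
#' @export
encode_structure_props <- function(props, residue_index, L) {
  L <- check_window(L)
  n <- nrow(props)
  if (residue_index < 1L || residue_index > n) {
    stop_ligbind("residue index %d outside chain of length %d",
                 residue_index, n)
  }
  base <- props_base_matrix(props)
  h <- (L - 1L) %/% 2L
  idx <- residue_index + seq(-h, h)
  out <- matrix(0, L, 6L)
  inside <- idx >= 1L & idx <= n
  out[inside, ] <- base[idx[inside], , drop = FALSE]
  as.numeric(t(out))
}
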