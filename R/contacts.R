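# Structure-derived binding-residue definition: a residue binds a ligand if
# any of its non-hydrogen atoms lies within the van der Waals contact
# envelope d_ij <= r_i + r_j + c of any non-hydrogen ligand atom, with
# tolerance c = 0.5 A by default.

#' Default van der Waals radius table
#'
#' Bondi radii for the main-group elements plus common crystallographic
#' values for the metals that occur as protein ligands.  Override single
#' entries via [contact_params()].
#'
#' @return Named numeric vector, element symbol (uppercase) to radius in
#'   Angstrom.
#' @export
vdw_radii <- function() {
  c(H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
    P = 1.80, S = 1.80, CL = 1.75, SE = 1.90, BR = 1.85, I = 1.98,
    NA. = 2.27, K = 2.75, MG = 1.73, CA = 2.31, MN = 2.05, FE = 2.05,
    CO = 2.00, NI = 1.63, CU = 1.40, ZN = 1.39)
}

#' Contact parameters for binding-residue labeling
#'
#' @param tolerance Tolerance distance `c` in Angstrom (default 0.5).
#' @param radii Named radius table (element to Angstrom); defaults to
#'   [vdw_radii()].  Entries given here override the defaults.
#' @param on_unknown What to do for an element absent from the table:
#'   `"error"` (default) or `"default"` (use `default_radius`).
#' @param default_radius Radius used when `on_unknown = "default"`.
#' @return A list of class `"contact_params"`.
#' @export
contact_params <- function(tolerance = 0.5, radii = NULL,
                           on_unknown = c("error", "default"),
                           default_radius = 1.70) {
  if (tolerance < 0) stop_ligbind("tolerance must be >= 0")
  tab <- vdw_radii()
  names(tab)[names(tab) == "NA."] <- "NA"
  if (!is.null(radii)) {
    if (any(radii <= 0)) stop_ligbind("all radii must be positive")
    tab[toupper(names(radii))] <- radii
  }
  structure(list(tolerance = tolerance, radii = tab,
                 on_unknown = match.arg(on_unknown),
                 default_radius = default_radius),
            class = "contact_params")
}

atom_radius <- function(element, params) {
  el <- toupper(element)
  r <- unname(params$radii[el])
  unknown <- is.na(r)
  if (any(unknown)) {
    if (params$on_unknown == "error") {
      stop_ligbind("no van der Waals radius for element '%s'",
                   el[unknown][1])
    }
    r[unknown] <- params$default_radius
  }
  r
}

is_hydrogen <- function(element) toupper(element) %in% c("H", "D")

#' Binding residues by the van der Waals contact criterion
#'
#' A residue is a binding residue iff at least one of its non-hydrogen atoms
#' `i` is within `r_i + r_j + c` of some non-hydrogen ligand atom `j`
#' (Euclidean distance; the boundary counts as contact).
#'
#' @param chain_atoms Atom table for the protein chain: a `data.frame` with
#'   columns `element`, `x`, `y`, `z` and `res_index` (and optionally
#'   `ins_code`), e.g. from [read_pdb()].
#' @param ligand Either a ligand atom `data.frame` with columns `element`,
#'   `x`, `y`, `z`, or a ligand instance from [ligand_instances()].
#' @param params A [contact_params()] object.
#' @return Sorted vector of binding residue identifiers: integer residue
#'   indices, or character `"<index><ins_code>"` keys when insertion codes
#'   are present.
#' @export
binding_residues <- function(chain_atoms, ligand, params = contact_params()) {
  if (inherits(ligand, "ligand_instance")) ligand <- ligand$atoms
  ca <- chain_atoms[!is_hydrogen(chain_atoms$element), , drop = FALSE]
  la <- ligand[!is_hydrogen(ligand$element), , drop = FALSE]
  if (!nrow(la)) stop_ligbind("ligand has no non-hydrogen atoms")
  if (!nrow(ca)) return(integer(0))
  pc <- as.matrix(ca[, c("x", "y", "z")])
  pl <- as.matrix(la[, c("x", "y", "z")])
  if (any(!is.finite(pc)) || any(!is.finite(pl))) {
    stop_ligbind("non-finite atom coordinates")
  }
  ri <- atom_radius(ca$element, params)
  rj <- atom_radius(la$element, params)
  d2 <- outer(rowSums(pc^2), rowSums(pl^2), `+`) - 2 * tcrossprod(pc, pl)
  d <- sqrt(pmax(d2, 0))
  envelope <- outer(ri, rj, `+`) + params$tolerance
  hit <- rowSums(d <= envelope) > 0
  has_icode <- "ins_code" %in% names(ca) && any(trimws(ca$ins_code) != "")
  key <- if (has_icode) paste0(ca$res_index, trimws(ca$ins_code))
         else ca$res_index
  ids <- unique(key[hit])
  if (has_icode) sort(as.character(ids)) else sort(as.integer(ids))
}

#' Read a PDB-format file
#'
#' Parses `ATOM` and `HETATM` records of the first model with the standard
#' fixed-column layout.  When alternate locations are present, only the
#' highest-occupancy conformer of each atom is kept.  The structure's
#' resolution is taken from the `REMARK   2 RESOLUTION.` record when present.
#'
#' @param path PDB file path.
#' @return A list of class `"pdb"` with `atoms` (one `data.frame`, protein
#'   `ATOM` records), `hetatms` (`HETATM` records excluding waters) and
#'   `resolution` (numeric or `NA`).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop_ligbind("PDB file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  end1 <- which(startsWith(lines, "ENDMDL"))
  if (length(end1)) lines <- lines[seq_len(end1[1] - 1L)]
  resolution <- NA_real_
  rr <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rr)) {
    num <- regmatches(rr[1], regexpr("[0-9]+\\.[0-9]+", rr[1]))
    if (length(num)) resolution <- as.numeric(num)
  }
  rec <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(rec)) stop_ligbind("no ATOM/HETATM records in '%s'", path)
  fw <- function(a, b) trimws(substr(rec, a, b))
  df <- data.frame(
    record = fw(1, 6),
    atom_name = fw(13, 16),
    altloc = substr(rec, 17, 17),
    res_name = fw(18, 20),
    chain = fw(22, 22),
    res_index = as.integer(fw(23, 26)),
    ins_code = substr(rec, 27, 27),
    x = as.numeric(fw(31, 38)),
    y = as.numeric(fw(39, 46)),
    z = as.numeric(fw(47, 54)),
    occupancy = suppressWarnings(as.numeric(fw(55, 60))),
    element = fw(77, 78),
    stringsAsFactors = FALSE)
  if (anyNA(df$x) || anyNA(df$y) || anyNA(df$z)) {
    stop_ligbind("malformed coordinates in '%s'", path)
  }
  df$occupancy[is.na(df$occupancy)] <- 1
  # fall back on the atom-name convention when the element column is blank
  blank <- df$element == ""
  df$element[blank] <- substr(gsub("[0-9']", "", df$atom_name[blank]), 1, 1)
  # altloc resolution: keep the highest-occupancy conformer per atom
  alt <- df$altloc != " " & df$altloc != ""
  if (any(alt)) {
    key <- paste(df$record, df$chain, df$res_index, df$ins_code, df$atom_name)
    keep <- rep(TRUE, nrow(df))
    for (k in unique(key[alt])) {
      rows <- which(key == k)
      if (length(rows) > 1L) {
        best <- rows[which.max(df$occupancy[rows])]
        keep[setdiff(rows, best)] <- FALSE
      }
    }
    df <- df[keep, , drop = FALSE]
  }
  structure(list(
    atoms = df[df$record == "ATOM", , drop = FALSE],
    hetatms = df[df$record == "HETATM" & df$res_name != "HOH", , drop = FALSE],
    resolution = resolution), class = "pdb")
}

#' @export
print.pdb <- function(x, ...) {
  cat(sprintf("PDB structure: %d protein atoms, %d heteroatoms, resolution %s\n",
              nrow(x$atoms), nrow(x$hetatms),
              if (is.na(x$resolution)) "n/a" else
                sprintf("%.2f A", x$resolution)))
  invisible(x)
}

#' Ligand instances of a structure
#'
#' Groups the `HETATM` records matching a ligand identifier into sites (one
#' per residue name + chain + residue number).  `HEME` matches both the
#' `HEM` and `HEC` chemical components.
#'
#' @param pdb A [read_pdb()] object (or a `HETATM` `data.frame`).
#' @param ligand_id Ligand identifier, e.g. `"ZN"`, `"ATP"`, `"HEME"`.
#' @return List of `"ligand_instance"` objects (`ligand_id`, `site`,
#'   `atoms`), possibly empty.
#' @export
ligand_instances <- function(pdb, ligand_id) {
  het <- if (inherits(pdb, "pdb")) pdb$hetatms else pdb
  ids <- ligand_id_aliases(ligand_id)
  sel <- het[het$res_name %in% ids, , drop = FALSE]
  if (!nrow(sel)) return(list())
  key <- paste(sel$res_name, sel$chain, sel$res_index, sel$ins_code)
  groups <- split(sel, factor(key, levels = unique(key)))
  lapply(seq_along(groups), function(i) {
    structure(list(ligand_id = toupper(ligand_id), site = i,
                   atoms = groups[[i]]),
              class = "ligand_instance")
  })
}

# HEME is an umbrella over the HEM and HEC chemical components
ligand_id_aliases <- function(ligand_id) {
  lid <- toupper(ligand_id)
  if (lid == "HEME") c("HEM", "HEC") else lid
}

#' Import a binding-site annotation table
#'
#' Reads the interchange TSV used by curated binding-site databases: one row
#' per annotated site with columns `chain_id`, `ligand_id`, `site_index` and
#' `residues` (comma-separated 1-based indices).  Sites of the requested
#' ligand are merged per chain (union over sites, `HEME` matching `HEM` and
#' `HEC`), giving labels directly comparable with [binding_residues()]
#' output.
#'
#' @param path TSV file path.
#' @param ligand_id Ligand to extract.
#' @param chain_lengths Optional named integer vector (chain id -> length);
#'   when given, full 0/1 label vectors are returned instead of index sets.
#' @return Named list, chain id -> sorted integer vector of binding residue
#'   indices (or 0/1 vectors when `chain_lengths` is supplied).
#' @export
read_binding_annotations <- function(path, ligand_id, chain_lengths = NULL) {
  if (!file.exists(path)) stop_ligbind("annotation file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chain_id", "ligand_id", "site_index", "residues")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_ligbind("annotation file '%s' lacks column(s): %s", path,
                 paste(miss, collapse = ", "))
  }
  keep <- toupper(tab$ligand_id) %in% ligand_id_aliases(ligand_id)
  tab <- tab[keep, , drop = FALSE]
  out <- lapply(split(tab$residues, tab$chain_id), function(res) {
    sort(unique(as.integer(unlist(strsplit(res, ",", fixed = TRUE)))))
  })
  if (!is.null(chain_lengths)) {
    out <- lapply(names(out), function(cid) {
      n <- chain_lengths[[cid]]
      if (is.null(n)) stop_ligbind("no chain length for '%s'", cid)
      if (length(out[[cid]]) && max(out[[cid]]) > n) {
        stop_ligbind("annotation of chain '%s' exceeds its length %d", cid, n)
      }
      as.integer(seq_len(n) %in% out[[cid]])
    })
    names(out) <- names(split(tab$residues, tab$chain_id))
  }
  out
}
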