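# Benchmark-dataset curation: global-alignment sequence identity, greedy
# redundancy filtering, and assembly of per-ligand labeled residue datasets.

#' Global (Needleman-Wunsch) alignment and identity
#'
#' `nw_align()` computes the optimal global alignment under a simple scoring
#' scheme (match +1, mismatch 0, linear gap -1 by default) with a
#' deterministic traceback tie-break (diagonal preferred over a gap in `b`,
#' over a gap in `a`).  `nw_identity()` returns the fraction of identical
#' aligned pairs; the denominator is the full alignment length by default, or
#' the shorter sequence length.  Identity is symmetric in its arguments.
#'
#' @param a,b Non-empty residue strings.
#' @param match,mismatch,gap Scoring parameters.
#' @param denominator `"alignment"` (default) or `"shorter"`.
#' @return `nw_align()`: list with `score`, `aligned_a`, `aligned_b`,
#'   `matches`, `length`.  `nw_identity()`: a fraction in \[0, 1\].
#' @export
nw_align <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  if (!nchar(a) || !nchar(b)) stop_ligbind("cannot align an empty sequence")
  ra <- split_residues(a)
  rb <- split_residues(b)
  n <- length(ra)
  m <- length(rb)
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1L] <- gap * (0:n)
  S[1L, ] <- gap * (0:m)
  sub <- outer(ra, rb, function(u, v) ifelse(u == v, match, mismatch))
  for (i in seq_len(n)) {
    diag_row <- S[i, seq_len(m)] + sub[i, ]
    up_row <- S[i, -1L] + gap
    prev <- S[i + 1L, 1L]
    row <- numeric(m)
    for (j in seq_len(m)) {
      prev <- max(diag_row[j], up_row[j], prev + gap)
      row[j] <- prev
    }
    S[i + 1L, -1L] <- row
  }
  # traceback, diagonal > gap-in-b (up) > gap-in-a (left)
  i <- n; j <- m
  aa <- bb <- character(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L && S[i + 1L, j + 1L] == S[i, j] + sub[i, j]) {
      aa <- c(ra[i], aa); bb <- c(rb[j], bb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      aa <- c(ra[i], aa); bb <- c("-", bb); i <- i - 1L
    } else {
      aa <- c("-", aa); bb <- c(rb[j], bb); j <- j - 1L
    }
  }
  list(score = S[n + 1L, m + 1L],
       aligned_a = paste(aa, collapse = ""),
       aligned_b = paste(bb, collapse = ""),
       matches = sum(aa == bb & aa != "-"),
       length = length(aa))
}

#' @rdname nw_align
#' @export
nw_identity <- function(a, b, match = 1, mismatch = 0, gap = -1,
                        denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  al <- nw_align(a, b, match = match, mismatch = mismatch, gap = gap)
  denom <- switch(denominator,
                  alignment = al$length,
                  shorter = min(nchar(a), nchar(b)))
  al$matches / denom
}

#' Greedy redundancy filter on pairwise identity
#'
#' Walks the chains in input order and retains a chain iff its global
#' identity to every already-retained chain is at most `threshold`.  The
#' result therefore never contains a pair above the threshold, and the
#' procedure is deterministic for a given input order.
#'
#' @param chains Named character vector of sequences.
#' @param threshold Identity threshold (default 0.4).
#' @param ... Passed on to [nw_identity()].
#' @return The retained subset of `chains`, in input order.
#' @export
redundancy_filter <- function(chains, threshold = 0.4, ...) {
  keep <- character(0)
  keep_idx <- integer(0)
  for (i in seq_along(chains)) {
    ok <- TRUE
    for (s in keep) {
      if (nw_identity(chains[[i]], s, ...) > threshold) { ok <- FALSE; break }
    }
    if (ok) { keep <- c(keep, chains[[i]]); keep_idx <- c(keep_idx, i) }
  }
  chains[keep_idx]
}

#' Curation thresholds for benchmark assembly
#'
#' @param max_resolution Keep structures with resolution strictly below this
#'   (Angstrom, default 3.0).
#' @param min_length Keep chains strictly longer than this (default 50).
#' @param identity_threshold Redundancy threshold for [redundancy_filter()].
#' @return A list of class `"curation_filter"`.
#' @export
curation_filter <- function(max_resolution = 3.0, min_length = 50L,
                            identity_threshold = 0.4) {
  if (max_resolution <= 0 || min_length <= 0 || identity_threshold <= 0) {
    stop_ligbind("curation thresholds must be positive")
  }
  structure(list(max_resolution = max_resolution,
                 min_length = as.integer(min_length),
                 identity_threshold = identity_threshold),
            class = "curation_filter")
}

#' Assemble a per-residue labeled dataset for one ligand
#'
#' Applies the curation filters (resolution strictly below the cutoff, chain
#' length strictly above the cutoff, greedy redundancy filtering), then
#' labels every residue of the surviving chains: positive iff it is in van
#' der Waals contact with ANY site of the requested ligand (union over
#' sites), negative otherwise.  `HEME` merges the `HEM` and `HEC` components.
#'
#' @param complexes List of complexes; each element is a list with
#'   `chain_id`, `sequence`, `atoms` (protein atom `data.frame` with 1-based
#'   `res_index` matching the sequence), `hetatms` (ligand atom
#'   `data.frame`), and `resolution`.  A `pdb` object plus `chain_id` /
#'   `sequence` works too.
#' @param ligand_id Ligand identifier.
#' @param filter A [curation_filter()].
#' @param params A [contact_params()].
#' @return List with `data` (`data.frame`: `chain_id`, `residue_index`,
#'   `residue`, `label`) and `report` (protein / positive / negative counts).
#' @export
assemble_dataset <- function(complexes, ligand_id,
                             filter = curation_filter(),
                             params = contact_params()) {
  if (!length(complexes)) stop_ligbind("no complexes supplied")
  has_lig <- vapply(complexes, function(cx) {
    length(ligand_instances(cx$hetatms, ligand_id)) > 0L
  }, logical(1))
  if (!any(has_lig)) {
    stop_ligbind("no complex carries ligand '%s'", ligand_id)
  }
  complexes <- complexes[has_lig]
  ok <- vapply(complexes, function(cx) {
    res_ok <- !is.na(cx$resolution) && cx$resolution < filter$max_resolution
    len_ok <- nchar(cx$sequence) > filter$min_length
    res_ok && len_ok
  }, logical(1))
  complexes <- complexes[ok]
  if (!length(complexes)) {
    stop_ligbind("no complex survives the resolution/length filters",
                 class = "ligbind_empty_dataset")
  }
  seqs <- vapply(complexes, `[[`, character(1), "sequence")
  names(seqs) <- vapply(complexes, `[[`, character(1), "chain_id")
  kept <- redundancy_filter(seqs, threshold = filter$identity_threshold)
  complexes <- complexes[match(names(kept), names(seqs))]
  rows <- lapply(complexes, function(cx) {
    sites <- ligand_instances(cx$hetatms, ligand_id)
    pos <- integer(0)
    for (s in sites) {
      pos <- union(pos, binding_residues(cx$atoms, s, params))
    }
    n <- nchar(cx$sequence)
    data.frame(chain_id = cx$chain_id, residue_index = seq_len(n),
               residue = split_residues(cx$sequence),
               label = as.integer(seq_len(n) %in% pos))
  })
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  list(data = data,
       report = data.frame(ligand = toupper(ligand_id),
                           proteins = length(complexes),
                           positives = sum(data$label == 1L),
                           negatives = sum(data$label == 0L)))
}
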