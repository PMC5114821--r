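# Synthetic fixture generators.  Everything the pipeline consumes can be
# simulated with planted statistical structure, so the whole package is
# testable without external predictors or databases.

#' Specification of a planted-signal sequence fixture
#'
#' The generator emulates the statistical skeleton of a per-ligand benchmark:
#' a severe class imbalance (default 50 non-binding residues per binding
#' residue, of the order seen in curated per-ligand datasets), an
#' evolutionary signal in a few PSSM columns at binding positions (mean shift
#' `delta`, default 2.0 raw score units against a discretized-normal noise
#' floor of sd 2, the typical spread of PSI-BLAST log-odds scores), a residue
#' motif at binding positions, and low-entropy MSA columns at binding
#' positions.
#'
#' @param n_chains Number of chains (default 60).
#' @param length_range Chain length range, inclusive (default both 120).
#' @param ratio Negatives per positive (default 50).
#' @param delta Raw-score mean shift added to the signal PSSM columns at
#'   binding positions (default 2.0).
#' @param signal_cols The 3 residue columns receiving the shift.
#' @param motif_residues Residues favoured at binding positions.
#' @param motif_weight Total probability mass shared by `motif_residues` at a
#'   binding position (rest uniform).
#' @param msa_depth Sequences per alignment, target included.
#' @param conservation Probability that a non-target MSA row copies the
#'   target residue at a binding column.
#' @param gap_rate Per-cell gap probability in non-target MSA rows.
#' @param decoy_cols,decoy_residues Optional second signature (PSSM columns
#'   and motif residues of ANOTHER ligand) planted, at the same rate as the
#'   binding positions, at positions labeled negative.  This emulates chains
#'   that also bind a different ligand: a ligand-specific model must learn to
#'   reject the foreign signature, while a general-purpose model pooled over
#'   ligands is drawn to call it positive.
#' @param seed RNG seed.
#' @return A list of class `"fixture_spec"`.
#' @export
fixture_spec <- function(n_chains = 60L, length_range = c(120L, 120L),
                         ratio = 50, delta = 2.0,
                         signal_cols = c("C", "H", "D"),
                         motif_residues = c("C", "H", "D", "E"),
                         motif_weight = 0.6, msa_depth = 10L,
                         conservation = 0.9, gap_rate = 0.05,
                         decoy_cols = NULL, decoy_residues = NULL,
                         seed = 1L) {
  if (n_chains < 1L || any(length_range < 1L)) {
    stop_ligbind("all fixture counts must be positive")
  }
  if (ratio < 1) stop_ligbind("ratio must be >= 1")
  if (!all(signal_cols %in% aa_alphabet())) {
    stop_ligbind("signal columns must be standard residues")
  }
  structure(list(n_chains = as.integer(n_chains),
                 length_range = as.integer(length_range),
                 ratio = ratio, delta = delta, signal_cols = signal_cols,
                 motif_residues = motif_residues,
                 motif_weight = motif_weight,
                 msa_depth = as.integer(msa_depth),
                 conservation = conservation, gap_rate = gap_rate,
                 decoy_cols = decoy_cols, decoy_residues = decoy_residues,
                 seed = seed),
            class = "fixture_spec")
}

#' Generate a planted-signal sequence fixture
#'
#' Produces, per chain: a residue sequence, a raw PSSM, a structure-property
#' table, a small MSA (target first) and binary binding labels.  Binding
#' positions are placed uniformly at random so that the overall
#' negative:positive ratio matches the spec; at those positions the
#' designated PSSM columns are shifted by `delta`, the residue is drawn from
#' the motif distribution, and the MSA column is made low-entropy.  All other
#' structure is noise: PSSM scores from a discretized normal (sd 2),
#' uniformly random structure properties, near-uniform MSA columns.
#' Bitwise reproducible for a given seed.
#'
#' @param spec A [fixture_spec()].
#' @return Named list of chains (class `"ligbind_dataset"`); each chain is a
#'   list with `sequence`, `pssm` ([pssm()]), `props`, `msa` and `labels`.
#' @export
make_sequence_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  aa <- aa_alphabet()
  # delta is the master effect size: at delta = 0 the fixture carries no
  # planted structure at all (uniform motif, unconserved MSA columns), so
  # "no signal implies no skill" holds exactly; the stated motif and
  # conservation levels apply at the default delta = 2 and interpolate
  # linearly below it
  scale <- min(spec$delta / 2, 1)
  uniform_mass <- length(spec$motif_residues) / 20
  mw <- uniform_mass + scale * (spec$motif_weight - uniform_mass)
  conservation <- scale * spec$conservation
  motif_p <- rep((1 - mw) / (20 - length(spec$motif_residues)), 20)
  motif_p[match(spec$motif_residues, aa)] <- mw / length(spec$motif_residues)
  sig_j <- match(spec$signal_cols, aa)
  has_decoy <- !is.null(spec$decoy_cols)
  if (has_decoy) {
    dmw <- length(spec$decoy_residues) / 20 +
      scale * (spec$motif_weight - length(spec$decoy_residues) / 20)
    decoy_p <- rep((1 - dmw) / (20 - length(spec$decoy_residues)), 20)
    decoy_p[match(spec$decoy_residues, aa)] <-
      dmw / length(spec$decoy_residues)
    decoy_j <- match(spec$decoy_cols, aa)
  }
  with_seed(spec$seed, {
    lens <- if (spec$length_range[1] == spec$length_range[2]) {
      rep(spec$length_range[1], spec$n_chains)
    } else {
      sample(seq(spec$length_range[1], spec$length_range[2]),
             spec$n_chains, replace = TRUE)
    }
    total <- sum(lens)
    n_pos_total <- round(total / (spec$ratio + 1))
    if (n_pos_total < 1L) {
      stop_ligbind("imbalance ratio %g infeasible for %d total residues",
                   spec$ratio, total, class = "ligbind_invalid_spec")
    }
    # distribute binding positions uniformly over the pooled residues;
    # decoy positions (if any) are drawn disjointly at the same rate
    pick <- sample.int(total, if (has_decoy) 2L * n_pos_total else n_pos_total)
    pos_global <- sort(pick[seq_len(n_pos_total)])
    decoy_global <- if (has_decoy) sort(pick[-seq_len(n_pos_total)])
                    else integer(0)
    offsets <- cumsum(c(0L, lens[-length(lens)]))
    chains <- vector("list", spec$n_chains)
    for (ci in seq_len(spec$n_chains)) {
      n <- lens[ci]
      mine <- pos_global[pos_global > offsets[ci] &
                         pos_global <= offsets[ci] + n] - offsets[ci]
      decoys <- decoy_global[decoy_global > offsets[ci] &
                             decoy_global <= offsets[ci] + n] - offsets[ci]
      labels <- integer(n)
      labels[mine] <- 1L
      res <- sample(aa, n, replace = TRUE)
      if (length(mine)) {
        res[mine] <- sample(aa, length(mine), replace = TRUE, prob = motif_p)
      }
      if (length(decoys)) {
        res[decoys] <- sample(aa, length(decoys), replace = TRUE,
                              prob = decoy_p)
      }
      raw <- matrix(round(stats::rnorm(n * 20L, sd = 2)), n, 20L)
      raw[mine, sig_j] <- raw[mine, sig_j] + spec$delta
      if (length(decoys)) {
        raw[decoys, decoy_j] <- raw[decoys, decoy_j] + spec$delta
      }
      props <- structure_props(
        ss = sample(c("H", "E", "C"), n, replace = TRUE),
        rsa = stats::runif(n),
        phi = stats::runif(n, -180, 180),
        psi = stats::runif(n, -180, 180))
      msa <- matrix("", spec$msa_depth, n)
      msa[1, ] <- res
      for (r in seq_len(spec$msa_depth)[-1]) {
        row <- sample(aa, n, replace = TRUE)
        if (length(mine)) {
          keep <- stats::runif(length(mine)) < conservation
          row[mine[keep]] <- res[mine[keep]]
        }
        if (length(decoys)) {
          keep <- stats::runif(length(decoys)) < conservation
          row[decoys[keep]] <- res[decoys[keep]]
        }
        # gaps fall uniformly, sites included: otherwise gap-free site
        # columns would leak label information even at delta = 0
        gaps <- stats::runif(n) < spec$gap_rate
        row[gaps] <- "-"
        msa[r, ] <- row
      }
      seqs <- apply(msa, 1L, paste, collapse = "")
      names(seqs) <- c("target", paste0("hom", seq_len(spec$msa_depth - 1L)))
      sequence <- paste(res, collapse = "")
      chains[[ci]] <- list(
        sequence = sequence,
        pssm = pssm(raw, sequence = sequence,
                    chain_id = sprintf("chain%03d", ci)),
        props = props, msa = seqs, labels = labels)
    }
    names(chains) <- sprintf("chain%03d", seq_len(spec$n_chains))
    structure(chains, class = c("ligbind_dataset", "list"))
  })
}

#' Generate a toy protein-ligand complex with a known contact set
#'
#' Places one-atom (C-alpha) residues and a single ligand atom so that
#' exactly `n_contacts` chosen residues satisfy the van der Waals contact
#' criterion at the default tolerance, with at least a 0.2 A margin on both
#' sides of the envelope boundary, so floating-point noise can never flip a
#' label.  Non-contact residues sit on a line far from the ligand.
#'
#' @param n_residues Number of residues.
#' @param ligand_id Ligand identifier; its element must have a radius (falls
#'   back to carbon otherwise).
#' @param n_contacts Number of binding residues to plant (`<= n_residues`).
#' @param seed RNG seed.
#' @param path Optional path; when given, PDB-format text is written there.
#' @return List with `pdb_lines` (character vector of PDB records),
#'   `contact_residues` (the planted sorted indices), `sequence` (poly-Ala),
#'   and `params` (the [contact_params()] the margins were built for).
#' @export
make_structure_fixture <- function(n_residues, ligand_id = "ZN",
                                   n_contacts = 0L, seed = 1L, path = NULL) {
  if (n_contacts > n_residues) {
    stop_ligbind("n_contacts (%d) exceeds n_residues (%d)",
                 n_contacts, n_residues)
  }
  params <- contact_params()
  lig_el <- if (toupper(ligand_id) %in% names(params$radii))
    toupper(ligand_id) else "C"
  r_res <- params$radii[["C"]]
  r_lig <- params$radii[[lig_el]]
  envelope <- r_res + r_lig + params$tolerance
  with_seed(seed, {
    lig_center <- c(0, 60, 0)
    contact_idx <- if (n_contacts > 0L) sort(sample.int(n_residues, n_contacts))
                   else integer(0)
    coords <- matrix(0, n_residues, 3L)
    # non-contact residues: a line along x at y = 0, >= 55 A from the ligand
    coords[, 1L] <- 8 * seq_len(n_residues)
    if (n_contacts > 0L) {
      # contact residues: on a sphere of radius envelope - 0.3 A
      ang <- 2 * pi * seq_len(n_contacts) / n_contacts
      rad <- envelope - 0.3
      coords[contact_idx, ] <- cbind(rad * cos(ang) + lig_center[1],
                                     rad * sin(ang) + lig_center[2],
                                     lig_center[3])
    }
    fmt_atom <- function(serial, name, res_name, chain, res_i, xyz, el,
                         record = "ATOM") {
      sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
              record, serial, name, " ", res_name, chain, res_i, " ",
              xyz[1], xyz[2], xyz[3], 1.00, 0.00, el)
    }
    lines <- c("HEADER    SYNTHETIC TOY COMPLEX",
               "REMARK   2 RESOLUTION.    1.50 ANGSTROMS.")
    for (i in seq_len(n_residues)) {
      lines <- c(lines, fmt_atom(i, "CA", "ALA", "A", i, coords[i, ], "C"))
    }
    lig_name <- substr(toupper(ligand_id), 1, 3)
    lines <- c(lines,
               fmt_atom(n_residues + 1L, lig_el, lig_name, "A",
                        n_residues + 1L, lig_center, lig_el,
                        record = "HETATM"),
               "END")
    if (!is.null(path)) writeLines(lines, path)
    list(pdb_lines = lines, contact_residues = contact_idx,
         sequence = paste(rep("A", n_residues), collapse = ""),
         params = params)
  })
}

#' Generate mock component-method predictions
#'
#' For each method, the candidate residue set is the truth with every
#' residue's membership flipped independently with probability
#' `1 - quality`; contiguous member runs become predicted sites.  The
#' C-score grows with the method's quality and the cluster density is
#' uniform noise.
#'
#' @param labels Named list: chain id -> 0/1 label vector.
#' @param quality Named numeric vector in \[0, 1\], one entry per method.
#' @param ligand_id Ligand the sites are annotated with.
#' @param seed RNG seed.
#' @param path Optional TSV output path
#'   (format of [read_component_predictions()]).
#' @return `data.frame` of predicted sites.
#' @export
make_component_fixture <- function(labels, quality, ligand_id = "LIG",
                                   seed = 1L, path = NULL) {
  if (any(quality < 0 | quality > 1)) {
    stop_ligbind("quality values must lie in [0, 1]")
  }
  if (is.null(names(quality))) {
    names(quality) <- paste0("method", seq_along(quality))
  }
  with_seed(seed, {
    rows <- list()
    for (mi in seq_along(quality)) {
      q <- quality[mi]
      for (cid in names(labels)) {
        truth <- as.logical(labels[[cid]])
        flip <- stats::runif(length(truth)) < (1 - q)
        member <- xor(truth, flip)
        if (!any(member)) next
        runs <- rle(member)
        ends <- cumsum(runs$lengths)
        starts <- ends - runs$lengths + 1L
        si <- 0L
        for (k in which(runs$values)) {
          si <- si + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            method = names(quality)[mi], chain_id = cid, site_index = si,
            ligand_id = ligand_id,
            c_score = round(q * stats::runif(1, 0.7, 1), 4),
            cluster_density = round(stats::runif(1), 4),
            residues = paste(seq(starts[k], ends[k]), collapse = ","))
        }
      }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(method = character(0), chain_id = character(0),
                 site_index = integer(0), ligand_id = character(0),
                 c_score = numeric(0), cluster_density = numeric(0),
                 residues = character(0))
    if (!is.null(path)) {
      utils::write.table(out, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    out
  })
}
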