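# Sliding-window feature assembly for the sequence-based predictor.
#
# Layout per residue, window length L (28*L + 2 features):
#   [ L x 20 normalized PSSM | L x 6 structure | L x 2 conservation |
#     segment score vs positive PWM | segment score vs negative PWM ]
# Within each block the window position varies slowest (position -h .. +h),
# the feature within the position fastest.  Padding outside the chain:
# PSSM slots 0.5 (raw score 0), structure and conservation slots 0, and the
# 21st symbol "X" for PWM scoring.

#' Residue windows of a chain as segment strings
#'
#' Returns the length-`L` window centred at every residue, with positions
#' beyond the termini filled with the 21st symbol `"X"`.
#'
#' @param sequence Residue string.
#' @param L Odd window length.
#' @return Character matrix, `nchar(sequence)` rows x `L` columns.
#' @export
chain_segments <- function(sequence, L) {
  L <- check_window(L)
  res <- split_residues(sequence)
  n <- length(res)
  h <- (L - 1L) %/% 2L
  padded <- c(rep("X", h), res, rep("X", h))
  idx <- outer(seq_len(n), seq(0L, L - 1L), `+`)
  matrix(padded[idx], n, L)
}

# shift the rows of per-residue matrix `base` by window offsets, padding with
# `pad`; returns n x (L * ncol(base)) with window position slowest
window_stack <- function(base, L, pad) {
  n <- nrow(base)
  k <- ncol(base)
  h <- (L - 1L) %/% 2L
  out <- matrix(pad, n, L * k)
  for (w in seq_len(L)) {
    off <- w - 1L - h
    src <- seq_len(n) + off
    inside <- src >= 1L & src <= n
    out[inside, (w - 1L) * k + seq_len(k)] <- base[src[inside], , drop = FALSE]
  }
  out
}

#' Feature dimension for a window length
#'
#' @param L Odd window length.
#' @return `28 * L + 2`.
#' @export
feature_dim <- function(L) 28L * check_window(L) + 2L

#' Encode every residue of a chain as a feature matrix
#'
#' Assembles the full sliding-window representation: normalized PSSM scores,
#' structure properties, per-position conservation, and the two segment
#' conservation scores against the positive- and negative-class PWMs.
#'
#' @param sequence Residue string of the chain.
#' @param pssm A [pssm()] object for the chain.
#' @param props Structure-properties `data.frame` (one row per residue).
#' @param cons Conservation `data.frame` with columns `re`, `jsd`
#'   (one row per residue), as from [conservation_profile()].
#' @param pos_pwm,neg_pwm PWMs built from positive / negative training
#'   segments ([build_pwm()]), window length `L`.
#' @param L Odd window length.
#' @return Numeric matrix, one row per residue, `28 * L + 2` columns.
#' @export
encode_chain <- function(sequence, pssm, props, cons, pos_pwm, neg_pwm, L) {
  L <- check_window(L)
  n <- nchar(sequence)
  if (is.null(pssm)) stop_ligbind("missing feature block: pssm")
  if (!inherits(pssm, "pssm")) stop_ligbind("pssm must be a 'pssm' object")
  if (is.null(props)) stop_ligbind("missing feature block: structure properties")
  if (is.null(cons)) stop_ligbind("missing feature block: conservation profile")
  if (is.null(pos_pwm) || is.null(neg_pwm)) {
    stop_ligbind("missing feature block: class position weight matrices")
  }
  if (nrow(pssm$raw) != n) {
    stop_ligbind("pssm rows (%d) do not match chain length (%d)",
                 nrow(pssm$raw), n)
  }
  if (nrow(props) != n) {
    stop_ligbind("structure properties rows (%d) do not match chain length (%d)",
                 nrow(props), n)
  }
  if (nrow(cons) != n) {
    stop_ligbind("conservation rows (%d) do not match chain length (%d)",
                 nrow(cons), n)
  }
  if (pos_pwm$L != L || neg_pwm$L != L) {
    stop_ligbind("PWM window (%d/%d) does not match requested window %d",
                 pos_pwm$L, neg_pwm$L, L)
  }
  pssm_block <- window_stack(pssm$normalized, L, pad = 0.5)
  struct_block <- window_stack(props_base_matrix(props), L, pad = 0)
  cons_block <- window_stack(as.matrix(cons[, c("re", "jsd")]), L, pad = 0)
  segs <- chain_segments(sequence, L)
  cbind(pssm_block, struct_block, cons_block,
        score_segment(pos_pwm, segs), score_segment(neg_pwm, segs))
}

#' Encode a single residue
#'
#' Single-residue convenience wrapper around [encode_chain()]; see there for
#' the layout.
#'
#' @inheritParams encode_chain
#' @param residue_index 1-based residue position.
#' @return Numeric feature vector of length `28 * L + 2`.
#' @export
encode_residue <- function(sequence, residue_index, pssm, props, cons,
                           pos_pwm, neg_pwm, L) {
  n <- nchar(sequence)
  if (residue_index < 1L || residue_index > n) {
    stop_ligbind("residue index %d outside chain of length %d",
                 residue_index, n)
  }
  encode_chain(sequence, pssm, props, cons, pos_pwm, neg_pwm, L)[residue_index, ]
}

#' Write / read a dense feature table
#'
#' Features are stored as TSV (`chain_id`, `residue_index`, then `f1..fk`)
#' with a JSON sidecar (`<path>.layout.json`) describing the window length
#' and block layout so the file is self-describing.
#'
#' @param x Numeric feature matrix.
#' @param chain_id,residue_index Provenance columns (recycled / per row).
#' @param path Output TSV path.
#' @param L Window length recorded in the sidecar (`NA` to omit).
#' @return `path`, invisibly (writer); a list with `features`, `chain_id`,
#'   `residue_index`, `layout` (reader).
#' @export
write_features <- function(x, chain_id, residue_index, path, L = NA) {
  df <- data.frame(chain_id = chain_id, residue_index = residue_index,
                   x, check.names = FALSE)
  colnames(df) <- c("chain_id", "residue_index",
                    paste0("f", seq_len(ncol(x))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  layout <- list(version = "1", n_features = ncol(x), window = L,
                 blocks = if (is.na(L)) list() else list(
                   pssm = 20L * L, structure = 6L * L,
                   conservation = 2L * L, segment_pwm = 2L))
  jsonlite::write_json(layout, paste0(path, ".layout.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop_ligbind("feature file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  fcols <- grep("^f[0-9]+$", names(df))
  if (!length(fcols)) stop_ligbind("no feature columns in '%s'", path)
  layout_path <- paste0(path, ".layout.json")
  layout <- if (file.exists(layout_path)) {
    jsonlite::read_json(layout_path, simplifyVector = TRUE)
  } else NULL
  list(features = as.matrix(df[, fcols, drop = FALSE]),
       chain_id = as.character(df$chain_id),
       residue_index = as.integer(df$residue_index),
       layout = layout)
}
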