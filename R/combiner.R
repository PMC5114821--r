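# Consensus meta-prediction: combine the sequence-based probability with
# C-score / cluster-density features from template-based component methods,
# per ligand, through the same boosted ensemble.

#' Read component-method predictions
#'
#' TSV columns: `method`, `chain_id`, `site_index`, `ligand_id`, `c_score`,
#' `cluster_density`, `residues` (comma-separated 1-based indices).  A site
#' may list several candidate ligands separated by `;`.
#'
#' @param path TSV path.
#' @return A `data.frame` of predicted sites.
#' @export
read_component_predictions <- function(path) {
  if (!file.exists(path)) stop_ligbind("component file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("method", "chain_id", "site_index", "ligand_id", "c_score",
            "cluster_density", "residues")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_ligbind("component file '%s' lacks column(s): %s", path,
                 paste(miss, collapse = ", "))
  }
  tab
}

#' Ligand-matched candidate map of one component method
#'
#' Keeps every predicted site whose candidate-ligand list contains the
#' requested ligand (`HEME` matches `HEM` and `HEC`).  Overlapping surviving
#' sites collapse per residue by the maximum C-score; the cluster density
#' retained is the one of the site providing that maximum.  Residues covered
#' by no surviving site get `(0, 0)`.
#'
#' @param sites `data.frame` of one method's sites for one chain (columns as
#'   in [read_component_predictions()]; `residues` may also be a list of
#'   integer vectors).
#' @param ligand_id Ligand to match.
#' @param chain_length Number of residues of the chain.
#' @return Numeric matrix `chain_length` x 2 (`c_score`, `cluster_density`).
#' @export
ligand_filter_sites <- function(sites, ligand_id, chain_length) {
  out <- matrix(0, chain_length, 2L,
                dimnames = list(NULL, c("c_score", "cluster_density")))
  if (is.null(sites) || !nrow(sites)) return(out)
  targets <- ligand_id_aliases(ligand_id)
  for (k in seq_len(nrow(sites))) {
    lig <- toupper(trimws(strsplit(as.character(sites$ligand_id[k]),
                                   ";", fixed = TRUE)[[1]]))
    lig <- unlist(lapply(lig, ligand_id_aliases))
    if (!any(targets %in% lig)) next
    res <- sites$residues[[k]]
    if (is.character(res)) {
      res <- as.integer(strsplit(res, ",", fixed = TRUE)[[1]])
    }
    res <- res[res >= 1L & res <= chain_length]
    if (!length(res)) next
    better <- sites$c_score[k] > out[res, "c_score"]
    upd <- res[better]
    out[upd, "c_score"] <- sites$c_score[k]
    out[upd, "cluster_density"] <- sites$cluster_density[k]
  }
  out
}

#' Windowed combined feature encoding
#'
#' For every residue, collects over a window of length `L` the sequence-based
#' probability and the (C-score, cluster density) pair of each of the four
#' component methods: 9 values per window position, `9 * L` features per
#' residue.  Window positions beyond the termini are zero; a missing
#' component method contributes zeros for its slots (with a warning), so the
#' combiner degrades gracefully on hard targets where template-based methods
#' fail.
#'
#' @param seq_prob Numeric vector: per-residue probability of the
#'   sequence-based method.
#' @param components Named list of up to 4 candidate maps (matrices from
#'   [ligand_filter_sites()]); `NULL` entries allowed.  Order defines the
#'   layout.
#' @param L Odd window length.
#' @return Numeric matrix, `length(seq_prob)` rows x `9 * L` columns.
#' @export
encode_combined <- function(seq_prob, components, L) {
  L <- check_window(L)
  n <- length(seq_prob)
  if (length(components) != 4L) {
    stop_ligbind("expected 4 component candidate maps, got %d",
                 length(components))
  }
  base <- matrix(0, n, 9L)
  base[, 1L] <- seq_prob
  for (k in seq_len(4L)) {
    cm <- components[[k]]
    if (is.null(cm)) {
      warning(sprintf("component method %s missing; its slots are zero",
                      if (!is.null(names(components)))
                        names(components)[k] else k), call. = FALSE)
      next
    }
    if (nrow(cm) != n) {
      stop_ligbind("component %d covers %d residues, chain has %d",
                   k, nrow(cm), n)
    }
    base[, 2L * k] <- cm[, 1L]
    base[, 2L * k + 1L] <- cm[, 2L]
  }
  window_stack(base, L, pad = 0)
}

#' Train / apply the consensus combiner
#'
#' Thin delegates to the boosted ensemble on combined feature matrices; kept
#' as named entry points so the combiner surface mirrors the sequence-based
#' one.
#'
#' @param x Combined feature matrix from [encode_combined()].
#' @param y Binary labels.
#' @param config An [imbboost_config()].
#' @param ... Passed to [imbboost()] / [predict.imbboost()].
#' @return [imbboost()] model / probability vector.
#' @export
train_combiner <- function(x, y, config = imbboost_config(), ...) {
  imbboost(x, y, config = config, ...)
}

#' @rdname train_combiner
#' @param model A fitted combiner model.
#' @export
predict_combiner <- function(model, x, ...) predict(model, x, ...)
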