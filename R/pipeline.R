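# The end-to-end sequence-based pipeline: per-fold feature encoding (class
# PWMs and background frequencies are always derived from training chains
# only) feeding the boosted ensemble.

# the PSSM / structure / conservation blocks do not depend on the training
# fold; precompute them once per chain so cross-validation only recomputes
# the two PWM segment scores
prepare_dataset <- function(dataset, L) {
  L <- check_window(L)
  check_dataset(dataset)
  for (cid in names(dataset)) {
    ch <- dataset[[cid]]
    if (!is.null(ch$.L) && identical(ch$.L, L)) next
    cons <- conservation_profile(ch$msa)
    fixed <- cbind(window_stack(ch$pssm$normalized, L, pad = 0.5),
                   window_stack(props_base_matrix(ch$props), L, pad = 0),
                   window_stack(as.matrix(cons[, c("re", "jsd")]), L, pad = 0))
    dataset[[cid]]$.fixed <- fixed
    dataset[[cid]]$.segs <- chain_segments(ch$sequence, L)
    dataset[[cid]]$.L <- L
  }
  dataset
}

# class PWMs from the training chains' labeled windows
train_pwms <- function(train, L) {
  seg_list <- lapply(train, function(ch) {
    segs <- if (!is.null(ch$.segs) && identical(ch$.L, L)) ch$.segs
            else chain_segments(ch$sequence, L)
    list(pos = segs[ch$labels == 1L, , drop = FALSE],
         neg = segs[ch$labels == 0L, , drop = FALSE])
  })
  pos <- do.call(rbind, lapply(seg_list, `[[`, "pos"))
  neg <- do.call(rbind, lapply(seg_list, `[[`, "neg"))
  if (!nrow(pos) || !nrow(neg)) {
    stop_ligbind("training chains must contain both classes")
  }
  bg <- pwm_background(rbind(pos, neg))
  list(pos = build_pwm(pos, background = bg),
       neg = build_pwm(neg, background = bg),
       background = bg)
}

encode_prepared <- function(chains, L, pwms) {
  mats <- lapply(names(chains), function(cid) {
    ch <- chains[[cid]]
    if (is.null(ch$.fixed) || !identical(ch$.L, L)) {
      cons <- conservation_profile(ch$msa)
      fixed <- cbind(window_stack(ch$pssm$normalized, L, pad = 0.5),
                     window_stack(props_base_matrix(ch$props), L, pad = 0),
                     window_stack(as.matrix(cons[, c("re", "jsd")]), L,
                                  pad = 0))
      segs <- chain_segments(ch$sequence, L)
    } else {
      fixed <- ch$.fixed
      segs <- ch$.segs
    }
    cbind(fixed, score_segment(pwms$pos, segs), score_segment(pwms$neg, segs))
  })
  x <- do.call(rbind, mats)
  info <- do.call(rbind, lapply(names(chains), function(cid) {
    data.frame(chain_id = cid,
               residue_index = seq_along(chains[[cid]]$labels),
               label = chains[[cid]]$labels)
  }))
  list(x = x, info = info)
}

#' Cross-validation trainer for the sequence-based pipeline
#'
#' Returns a `function(train, test, seed)` suitable for [five_fold_cv()] /
#' [general_vs_specific()]: it builds the positive/negative PWMs and the
#' background frequencies from the training chains, encodes both partitions,
#' fits the boosted ensemble and returns out-of-fold probabilities.
#'
#' @param L Odd window length.
#' @param config An [imbboost_config()] (its `seed` is superseded by the
#'   fold seed).
#' @return A trainer closure.
#' @export
seqpred_trainer <- function(L = 7L, config = imbboost_config()) {
  L <- check_window(L)
  force(config)
  function(train, test, seed) {
    pwms <- train_pwms(train, L)
    tr <- encode_prepared(train, L, pwms)
    te <- encode_prepared(test, L, pwms)
    model <- imbboost(tr$x, tr$info$label, config = config, seed = seed)
    out <- te$info
    out$prob <- predict(model, te$x)
    out
  }
}

#' Cross-validate the sequence-based pipeline on a residue dataset
#'
#' Convenience wrapper: precomputes the fold-independent feature blocks once,
#' then runs chain-grouped cross-validation with [seqpred_trainer()].
#'
#' @param dataset Residue dataset (e.g. from [make_sequence_fixture()]).
#' @param L Odd window length.
#' @param config An [imbboost_config()].
#' @param seed Partition seed.
#' @param k Folds.
#' @return A [five_fold_cv()] result.
#' @export
seqpred_cv <- function(dataset, L = 7L, config = imbboost_config(),
                         seed = 1L, k = 5L) {
  dataset <- prepare_dataset(dataset, L)
  five_fold_cv(dataset, seqpred_trainer(L, config), seed = seed, k = k,
               threshold = config$threshold)
}

#' Train on one dataset and predict every residue of another
#'
#' Fits the full sequence-based pipeline (PWMs, background, ensemble) on
#' `train` and returns per-residue predictions for `test` in the standard
#' prediction-table layout.
#'
#' @param train,test Residue datasets.
#' @param L Odd window length.
#' @param config An [imbboost_config()].
#' @param seed Training seed.
#' @return List with `predictions` (`data.frame`: `chain_id`,
#'   `residue_index`, `residue`, `probability`, `call`), the fitted `model`
#'   and the training `pwms`.
#' @export
seqpred_run <- function(train, test = train, L = 7L,
                          config = imbboost_config(), seed = 1L) {
  train <- prepare_dataset(train, L)
  test <- prepare_dataset(test, L)
  pwms <- train_pwms(train, L)
  tr <- encode_prepared(train, L, pwms)
  te <- encode_prepared(test, L, pwms)
  model <- imbboost(tr$x, tr$info$label, config = config, seed = seed)
  prob <- predict(model, te$x)
  res <- unlist(lapply(test, function(ch) split_residues(ch$sequence)),
                use.names = FALSE)
  list(predictions = data.frame(
         chain_id = te$info$chain_id,
         residue_index = te$info$residue_index,
         residue = res,
         probability = prob,
         call = as.integer(prob >= config$threshold)),
       model = model, pwms = pwms)
}

#' Write / read a residue-dataset fixture as plain-text files
#'
#' Lays a residue dataset out on disk in the external formats the readers
#' understand: `chains.fasta`, one PSI-BLAST ASCII PSSM and one aligned
#' FASTA MSA per chain, a pooled structure-properties TSV and a labels TSV.
#'
#' @param dataset Residue dataset.
#' @param dir Output directory (created).
#' @return `dir` (writer) / the reconstructed dataset (reader).
#' @export
write_dataset <- function(dataset, dir) {
  check_dataset(dataset)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- vapply(dataset, `[[`, character(1), "sequence")
  write_fasta(seqs, file.path(dir, "chains.fasta"))
  props <- list()
  labels <- list()
  for (cid in names(dataset)) {
    ch <- dataset[[cid]]
    write_pssm(ch$pssm, file.path(dir, paste0(cid, ".pssm")))
    write_fasta(ch$msa, file.path(dir, paste0(cid, ".aln.fasta")))
    n <- length(ch$labels)
    props[[cid]] <- data.frame(chain_id = cid, residue_index = seq_len(n),
                               ch$props)
    labels[[cid]] <- data.frame(chain_id = cid, residue_index = seq_len(n),
                                residue = split_residues(ch$sequence),
                                label = ch$labels)
  }
  utils::write.table(do.call(rbind, props), file.path(dir, "props.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, labels), file.path(dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  fasta <- file.path(dir, "chains.fasta")
  if (!file.exists(fasta)) stop_ligbind("no chains.fasta under '%s'", dir)
  seqs <- read_fasta(fasta)
  labels_tab <- utils::read.delim(file.path(dir, "labels.tsv"),
                                  stringsAsFactors = FALSE)
  chains <- list()
  for (cid in names(seqs)) {
    lab <- labels_tab[labels_tab$chain_id == cid, , drop = FALSE]
    lab <- lab[order(lab$residue_index), , drop = FALSE]
    chains[[cid]] <- list(
      sequence = seqs[[cid]],
      pssm = read_pssm(file.path(dir, paste0(cid, ".pssm")),
                       sequence = seqs[[cid]], chain_id = cid),
      props = read_structure_props(file.path(dir, "props.tsv"),
                                   chain_id = cid),
      msa = read_msa(file.path(dir, paste0(cid, ".aln.fasta"))),
      labels = as.integer(lab$label))
  }
  structure(chains, class = c("ligbind_dataset", "list"))
}

#' Write a per-residue prediction table
#'
#' @param predictions `data.frame` with columns `chain_id`, `residue_index`,
#'   `residue`, `probability`, `call`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
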