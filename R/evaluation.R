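# Confusion-matrix metrics and the grouped cross-validation harness.

#' Confusion counts of binary calls
#'
#' @param labels Binary reference labels (1 = binding).
#' @param calls Binary predicted calls.
#' @return Object of class `"confusion_counts"`: named integer vector
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(labels, calls) {
  if (length(labels) != length(calls)) {
    stop_ligbind("labels and calls have different lengths (%d vs %d)",
                 length(labels), length(calls))
  }
  labels <- as.integer(labels)
  calls <- as.integer(calls)
  if (!all(labels %in% c(0L, 1L)) || !all(calls %in% c(0L, 1L))) {
    stop_ligbind("labels and calls must be 0/1")
  }
  structure(c(tp = sum(labels == 1L & calls == 1L),
              fp = sum(labels == 0L & calls == 1L),
              tn = sum(labels == 0L & calls == 0L),
              fn = sum(labels == 1L & calls == 0L)),
            class = "confusion_counts")
}

#' Accuracy, sensitivity, specificity and MCC
#'
#' Standard confusion-matrix metrics:
#' accuracy `(TP+TN)/(TP+FP+TN+FN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Degenerate denominators follow common practice: a zero factor in the MCC
#' root makes the MCC 0; sensitivity/specificity of an absent class are 0.
#'
#' @param counts A [confusion()] object, or a vector/list with components
#'   `tp`, `fp`, `tn`, `fn`.
#' @return Object of class `"ligbind_metrics"`: list with `accuracy`,
#'   `sensitivity`, `specificity`, `mcc` and the `counts`.
#' @export
#' @examples
#' metrics(confusion(c(1, 1, 0, 0), c(1, 0, 0, 1)))
metrics <- function(counts) {
  cc <- as.numeric(counts[c("tp", "fp", "tn", "fn")])
  if (anyNA(cc)) stop_ligbind("counts must provide tp, fp, tn and fn")
  tp <- cc[1]; fp <- cc[2]; tn <- cc[3]; fn <- cc[4]
  total <- tp + fp + tn + fn
  if (total <= 0) stop_ligbind("empty confusion table")
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  structure(list(
    accuracy = (tp + tn) / total,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else 0,
    specificity = if (tn + fp > 0) tn / (tn + fp) else 0,
    mcc = if (denom2 > 0) (tp * tn - fp * fn) / sqrt(denom2) else 0,
    counts = c(tp = tp, fp = fp, tn = tn, fn = fn)),
    class = "ligbind_metrics")
}

#' @export
print.ligbind_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%  MCC %.4f\n",
    100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity, x$mcc))
  invisible(x)
}

# residue dataset: named list of chains, each chain a list with at least
# `labels`; the sequence-pipeline chains also carry sequence/pssm/props/msa
check_dataset <- function(dataset) {
  if (!is.list(dataset) || is.null(names(dataset)) ||
      any(names(dataset) == "")) {
    stop_ligbind("a residue dataset must be a named list of chains")
  }
  invisible(dataset)
}

#' Chain-grouped k-fold cross-validation
#'
#' Partitions the chains (never individual residues) into `k` folds with a
#' seeded random shuffle, so all residues of a chain land in the same fold
#' and no chain appears in both train and test.  The `trainer` is called once
#' per fold and must do all of its fitting - including any training-derived
#' encodings such as class PWMs and background frequencies - from the
#' training chains only.
#'
#' @param dataset Named list of chains; each chain is a list carrying at
#'   least a `labels` vector (plus whatever the trainer needs).
#' @param trainer `function(train, test, seed)` receiving the two chain
#'   sublists and a fold-specific seed, returning a `data.frame` with columns
#'   `chain_id`, `residue_index`, `label`, `prob`.
#' @param seed Seed for the fold partition (and the per-fold trainer seeds).
#' @param k Number of folds (default 5).
#' @param threshold Probability cutoff used for the pooled binary calls.
#' @return List of class `"ligbind_cv"`: `pooled` metrics over all
#'   out-of-fold predictions, `per_fold` list of metrics, `fold_mean` of the
#'   per-fold MCCs, `predictions`, and the fold assignment.
#' @export
five_fold_cv <- function(dataset, trainer, seed = 1L, k = 5L,
                         threshold = 0.5) {
  check_dataset(dataset)
  ids <- names(dataset)
  if (length(ids) < k) {
    stop_ligbind("need at least %d chains for %d-fold cross-validation", k, k)
  }
  folds <- with_seed(seed, {
    shuffled <- sample(ids)
    split(shuffled, rep_len(seq_len(k), length(shuffled)))
  })
  preds <- vector("list", k)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test_ids <- folds[[f]]
    train_ids <- setdiff(ids, test_ids)
    out <- trainer(dataset[train_ids], dataset[test_ids],
                   child_seed(seed, f))
    need <- c("chain_id", "residue_index", "label", "prob")
    if (!all(need %in% names(out))) {
      stop_ligbind("trainer must return columns %s",
                   paste(need, collapse = ", "))
    }
    out$fold <- f
    preds[[f]] <- out
    per_fold[[f]] <- metrics(confusion(out$label,
                                       as.integer(out$prob >= threshold)))
  }
  all_pred <- do.call(rbind, preds)
  pooled <- metrics(confusion(all_pred$label,
                              as.integer(all_pred$prob >= threshold)))
  structure(list(pooled = pooled, per_fold = per_fold,
                 fold_mean = mean(vapply(per_fold, `[[`, numeric(1), "mcc")),
                 predictions = all_pred, folds = folds, k = k,
                 threshold = threshold),
            class = "ligbind_cv")
}

#' @export
print.ligbind_cv <- function(x, ...) {
  cat(sprintf("%d-fold chain-grouped cross-validation (pooled):\n", x$k))
  print(x$pooled)
  cat(sprintf("mean per-fold MCC: %.4f\n", x$fold_mean))
  invisible(x)
}

#' Ligand-specific versus general-purpose comparison
#'
#' Merges the per-ligand datasets into one pool and evaluates, under
#' identical chain-grouped folds, (a) one model trained on the merged
#' training chains ("general") and (b) one model per ligand trained on that
#' ligand's training chains only ("specific").  Metrics are reported per
#' ligand for both modes, mirroring how general-purpose and ligand-specific
#' training strategies are compared.
#'
#' @param datasets Named list (ligand id -> residue dataset as in
#'   [five_fold_cv()]).
#' @param trainer As in [five_fold_cv()].
#' @param seed Seed controlling the shared fold partitions.
#' @param k Folds.
#' @param threshold Probability cutoff.
#' @return List of class `"ligbind_gvs"`: `table` (`data.frame` with one row
#'   per ligand x mode) and the per-mode prediction frames.
#' @export
general_vs_specific <- function(datasets, trainer, seed = 1L, k = 5L,
                                threshold = 0.5) {
  if (length(datasets) < 2L) {
    stop_ligbind("need at least two ligand datasets to compare modes")
  }
  if (is.null(names(datasets))) stop_ligbind("datasets must be named by ligand")
  # one shared fold partition per ligand, drawn from the same seed
  fold_of <- list()
  for (li in seq_along(datasets)) {
    ids <- names(datasets[[li]])
    folds <- with_seed(child_seed(seed, li), {
      shuffled <- sample(ids)
      split(shuffled, rep_len(seq_len(k), length(shuffled)))
    })
    fold_of[[names(datasets)[li]]] <- folds
  }
  run_mode <- function(mode) {
    preds <- list()
    for (f in seq_len(k)) {
      if (mode == "general") {
        train <- list(); test <- list(); test_lig <- character(0)
        for (lig in names(datasets)) {
          ds <- datasets[[lig]]
          te <- fold_of[[lig]][[f]]
          tr <- setdiff(names(ds), te)
          # prefix ids so merged chains stay unique
          train <- c(train, stats::setNames(ds[tr], paste0(lig, ":", tr)))
          test <- c(test, stats::setNames(ds[te], paste0(lig, ":", te)))
          test_lig <- c(test_lig, rep(lig, length(te)))
        }
        out <- trainer(train, test, child_seed(seed, 100 + f))
        out$ligand <- sub(":.*$", "", out$chain_id)
        preds[[length(preds) + 1L]] <- out
      } else {
        for (lig in names(datasets)) {
          ds <- datasets[[lig]]
          te <- fold_of[[lig]][[f]]
          tr <- setdiff(names(ds), te)
          out <- trainer(stats::setNames(ds[tr], paste0(lig, ":", tr)),
                         stats::setNames(ds[te], paste0(lig, ":", te)),
                         child_seed(seed, 100 + f))
          out$ligand <- lig
          preds[[length(preds) + 1L]] <- out
        }
      }
    }
    do.call(rbind, preds)
  }
  gen <- run_mode("general")
  spec <- run_mode("specific")
  rows <- list()
  for (lig in names(datasets)) {
    for (mode in c("general", "specific")) {
      pr <- if (mode == "general") gen else spec
      pr <- pr[pr$ligand == lig, , drop = FALSE]
      m <- metrics(confusion(pr$label, as.integer(pr$prob >= threshold)))
      rows[[length(rows) + 1L]] <- data.frame(
        ligand = lig, mode = mode,
        accuracy = m$accuracy, sensitivity = m$sensitivity,
        specificity = m$specificity, mcc = m$mcc)
    }
  }
  structure(list(table = do.call(rbind, rows),
                 general = gen, specific = spec),
            class = "ligbind_gvs")
}

#' @export
print.ligbind_gvs <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write a per-ligand performance report
#'
#' TSV with the conventional column order: Ligand, Method, Accuracy (%),
#' Sensitivity (%), Specificity (%), MCC.
#'
#' @param table `data.frame` with columns `ligand`, `mode`/`method`,
#'   `accuracy`, `sensitivity`, `specificity`, `mcc` (fractions).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(table, path) {
  method_col <- if ("method" %in% names(table)) table$method else table$mode
  out <- data.frame(Ligand = table$ligand, Method = method_col,
                    `Accuracy (%)` = round(100 * table$accuracy, 2),
                    `Sensitivity (%)` = round(100 * table$sensitivity, 2),
                    `Specificity (%)` = round(100 * table$specificity, 2),
                    MCC = round(table$mcc, 4), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
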