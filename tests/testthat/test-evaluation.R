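test_that("confusion counting is exact, including degenerate call patterns", {
  y <- c(1, 1, 0, 0, 1)
  expect_identical(unclass(confusion(y, y))[c("fp", "fn")], c(fp = 0L, fn = 0L))
  flip <- 1 - y
  cc <- confusion(y, flip)
  expect_identical(unclass(cc)[c("tp", "tn")], c(tp = 0L, tn = 0L))
  expect_error(confusion(y, c(1, 0)), "lengths")
  set.seed(61)
  labels <- sample(0:1, 1000, replace = TRUE)
  calls <- sample(0:1, 1000, replace = TRUE)
  cc <- confusion(labels, calls)
  expect_identical(cc[["tp"]], sum(labels & calls))
  expect_identical(cc[["tn"]], sum(!labels & !calls))
  expect_identical(cc[["fp"]], sum(!labels & calls))
  expect_identical(cc[["fn"]], sum(labels & !calls))
  expect_identical(sum(cc), 1000L)
})

test_that("metric formulas match hand-worked values and handle zero denominators", {
  m <- metrics(c(tp = 3, fp = 1, tn = 5, fn = 1))
  expect_equal(m$mcc, 14 / 24, tolerance = 1e-15)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 5 / 6)
  perfect <- metrics(confusion(c(1, 0, 1), c(1, 0, 1)))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)
  # all-negative calls on mixed labels: sensitivity 0, MCC 0 by convention
  degen <- metrics(confusion(c(1, 0, 0), c(0, 0, 0)))
  expect_equal(degen$sensitivity, 0)
  expect_equal(degen$mcc, 0)
})

test_that("metrics agree with an independent formula oracle on random tables", {
  set.seed(62)
  for (k in 1:500) {
    cc <- as.list(sample(0:50, 4, replace = TRUE))
    names(cc) <- c("tp", "fp", "tn", "fn")
    if (sum(unlist(cc)) == 0) next
    got <- metrics(unlist(cc))
    want <- oracle_metrics(cc$tp, cc$fp, cc$tn, cc$fn)
    for (f in c("accuracy", "sensitivity", "specificity", "mcc")) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-12)
    }
    # accuracy is the prevalence-weighted mix of sensitivity and specificity
    npos <- cc$tp + cc$fn
    nneg <- cc$tn + cc$fp
    expect_equal(got$accuracy,
                 (npos * got$sensitivity + nneg * got$specificity) /
                   (npos + nneg), tolerance = 1e-12)
  }
})

trivial_trainer <- function(train, test, seed) {
  # memorizes nothing; returns the chain's own labels as probabilities
  do.call(rbind, lapply(names(test), function(cid) {
    data.frame(chain_id = cid,
               residue_index = seq_along(test[[cid]]$labels),
               label = test[[cid]]$labels,
               prob = ifelse(test[[cid]]$labels == 1, 0.9, 0.1))
  }))
}

test_that("cross-validation partitions chains exactly once and is seed-stable", {
  ds <- lapply(1:10, function(i) list(labels = rep(c(1L, 0L), c(2, 8))))
  names(ds) <- paste0("c", 1:10)
  cv1 <- five_fold_cv(ds, trivial_trainer, seed = 5)
  cv2 <- five_fold_cv(ds, trivial_trainer, seed = 5)
  expect_identical(cv1$folds, cv2$folds)
  tested <- sort(unname(unlist(cv1$folds)))
  expect_identical(tested, sort(names(ds)))
  expect_identical(nrow(cv1$predictions), 100L)
  # chain-level grouping: no chain id in two folds
  expect_false(any(duplicated(unlist(cv1$folds))))
  expect_equal(cv1$pooled$mcc, 1)
  expect_error(five_fold_cv(ds[1:4], trivial_trainer, seed = 1),
               "at least 5")
})

test_that("general and specific modes run under shared folds and report per ligand", {
  ds <- lapply(1:10, function(i) list(labels = rep(c(1L, 0L), c(2, 8))))
  names(ds) <- paste0("c", 1:10)
  gv <- general_vs_specific(list(A = ds, B = ds), trivial_trainer, seed = 9)
  expect_identical(nrow(gv$table), 4L)
  expect_setequal(gv$table$ligand, c("A", "B"))
  # identical ligand datasets: the two modes agree to within noise (here the
  # trainer is label-echoing, so exactly)
  expect_equal(gv$table$mcc, rep(1, 4))
  expect_error(general_vs_specific(list(A = ds), trivial_trainer, seed = 1),
               "at least two")
})

test_that("report writer emits the conventional percentage table", {
  tab <- data.frame(ligand = "ZN", mode = "specific", accuracy = 0.9901,
                    sensitivity = 0.4178, specificity = 0.9968, mcc = 0.50)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(tab, path)
  back <- read.delim(path, check.names = FALSE)
  expect_identical(names(back),
                   c("Ligand", "Method", "Accuracy (%)", "Sensitivity (%)",
                     "Specificity (%)", "MCC"))
  expect_equal(back$`Accuracy (%)`, 99.01)
})
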