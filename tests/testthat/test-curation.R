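test_that("alignment identity has the expected fixed points and symmetry", {
  expect_equal(nw_identity("ACDEFG", "ACDEFG"), 1)
  expect_equal(nw_identity("ACD", "QWE"), 0)
  set.seed(41)
  for (k in 1:5) {
    a <- rand_seq(sample(10:25, 1))
    b <- rand_seq(sample(10:25, 1))
    expect_equal(nw_identity(a, b), nw_identity(b, a), tolerance = 1e-12)
  }
  expect_error(nw_identity("", "ACD"), "empty")
})

test_that("alignment scores and identities match an independent DP oracle", {
  set.seed(42)
  for (k in 1:20) {
    a <- rand_seq(30)
    b <- rand_seq(30)
    got <- nw_align(a, b)
    want <- oracle_nw(a, b)
    expect_identical(got$score, want$score)
    expect_identical(got$matches, want$matches)
    expect_identical(got$length, want$length)
    expect_equal(nw_identity(a, b), want$matches / want$length)
  }
})

test_that("the shorter-sequence denominator is selectable", {
  a <- "ACDEFGHIKL"
  b <- "ACDEF"
  al <- nw_align(a, b)
  expect_equal(nw_identity(a, b, denominator = "shorter"),
               al$matches / 5)
  expect_equal(nw_identity(a, b, denominator = "alignment"),
               al$matches / al$length)
})

test_that("redundancy filtering removes duplicates, keeps distinct chains, and never leaves a close pair", {
  set.seed(43)
  distinct <- setNames(replicate(6, rand_seq(40)), paste0("c", 1:6))
  expect_identical(redundancy_filter(distinct, 0.9), distinct)
  dup <- c(distinct, dup1 = unname(distinct[[2]]))
  expect_identical(names(redundancy_filter(dup, 0.9)), names(distinct))
  # post-condition on a family of related sequences, checked exhaustively,
  # for the original and a shuffled input order
  base <- rand_seq(50)
  mutate <- function(s, k) {
    r <- strsplit(s, "")[[1]]
    i <- sample(length(r), k)
    r[i] <- sample(aa_alphabet(), k, replace = TRUE)
    paste(r, collapse = "")
  }
  fam <- setNames(c(base, vapply(c(2, 5, 10, 20, 35, 45), mutate,
                                 character(1), s = base)), paste0("f", 1:7))
  for (ord in list(seq_along(fam), sample(seq_along(fam)))) {
    kept <- redundancy_filter(fam[ord], 0.4)
    if (length(kept) > 1) {
      pairs <- combn(seq_along(kept), 2)
      for (p in seq_len(ncol(pairs))) {
        expect_lte(nw_identity(kept[[pairs[1, p]]], kept[[pairs[2, p]]]), 0.4)
      }
    }
  }
})

make_complex <- function(chain_id, n, contact_idx, resolution = 1.8,
                         seed = 1) {
  fx <- make_structure_fixture(n, "ZN", length(contact_idx), seed = seed)
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(fx$pdb_lines, path)
  p <- read_pdb(path)
  list(chain_id = chain_id, sequence = fx$sequence, atoms = p$atoms,
       hetatms = p$hetatms, resolution = resolution,
       truth = fx$contact_residues)
}

test_that("dataset assembly applies the strict resolution and length filters", {
  set.seed(44)
  good <- make_complex("good", 60, 1:4, resolution = 2.5, seed = 44)
  too_coarse <- make_complex("coarse", 60, 1:4, resolution = 3.2, seed = 45)
  boundary_len <- make_complex("len50", 50, 1:2, resolution = 2.0, seed = 46)
  out <- assemble_dataset(list(good, too_coarse, boundary_len), "ZN")
  expect_identical(unique(out$data$chain_id), "good")
  expect_identical(out$report$proteins, 1L)
  # resolution exactly 3.0 is excluded (strictly below)
  at_boundary <- make_complex("res3", 60, 1:4, resolution = 3.0, seed = 47)
  expect_error(assemble_dataset(list(at_boundary), "ZN"),
               class = "ligbind_empty_dataset")
})

test_that("assembled labels equal the planted contact set and partition all residues", {
  cx <- make_complex("c1", 70, 1:5, seed = 48)
  out <- assemble_dataset(list(cx), "ZN")
  expect_identical(out$data$residue_index[out$data$label == 1L], cx$truth)
  expect_identical(nrow(out$data), 70L)
  expect_identical(out$report$positives + out$report$negatives, 70L)
  expect_error(assemble_dataset(list(cx), "ATP"), "no complex carries")
})

test_that("multiple sites of the same ligand are labeled as a union", {
  cx <- make_complex("c1", 60, 1:3, seed = 49)
  # append a second ZN site next to residue 40
  r40 <- cx$atoms[cx$atoms$res_index == 40, ]
  site2 <- r40
  site2$record <- "HETATM"
  site2$res_name <- "ZN"
  site2$element <- "ZN"
  site2$res_index <- 999L
  site2$x <- site2$x + 3.0
  cx$hetatms <- rbind(cx$hetatms, site2)
  out <- assemble_dataset(list(cx), "ZN")
  pos <- out$data$residue_index[out$data$label == 1L]
  expect_true(all(cx$truth %in% pos))
  expect_true(40L %in% pos)
})
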