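atoms_df <- function(el, xyz, res_index = seq_along(el)) {
  data.frame(element = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             res_index = res_index)
}

test_that("the contact envelope boundary is inclusive at r_i + r_j + c", {
  # two carbons (r = 1.70) and c = 0.5: envelope 3.90
  chain <- atoms_df("C", matrix(c(0, 0, 0), 1), res_index = 1L)
  lig_in <- atoms_df("C", matrix(c(3.90, 0, 0), 1))
  lig_out <- atoms_df("C", matrix(c(3.91, 0, 0), 1))
  expect_identical(binding_residues(chain, lig_in), 1L)
  expect_identical(binding_residues(chain, lig_out), integer(0))
})

test_that("hydrogens are ignored and unknown elements are configurable", {
  chain <- atoms_df(c("C", "H"), rbind(c(10, 0, 0), c(3.0, 0, 0)),
                    res_index = c(1L, 1L))
  lig <- atoms_df("C", matrix(c(0, 0, 0), 1))
  # only the hydrogen is near the ligand: no contact
  expect_identical(binding_residues(chain, lig), integer(0))
  weird <- atoms_df("XQ", matrix(c(3.0, 0, 0), 1))
  expect_error(binding_residues(weird, lig), "radius")
  perm <- contact_params(on_unknown = "default")
  expect_identical(binding_residues(weird, lig, perm), 1L)
})

test_that("contact sets match a brute-force all-pairs oracle on generated complexes", {
  params <- contact_params()
  for (s in 1:50) {
    fx <- make_structure_fixture(n_residues = 12 + (s %% 9),
                                 ligand_id = c("ZN", "CU", "ATP")[1 + s %% 3],
                                 n_contacts = s %% 6, seed = s)
    path <- withr::local_tempfile(fileext = ".pdb")
    writeLines(fx$pdb_lines, path)
    p <- read_pdb(path)
    lig <- p$hetatms
    got <- binding_residues(p$atoms, lig, params)
    want <- oracle_contacts(p$atoms, lig, as.list(params$radii),
                            params$tolerance)
    expect_identical(as.integer(got), as.integer(want))
    expect_identical(as.integer(got), fx$contact_residues)
  }
})

test_that("contacts grow monotonically with tolerance and survive rigid motion", {
  fx <- make_structure_fixture(20, "ZN", 6, seed = 77)
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(fx$pdb_lines, path)
  p <- read_pdb(path)
  set0 <- binding_residues(p$atoms, p$hetatms, contact_params(tolerance = 0))
  set5 <- binding_residues(p$atoms, p$hetatms, contact_params(tolerance = 0.5))
  set2 <- binding_residues(p$atoms, p$hetatms, contact_params(tolerance = 2))
  expect_true(all(set0 %in% set5))
  expect_true(all(set5 %in% set2))
  # random rigid transforms leave the contact set unchanged
  set.seed(78)
  for (k in 1:5) {
    rot <- qr.Q(qr(matrix(rnorm(9), 3)))
    shift <- rnorm(3, sd = 20)
    move <- function(df) {
      xyz <- as.matrix(df[, c("x", "y", "z")]) %*% rot
      df$x <- xyz[, 1] + shift[1]
      df$y <- xyz[, 2] + shift[2]
      df$z <- xyz[, 3] + shift[3]
      df
    }
    expect_identical(binding_residues(move(p$atoms), move(p$hetatms)),
                     set5)
  }
})

test_that("PDB round trip preserves atoms; altlocs resolve to highest occupancy", {
  fx <- make_structure_fixture(15, "ZN", 3, seed = 79)
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(fx$pdb_lines, path)
  p <- read_pdb(path)
  expect_identical(nrow(p$atoms), 15L)
  expect_identical(nrow(p$hetatms), 1L)
  expect_equal(p$resolution, 1.5)
  # hand-built altloc pair: B has the higher occupancy and must win
  alt <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.60  0.00           C",
    "HETATM    3 ZN   ZN  A   2       9.000   0.000   3.000  1.00  0.00          ZN",
    "END")
  path2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(alt, path2)
  p2 <- read_pdb(path2)
  expect_identical(nrow(p2$atoms), 1L)
  expect_equal(p2$atoms$x, 9.0)
  expect_identical(binding_residues(p2$atoms, p2$hetatms), 1L)
})

test_that("ligand instances group HETATM records per site and honour HEME aliasing", {
  lines <- c(
    "HETATM    1 FE   HEM A 201       0.000   0.000   0.000  1.00  0.00          FE",
    "HETATM    2  C1  HEM A 201       1.000   0.000   0.000  1.00  0.00           C",
    "HETATM    3 FE   HEC B 301       9.000   9.000   9.000  1.00  0.00          FE",
    "HETATM    4 ZN   ZN  A 401       5.000   5.000   5.000  1.00  0.00          ZN",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  p <- read_pdb(path)
  heme <- ligand_instances(p, "HEME")
  expect_length(heme, 2L)
  expect_identical(nrow(heme[[1]]$atoms), 2L)
  expect_length(ligand_instances(p, "ZN"), 1L)
  expect_length(ligand_instances(p, "ATP"), 0L)
})

test_that("annotation tables import as per-chain label sets with HEME aliasing", {
  tab <- data.frame(chain_id = c("a", "a", "b", "b"),
                    ligand_id = c("ZN", "ZN", "HEM", "ATP"),
                    site_index = c(1, 2, 1, 1),
                    residues = c("3,5", "5,9", "2,4", "7"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  zn <- read_binding_annotations(path, "ZN")
  expect_identical(zn, list(a = c(3L, 5L, 9L)))
  heme <- read_binding_annotations(path, "HEME",
                                   chain_lengths = c(a = 10L, b = 6L))
  expect_identical(heme$b, c(0L, 1L, 0L, 1L, 0L, 0L))
  bad <- data.frame(chain_id = "a", residues = "1")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_binding_annotations(path2, "ZN"), "lacks column")
})
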