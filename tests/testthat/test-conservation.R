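test_that("RE and JSD vanish for background-identical columns and peak for point masses", {
  # a column whose distribution equals the uniform background: both scores 0;
  # the alignment is one sequence per residue type (target's A included)
  aln <- setNames(aa_alphabet(), paste0("s", 1:20))
  names(aln)[1] <- "target"
  prof <- conservation_profile(aln)
  expect_equal(prof$re, 0, tolerance = 1e-12)
  expect_equal(prof$jsd, 0, tolerance = 1e-12)
  # single-symbol column vs uniform background: RE = log2(20)
  point <- setNames(rep("W", 12), c("target", paste0("h", 1:11)))
  prof2 <- conservation_profile(point)
  expect_equal(prof2$re, log2(20), tolerance = 1e-12)
  expect_gt(prof2$jsd, 0.5)
})

test_that("JSD scales linearly with the non-gap fraction of a column", {
  full <- setNames(rep("H", 10), c("t", paste0("h", 1:9)))
  half <- setNames(c(rep("H", 5), rep("-", 5)), c("t", paste0("h", 1:9)))
  j_full <- conservation_profile(full)$jsd
  j_half <- conservation_profile(half)$jsd
  expect_equal(j_half, j_full / 2, tolerance = 1e-12)
})

test_that("JSD matches an independent two-KL oracle on random columns", {
  set.seed(21)
  aa <- aa_alphabet()
  q <- rep(1 / 20, 20)
  for (i in 1:100) {
    depth <- sample(5:40, 1)
    col <- sample(aa, depth, replace = TRUE,
                  prob = as.vector(rexp(20) + 0.05))
    aln <- setNames(col, c("t", paste0("h", seq_len(depth - 1))))
    got <- conservation_profile(aln)$jsd
    p <- tabulate(match(col, aa), 20) / depth
    expect_equal(got, oracle_jsd(p, q), tolerance = 1e-10)
  }
})

test_that("columns where the target is gapped are dropped; errors are informative", {
  aln <- c(t = "A-C", h1 = "AAC", h2 = "CC-")
  prof <- conservation_profile(aln)
  expect_identical(nrow(prof), 2L)            # target has 2 residues
  expect_error(conservation_profile(character(0)), "empty")
  expect_error(conservation_profile(c(t = "AC", h = "ACD")), "unequal")
  expect_error(conservation_profile(c(t = "AC"), background = rep(1, 20)),
               "summing to 1")
})

test_that("PWM frequencies obey the pseudocount identity and worked example", {
  # one segment with 'A' at a position: p = (1 + 1/21) / (1 + 1) = 11/21
  pw <- build_pwm("A")
  expect_equal(unname(pw$p[1, "A"]), 11 / 21, tolerance = 1e-15)
  # sum_j p_ij = 1 exactly, for random segment sets (1000 positions total)
  set.seed(22)
  for (rep in 1:50) {
    L <- 20
    nseg <- sample(1:30, 1)
    segs <- matrix(sample(aa_alphabet21(), nseg * L, replace = TRUE), nseg, L)
    pw <- build_pwm(segs)
    expect_equal(rowSums(pw$p), rep(1, L), tolerance = 1e-12)
    expect_equal(apply(pw$m, 1, min), pw$m_min, ignore_attr = TRUE)
    expect_equal(apply(pw$m, 1, max), pw$m_max, ignore_attr = TRUE)
  }
})

test_that("log-odds are zero when a frequency matches the background", {
  # background uniform 1/21 and counts arranged so p_ij == 1/21 cannot be
  # engineered exactly; instead use the pooled background of the segments
  # themselves: a PWM built from one segment repeated has p = background at
  # every position of that residue
  segs <- rep("ACD", 5)
  bg <- pwm_background(segs)
  pw <- build_pwm(segs, background = bg)
  # each position is a point mass identical across segments; p_i,sym and the
  # pooled background share the count structure only for the uniform case,
  # so instead check the identity m = log(p / bg) entrywise
  expect_equal(pw$m, log(sweep(pw$p, 2, bg, "/")), ignore_attr = TRUE)
  expect_error(build_pwm(character(0)), "empty")
  expect_error(build_pwm("ACD", background = c(rep(0, 20), 1)), "positive")
})

test_that("segment scores hit 1 at the arg-max segment, 0 at the arg-min, and stay in [0,1]", {
  set.seed(23)
  a21 <- aa_alphabet21()
  for (rep in 1:100) {
    L <- sample(c(3L, 5L, 7L), 1)
    segs <- matrix(sample(a21, 12 * L, replace = TRUE), 12, L)
    pw <- build_pwm(segs)
    best <- paste(a21[apply(pw$m, 1, which.max)], collapse = "")
    worst <- paste(a21[apply(pw$m, 1, which.min)], collapse = "")
    expect_equal(score_segment(pw, best), 1, tolerance = 1e-12)
    expect_equal(score_segment(pw, worst), 0, tolerance = 1e-12)
    s <- score_segment(pw, paste(sample(a21, L, TRUE), collapse = ""))
    expect_true(s >= 0 && s <= 1)
  }
})

test_that("segment scoring matches a per-position summation oracle and is shift invariant", {
  set.seed(24)
  for (rep in 1:20) {
    L <- 7L
    segs <- matrix(sample(aa_alphabet21(), 15 * L, replace = TRUE), 15, L)
    pw <- build_pwm(segs)
    seg <- sample(aa_alphabet21(), L, replace = TRUE)
    idx <- match(seg, aa_alphabet21())
    num <- sum(vapply(seq_len(L), function(i) pw$m[i, idx[i]] - pw$m_min[i],
                      numeric(1)))
    den <- sum(pw$m_max - pw$m_min)
    expect_equal(score_segment(pw, paste(seg, collapse = "")), num / den,
                 tolerance = 1e-12)
    # adding a constant to one PWM row cancels in the score
    pw2 <- pw
    pw2$m[3, ] <- pw2$m[3, ] + 4.2
    pw2$m_min[3] <- pw2$m_min[3] + 4.2
    pw2$m_max[3] <- pw2$m_max[3] + 4.2
    expect_equal(score_segment(pw2, paste(seg, collapse = "")),
                 score_segment(pw, paste(seg, collapse = "")),
                 tolerance = 1e-12)
  }
})

test_that("degenerate PWMs score 0.5 and bad symbols error", {
  pw <- build_pwm("AAA")
  pw$m[] <- 1; pw$m_min[] <- 1; pw$m_max[] <- 1   # all-constant columns
  expect_equal(score_segment(pw, "ACD"), 0.5)
  pw2 <- build_pwm(c("AC", "CD"))
  expect_error(score_segment(pw2, "A?"), "alphabet")
  expect_error(score_segment(pw2, "ACD"), "does not match")
})
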