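# Evolutionary conservation: per-position relative entropy and
# Jensen-Shannon divergence from an MSA, and the position-weight-matrix
# segment conservation score.

entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Per-position conservation scores from an MSA
#'
#' The first sequence of the alignment is the target; alignment columns where
#' the target has a gap are dropped, so the result has one row per target
#' residue.  For each column the observed amino-acid distribution `p` (gaps
#' and `X` excluded) is compared with a background `q`:
#' the relative entropy `RE = sum p * log2(p/q)` and the Jensen-Shannon
#' divergence `JSD = H((p+q)/2) - (H(p)+H(q))/2` (base-2 logs, so JSD lies in
#' \[0, 1\]).  The JSD is down-weighted by the fraction of non-residue symbols
#' in the column, so heavily gapped columns cannot look conserved.
#'
#' @param msa Named character vector of aligned sequences (equal widths),
#'   target first, as from [read_msa()].
#' @param background Background amino-acid frequencies: numeric vector of
#'   length 20 in the canonical residue order, positive, summing to 1.
#'   Default uniform.
#' @return A `data.frame` with columns `re` and `jsd`, one row per target
#'   residue.
#' @export
conservation_profile <- function(msa, background = NULL) {
  if (length(msa) < 1L) stop_ligbind("empty MSA")
  widths <- nchar(msa)
  if (length(unique(widths)) != 1L) stop_ligbind("MSA sequences have unequal widths")
  if (is.null(background)) background <- rep(1 / 20, 20)
  if (length(background) != 20L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6) {
    stop_ligbind("background must be 20 positive frequencies summing to 1")
  }
  aa <- aa_alphabet()
  mat <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  keep <- mat[1, ] %in% aa_alphabet21()   # drop target-gap columns
  mat <- mat[, keep, drop = FALSE]
  nres <- ncol(mat)
  if (nres == 0L) stop_ligbind("target sequence of the MSA is all gaps")
  q <- background
  hq <- entropy2(q)
  re <- jsd <- numeric(nres)
  depth <- nrow(mat)
  for (cc in seq_len(nres)) {
    col <- mat[, cc]
    obs <- col[col %in% aa]
    gap_frac <- 1 - length(obs) / depth
    if (!length(obs)) next                # all-gap column scores 0
    p <- tabulate(match(obs, aa), nbins = 20L) / length(obs)
    nz <- p > 0
    re[cc] <- sum(p[nz] * log2(p[nz] / q[nz]))
    m <- (p + q) / 2
    jsd[cc] <- (entropy2(m) - (entropy2(p) + hq) / 2) * (1 - gap_frac)
  }
  data.frame(re = re, jsd = pmin(pmax(jsd, 0), 1))
}

segments_as_matrix <- function(segments) {
  if (is.matrix(segments)) return(segments)
  if (is.character(segments)) {
    return(do.call(rbind, strsplit(segments, "", fixed = TRUE)))
  }
  stop_ligbind("segments must be a character matrix or vector of strings")
}

#' Pooled background frequencies over the 21-letter alphabet
#'
#' Estimates the background residue frequencies from training segments pooled
#' over all window positions and both classes, with the same square-root
#' pseudocount used for the position-specific frequencies, so no symbol gets
#' zero mass.  Falls back to uniform 1/21 when no segments are given.
#'
#' @param segments Character matrix of segments (rows) by window positions
#'   (columns), or vector of equal-length strings; symbols from
#'   [aa_alphabet21()].
#' @return Numeric vector of 21 positive frequencies summing to 1.
#' @export
pwm_background <- function(segments = NULL) {
  a21 <- aa_alphabet21()
  if (is.null(segments) || !length(segments)) {
    p <- rep(1 / 21, 21)
    names(p) <- a21
    return(p)
  }
  m <- segments_as_matrix(segments)
  sym <- as.vector(m)
  if (!all(sym %in% a21)) {
    stop_ligbind("segment symbol outside the 21-letter alphabet: '%s'",
                 setdiff(sym, a21)[1])
  }
  n <- tabulate(match(sym, a21), nbins = 21L)
  N <- sum(n)
  p <- (n + sqrt(N) / 21) / (N + sqrt(N))
  names(p) <- a21
  p
}

#' Build a position weight matrix from training segments
#'
#' For window position `i` and symbol `j` the pseudocounted frequency is
#' `p_ij = (n_ij + sqrt(N_i)/21) / (N_i + sqrt(N_i))`, where `n_ij` counts
#' occurrences of symbol `j` at position `i` and `N_i` counts all symbols at
#' position `i`; the matrix entry is the natural log-odds against the
#' background, `m_ij = log(p_ij / P_j)`.  Per-position minima and maxima are
#' cached for segment scoring.  The 21st symbol `X` stands for unknown
#' residues and window positions outside the chain.
#'
#' @param segments Character matrix or vector of equal-length strings over
#'   [aa_alphabet21()].
#' @param background 21 positive frequencies summing to 1 (default: pooled
#'   estimate from `segments` via [pwm_background()]).
#' @return An object of class `"pwm"`: window length `L`, log-odds matrix `m`
#'   (`L` x 21), `m_min`, `m_max`, `p` (the frequencies) and `background`.
#' @export
build_pwm <- function(segments, background = NULL) {
  if (!length(segments)) {
    stop_ligbind("cannot build a PWM from an empty segment list")
  }
  m <- segments_as_matrix(segments)
  if (!nrow(m)) stop_ligbind("cannot build a PWM from an empty segment list")
  a21 <- aa_alphabet21()
  if (!all(m %in% a21)) {
    stop_ligbind("segment symbol outside the 21-letter alphabet: '%s'",
                 setdiff(as.vector(m), a21)[1])
  }
  if (is.null(background)) background <- pwm_background(m)
  if (length(background) != 21L || any(background <= 0)) {
    stop_ligbind("background must be 21 strictly positive frequencies")
  }
  if (abs(sum(background) - 1) > 1e-6) {
    stop_ligbind("background frequencies must sum to 1")
  }
  L <- ncol(m)
  counts <- t(apply(m, 2L, function(col) tabulate(match(col, a21), nbins = 21L)))
  Ni <- rowSums(counts)                      # == nrow(m) at every position
  p <- (counts + sqrt(Ni) / 21) / (Ni + sqrt(Ni))
  dimnames(p) <- list(NULL, a21)
  lw <- log(sweep(p, 2L, background, "/"))
  dimnames(lw) <- list(NULL, a21)
  structure(list(L = L, m = lw,
                 m_min = apply(lw, 1L, min), m_max = apply(lw, 1L, max),
                 p = p, background = background),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("position weight matrix: window %d x 21 symbols\n", x$L))
  invisible(x)
}

#' Segment conservation score against a PWM
#'
#' Scores a residue window by how typical it is of the PWM's training class:
#' `S = sum_i (m[i, s_i] - m_min[i]) / sum_i (m_max[i] - m_min[i])`, which is
#' 1 when the segment picks the arg-max symbol at every position and 0 for
#' the arg-min everywhere.  A degenerate PWM whose columns are all constant
#' (zero denominator) scores 0.5.
#'
#' @param pwm A [build_pwm()] object.
#' @param segment Residue window: a string of length `L`, or a character
#'   matrix / vector of strings to score several segments at once.
#' @return Numeric vector of scores in \[0, 1\].
#' @export
score_segment <- function(pwm, segment) {
  stopifnot(inherits(pwm, "pwm"))
  m <- segments_as_matrix(segment)
  if (ncol(m) != pwm$L) {
    stop_ligbind("segment length %d does not match PWM window %d",
                 ncol(m), pwm$L)
  }
  idx <- match(m, aa_alphabet21())
  if (anyNA(idx)) {
    stop_ligbind("segment symbol outside the 21-letter alphabet: '%s'",
                 as.vector(m)[which(is.na(idx))[1]])
  }
  idx <- matrix(idx, nrow(m), ncol(m))
  denom <- sum(pwm$m_max - pwm$m_min)
  if (denom <= 1e-12) return(rep(0.5, nrow(m)))
  num <- vapply(seq_len(nrow(m)), function(r) {
    sum(pwm$m[cbind(seq_len(pwm$L), idx[r, ])] - pwm$m_min)
  }, numeric(1))
  num / denom
}
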