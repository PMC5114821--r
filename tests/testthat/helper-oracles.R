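# Independent oracles used by the property and acceptance tests.  These are
# deliberately written from the definitions, not by calling the package
# implementation paths they check.

# random residue string
rand_seq <- function(n) paste(sample(aa_alphabet(), n, replace = TRUE),
                              collapse = "")

# --- Needleman-Wunsch oracle: memoized recursion over (i, j), same scoring
# and the same deterministic tie precedence (diagonal, then gap in b, then
# gap in a) as the documented package convention -------------------------
oracle_nw <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  ra <- strsplit(a, "")[[1]]
  rb <- strsplit(b, "")[[1]]
  n <- length(ra); m <- length(rb)
  memo <- array(NA_real_, dim = c(n + 1, m + 1))
  sc <- function(i, j) {
    if (!is.na(memo[i + 1, j + 1])) return(memo[i + 1, j + 1])
    v <- if (i == 0 && j == 0) 0
    else if (i == 0) sc(0, j - 1) + gap
    else if (j == 0) sc(i - 1, 0) + gap
    else max(sc(i - 1, j - 1) + (if (ra[i] == rb[j]) match else mismatch),
             sc(i - 1, j) + gap,
             sc(i, j - 1) + gap)
    memo[i + 1, j + 1] <<- v
    v
  }
  score <- sc(n, m)
  # traceback with the same precedence
  i <- n; j <- m; matches <- 0L; len <- 0L
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        sc(i, j) == sc(i - 1, j - 1) +
          (if (ra[i] == rb[j]) match else mismatch)) {
      if (ra[i] == rb[j]) matches <- matches + 1L
      i <- i - 1; j <- j - 1
    } else if (i > 0 && sc(i, j) == sc(i - 1, j) + gap) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    len <- len + 1L
  }
  list(score = score, matches = matches, length = len)
}

# --- all-pairs brute-force contact oracle over Eq.-style envelope -------
oracle_contacts <- function(chain_atoms, ligand_atoms, radii, tol) {
  ca <- chain_atoms[!toupper(chain_atoms$element) %in% c("H", "D"), ]
  la <- ligand_atoms[!toupper(ligand_atoms$element) %in% c("H", "D"), ]
  hits <- integer(0)
  for (i in seq_len(nrow(ca))) {
    for (j in seq_len(nrow(la))) {
      d <- sqrt((ca$x[i] - la$x[j])^2 + (ca$y[i] - la$y[j])^2 +
                (ca$z[i] - la$z[j])^2)
      if (d <= radii[[toupper(ca$element[i])]] +
              radii[[toupper(la$element[j])]] + tol) {
        hits <- c(hits, ca$res_index[i])
      }
    }
  }
  sort(unique(hits))
}

# --- confusion-metric formula oracle, straight from the definitions -----
oracle_metrics <- function(tp, fp, tn, fn) {
  tp <- as.double(tp); fp <- as.double(fp)
  tn <- as.double(tn); fn <- as.double(fn)
  total <- tp + fp + tn + fn
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  list(accuracy = (tp + tn) / total,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else 0,
       specificity = if (tn + fp > 0) tn / (tn + fp) else 0,
       mcc = if (den > 0) (tp * tn - fp * fn) / den else 0)
}

# --- JSD oracle via the two-KL form: JSD = (KL(p||m) + KL(q||m)) / 2 ----
oracle_jsd <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

# --- classical AdaBoost reference trace, sampling-free: every round uses
# the full pool, positives keep fixed uniform weights, negatives follow the
# textbook update exp(alpha_t) with no damping ---------------------------
oracle_adaboost_trace <- function(x, y, rounds, gamma, cost) {
  pos <- which(y == 1L); neg <- which(y == 0L)
  w <- rep(1 / length(neg), length(neg))
  eps_tr <- alpha_tr <- numeric(0)
  for (t in seq_len(rounds)) {
    base <- ligbind:::klr_fit(x, y, gamma = gamma, cost = cost,
                              max_centers = nrow(x))
    p <- ligbind:::klr_prob(base, x)
    mis_pos <- p[pos] < 0.5
    mis_neg <- p[neg] >= 0.5
    eps <- 0.5 * mean(mis_pos) + 0.5 * sum(w * mis_neg)
    if (eps >= 0.5) break
    eps <- max(eps, 1e-6)
    alpha <- 0.5 * log((1 - eps) / eps)
    eps_tr <- c(eps_tr, eps)
    alpha_tr <- c(alpha_tr, alpha)
    w[mis_neg] <- w[mis_neg] * exp(alpha)
    w <- w / sum(w)
  }
  list(epsilons = eps_tr, alphas = alpha_tr, neg_weights = w)
}

# small labeled 2-class Gaussian blob problem
gauss_blobs <- function(n_pos, n_neg, shift = 2, d = 2, seed = 1) {
  set.seed(seed)
  list(x = rbind(matrix(rnorm(n_pos * d, shift), n_pos),
                 matrix(rnorm(n_neg * d), n_neg)),
       y = rep(c(1L, 0L), c(n_pos, n_neg)))
}

# tiny residue dataset for pipeline tests
tiny_dataset <- function(n_chains = 8, len = 60, ratio = 20, seed = 1, ...) {
  make_sequence_fixture(fixture_spec(n_chains = n_chains,
                                     length_range = c(len, len),
                                     ratio = ratio, seed = seed, ...))
}
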