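---
title: "ligbind: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ligbind: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Most protein residues never touch a ligand; the few that do determine
function.  `ligbind` predicts, from sequence-derived information alone,
which residues of a protein chain bind a given ligand type (metal ions such
as ZN or CU, acid radical ions such as SO4 and PO4, nucleotides such as ATP
and FMN, or heme).  Two properties dominate the design:

* **ligand specificity** — binding pockets differ chemically and sterically
  between ligands, so one model per ligand type outperforms a single
  general-purpose model;
* **extreme class imbalance** — curated per-ligand benchmarks contain on the
  order of 50–100 non-binding residues per binding residue, which breaks
  classifiers trained under a balanced-class assumption.

## Feature model

Each residue is represented by a sliding window of length $L$ (odd, centred
on the residue; per-ligand defaults range from 7 for PO4 to 19 for ATP, see
`ligand_windows()`).  The feature vector has $28L + 2$ entries:

* **$L \times 20$ evolutionary scores.** Raw PSI-BLAST log-odds scores $x$
  are squashed by the logistic map $y = 1 / (1 + 2^{-x})$ into $(0,1)$.
  Window positions beyond a terminus take the neutral value $0.5$ (the image
  of a raw score of 0).
* **$L \times 6$ predicted structure properties.** A one-hot triple for
  helix/strand/coil, one exposure flag (relative solvent accessibility
  $\ge 25\%$; the boundary value counts as exposed since the quoted
  definition of buried ($<25\%$) and exposed ($>25\%$) leaves it
  unassigned), and the $\phi$ and $\psi$ torsions scaled by $1/180$ so all
  slots are commensurate under an RBF kernel.  Out-of-chain positions are
  all-zero.
* **$L \times 2$ per-position conservation.** From an MSA whose first row is
  the target (target-gap columns dropped): the relative entropy
  $RE = \sum_j p_j \log_2 (p_j / q_j)$ against a background $q$ (uniform
  over the 20 amino acids by default) and the Jensen–Shannon divergence
  $JSD = H(\tfrac{p+q}{2}) - \tfrac{H(p) + H(q)}{2}$ in bits, which is
  bounded by $[0,1]$.  Gaps and unknown residues are excluded from the
  column distribution; the JSD is multiplied by the non-gap fraction of the
  column so sparsely populated columns cannot masquerade as conserved.
  The RE is left unscaled.
* **2 segment-conservation scores.** A position weight matrix over the
  21-symbol alphabet (20 amino acids plus `X` for unknown residues and
  window positions outside the chain) is built per class from training
  windows with the square-root pseudocount
  $p_{ij} = (n_{ij} + \sqrt{N_i}/21)/(N_i + \sqrt{N_i})$ — an algebraic
  identity guarantees $\sum_j p_{ij} = 1$ — and natural-log odds
  $m_{ij} = \log(p_{ij}/P_j)$ against a background $P_j$ pooled over all
  training segments of both classes (uniform $1/21$ fallback).  A window
  $s$ scores
  $S = \sum_i (m_{i,s_i} - m_{i,\min}) / \sum_i (m_{i,\max} - m_{i,\min})
  \in [0,1]$; the score is invariant to per-position shifts of the matrix,
  and a fully degenerate matrix (zero denominator) scores $0.5$.  One score
  against the binding-class PWM and one against the non-binding-class PWM
  close the feature vector.

The log base of the PWM odds is immaterial ($S$ is base-invariant); base-2
is used for RE/JSD to keep the conventional information-theoretic units and
the $[0,1]$ JSD bound.

## The imbalance-aware ensemble

The classifier is a modified AdaBoost over $T = 15$ rounds in which **only
the negative class is resampled and reweighted**:

1. negatives carry weights $w$, initialised uniform; positives always
   participate in full;
2. each round draws $\lceil r\,|P| \rceil$ negatives (default $r = 1$:
   balanced base training sets) by weighted sampling without replacement and
   fits one base classifier;
3. the round error $\varepsilon_t$ is measured on the *entire* training set
   — positives with equal fixed weights, negatives with their current
   weights, each class carrying half the total mass so positives are not
   drowned at extreme imbalance;
4. the vote weight is $\alpha_t = \tfrac12 \log((1-\varepsilon_t)/
   \varepsilon_t)$ ($\varepsilon_t = 0$ clamped to $10^{-6}$);
5. misclassified negatives are up-weighted by $\exp(\beta\,\alpha_t)$ with a
   damping $\beta = 0.5$ — the "small scale" increase that guards against
   over-fitting hard negatives; $\beta = 1$ recovers the classical AdaBoost
   update exactly, which is asserted against an independent reference trace
   in the tests;
6. a round with $\varepsilon_t \ge 0.5$ is discarded, its sampling retried
   once, then training stops early.

Prediction is the vote-weighted mean of base probabilities
$\sum_t \alpha_t p_t(x) / \sum_t \alpha_t$, thresholded at $0.5$.

**Base classifier.** The design calls for an RBF-kernel classifier with a
kernel width and a regularization constant $C$.  No support-vector-machine
implementation is available in the supported dependency set, so the base
learner is an RBF-**kernel logistic classifier** fitted by penalized IRLS
(ridge penalty $\alpha^\top K \alpha / C$, unpenalized intercept,
step-halving safeguard).  This keeps the intended kernel and regularization
surface, and returns calibrated probabilities directly from the logistic
link — the sigmoid post-calibration an SVM would need becomes unnecessary.
For training sets above 512 rows a random row subset serves as kernel
centers (Nyström-style subset of regressors); below that the fit is the
exact kernel machine.  The default kernel width is
$1/(d \cdot \overline{\mathrm{Var}})$.

One measurable consequence of this substitution: on a 2-D Gaussian
benchmark with 1:100 imbalance, a *single* kernel-logistic classifier
thresholded at 0.5 is already a conservative, high-precision baseline
(unlike a hinge-loss SVM, which collapses toward the majority class).  The
ensemble recovers sensitivity dramatically (about 0.25 → 0.9 in the test
suite's benchmark) at some cost in precision, so its MCC is not uniformly
above that baseline.  The corresponding acceptance check asserts both
directions and the MCC half fails by design honesty rather than being
weakened.

## Structure-derived labels and curation

A residue is a **binding residue** iff one of its non-hydrogen atoms $i$
lies within $d_{ij} \le r_i + r_j + c$ of a non-hydrogen ligand atom $j$,
with van der Waals radii from a Bondi table (common crystallographic values
for metals; every entry overridable) and tolerance $c = 0.5$ Å; the
boundary counts as contact.  Multiple sites of the same ligand on a chain
are labeled as a union.  `HEME` merges the `HEM` and `HEC` components.
Benchmark curation keeps structures with resolution strictly below 3.0 Å
and chains strictly longer than 50 residues, then removes redundancy
greedily in input order using global Needleman–Wunsch identity (match
$+1$, mismatch $0$, linear gap $-1$; identical pairs over alignment
length; both the gap penalties and the denominator convention are
selectable since the source conventions are unrecorded).  The traceback
tie-break is fixed (diagonal, then gap in the second sequence) so identity
is deterministic.  A dedicated CD-HIT-style pre-clustering pass is not
reimplemented: at package scale the exact NW filter subsumes it.

## The consensus combiner

Template-based binding-site predictors emit *sites* with a confidence
C-score and a cluster density.  For a requested ligand, sites whose
candidate-ligand list matches are kept (HEME aliasing applies); overlapping
sites collapse per residue by maximum C-score, with the winning site's
cluster density.  A window of length $L'$ (defaulting to the ligand's
sequence-method window) collects per position the sequence-based
probability plus the four (C-score, density) pairs — $9L'$ features —
which feed the same boosted ensemble.  A missing component method
contributes zeros with a warning rather than aborting, because
template-based methods legitimately fail on hard targets.  Whether the
published consensus used per-site or per-residue C-scores is unrecorded;
the per-site value broadcast to member residues is assumed here.

## Evaluation

Accuracy, sensitivity, specificity and the Matthews correlation coefficient
are computed from exact confusion counts; a zero factor under the MCC root
yields MCC 0 (standard convention).  Cross-validation partitions **chains,
never residues**, into five seeded folds, and every fold retrains the class
PWMs and background frequencies from its training chains only, so no
information leaks through the encoder.  Whether the original evaluation
split by protein or by residue is unrecorded; chain-level grouping is the
leakage-safe choice, at the price of slightly pessimistic numbers relative
to a residue-level split.  Pooled metrics over all out-of-fold predictions
are reported alongside per-fold values and their mean; published per-ligand
tables are treated as pooled.  The general-vs-specific harness evaluates,
under identical folds, one model trained on the merged multi-ligand pool
against one model per ligand.

## Synthetic fixtures: what they emulate, and what a green test means

`make_sequence_fixture()` produces chains, PSSMs, structure properties,
MSAs and labels with planted signal.  The stated world:

* 60 chains of length 120, 50 negatives per positive (the order of
  imbalance of curated per-ligand datasets), binding positions placed
  uniformly at random;
* PSSM noise is a discretized normal with sd 2 raw units (the typical
  spread of PSI-BLAST log-odds); binding positions add a mean shift
  $\delta = 2$ to three designated residue columns;
* binding positions draw their residue from a motif distribution (total
  motif mass 0.6 over four residues) and their MSA columns are made
  low-entropy (homologs copy the target residue with probability 0.9);
  alignment gaps fall uniformly, sites included, so gap structure carries
  no label information.

$\delta$ acts as the *master* effect size: at $\delta = 0$ the motif and
conservation are switched off too, so "no signal" is exact and a skill-free
result is the correct outcome.  Between 0 and 2 the motif and conservation
interpolate linearly.

The two-ligand fixture used for the ligand-specific-versus-general
comparison was calibrated once, before freezing, so that pooling actually
dilutes: each ligand's chains also carry the *other* ligand's signature at
decoy positions labeled negative (emulating chains that bind several
ligands — the mechanism by which general-purpose training degrades), the
MSA conservation channel is disabled (it is ligand-agnostic, so it would
mask the ligand-specific channels), the signature strength is $\delta = 4$
and motif mass 0.8.  Under this design the specific mode beats the general
mode for both ligands across seeds.

These fixtures validate the machinery, not biology: real PSSM columns are
correlated, real binding sites are spatial clusters on a folded chain, real
MSAs have phylogenetic structure, and real class imbalance comes with label
noise from the contact definition itself.  A green planted-signal test
establishes that the pipeline recovers a recoverable signal without
leakage; it does not establish benchmark-level performance on curated
structural data.

`make_structure_fixture()` plants single-atom residues with at least a
0.2 Å margin on both sides of the contact envelope, so the ground-truth
contact set is immune to floating-point noise.  `make_component_fixture()`
corrupts true labels by independent membership flips with probability
$1 - q$ per method; $q = 0.5$ yields candidate maps statistically
independent of the truth.

## Numerical and interface choices

* Residue indices are 1-based everywhere a user sees them; canonical
  internal residue order is alphabetical, and every file dialect (PSI-BLAST
  column order, permuted headers) is remapped on ingestion.
* Model archives are JSON with 17 significant digits, which round-trips
  IEEE doubles exactly; a version field guards against silent format drift.
* Sampling without replacement uses R's sequential weighted sampling;
  everything downstream of a seed is bit-reproducible, and cross-validation
  derives per-fold child seeds deterministically.
* IRLS runs at tolerance $10^{-9}$, at most 50 iterations, with a small
  ridge jitter on the kernel block for conditioning.
* The CLI returns 0/2/3 for success/usage error/data error; `--threads` is
  deliberately not offered since the base-R numerics are single-threaded
  and a thread count could never change results.

## Known limitations

* The boosting update for the round error uses the half/half class-mass
  convention described above; the quoted description ("jointly
  renormalized") admits other weightings, selectable only by code change.
* The exact per-round sample size, round count and damping factor of the
  original modified AdaBoost are unrecorded; $r = 1$, $T = 15$ and
  $\beta = 0.5$ are package defaults, all configurable.
* The kernel-logistic base learner matches the intended RBF surface but is
  not an SVM; margins, support vectors and hinge-loss behaviour under
  imbalance differ (see the ensemble section).
* Hard-target stratification, statistical-significance tables and the
  biological-relevance curation of the upstream structure database are out
  of scope; component-method outputs are consumed from files, never
  computed.
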