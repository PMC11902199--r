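---
title: "Dynamic functional connectivity in eigenspace: models, measures and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic functional connectivity in eigenspace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfconn)
```

## The model

Dynamic functional connectivity (dFC) describes a multivariate recording
$x(t) \in \mathbb{R}^N$ (one signal per brain location) by a time-indexed
family of symmetric pairwise-interaction matrices $C(t)$. Every matrix type
supported here can be written as a weighted *dyadic sum* over a window of
$T$ frames centred on $t$:

$$C(t) \;=\; s \sum_{i = t - \lfloor T/2 \rfloor}^{t + \lfloor T/2 \rfloor}
  w_i\, x(i)\, x(i)^{H},$$

where the $x(i)$ are transformed signal vectors, $w_i \ge 0$ are window
weights and $s$ a global scale. The supported instances are:

| type | factors $x(i)$ | scale | rank $\le$ | trace |
|---|---|---|---|---|
| windowed correlation | within-window z-scored signals | $1/(T-1)$ | $T-1$ | $N$ |
| windowed covariance | within-window demeaned signals | $1/(T-1)$ | $T-1$ | varies |
| co-fluctuation | globally z-scored signal at $t$ (one factor) | $1$ | $1$ | $\|\zeta(t)\|^2$ |
| phase alignment (iPA) | $\cos\theta(t)$ and $\sin\theta(t)$ (two factors) | $1$ | $2$ | $N$ |
| phase locking | $e^{i\theta(\tau)}$ over the window (complex) | $1/T$ | $T$ | $N$ |
| wavelet coherence | unit-modulus wavelet coefficient vectors (complex) | $1/T$ | $T$ | $N$ |

Because each $C(t)$ is a sum of at most $T$ dyads it is positive
semidefinite with rank at most $T$ — typically $T \ll N$ — and its entire
information content fits in a handful of eigenpairs.

### The Gram-matrix (temporal covariance) eigendecomposition

Collect the scaled factors of one frame as columns of the $N \times k$
matrix $X$. The nonzero eigenvalues of $C = s\,XX^{H}$ equal $s$ times
those of the small $k \times k$ Gram matrix $R = X^{H}X$ — the matrix of
inner products between whole-brain configurations at the window's time
points — and each eigenvector of $C$ is the corresponding linear
combination $X v$ of the factors, normalised. The per-frame cost is
$O(Nk^2 + k^3)$ instead of $O(N^3)$, and nothing of size $N \times N$ is
ever formed. `dfc()` applies this to every frame; the rank-1
(co-fluctuation) and rank-2 (phase alignment, solved from the quadratic
characteristic polynomial of the $2\times2$ Gram) cases use closed forms.
When $k > N$ the matrix is full-rank and the Gram route has no advantage,
so the implementation reconstructs the (then small) dense matrix and
decomposes it directly, noting the switch.

### Measures computed in eigenspace

With $C(t) = U \Lambda U^{H}$ per frame, all measures avoid dense
matrices:

* **Schatten norms** — $p=1$: $\sum_i |\lambda_i|$ (trivially $N$ for the
  fixed-trace types); $p=2$: $(\sum_i \lambda_i^2)^{1/2}$, identical to
  the Euclidean norm of the vectorised matrix; $p=\infty$:
  $\max_i|\lambda_i|$.
* **Metastability** — the sample SD in time of a chosen norm
  ($p = \infty$ gives spectral metastability).
* **Distances** — Schatten norms of $C(t_1) - C(t_2)$ from the signed
  spectrum of the difference, computed in the $(r_1 + r_2)$-dimensional
  span of the two eigenbases (below). An optional normalisation rescales
  both frames to unit $p$-norm first, using the same $p$ as the distance
  (self-consistency; the flag is recorded in pipeline outputs).
* **Frobenius product and cosine alignment** —
  $\langle A,B \rangle = \sum_{ij} \lambda_i \mu_j |u_i^{H} v_j|^2$, an
  $r_A \times r_B$ computation.
* **Projector distance** — $\sqrt{2r - 2\sum_{ij} |u_i^{H}v_j|^2}$ over
  the top-$r$ eigenvectors: an eigenvalue-free subspace comparison.
* **Von Neumann entropy** — Shannon entropy of the spectrum normalised to
  sum 1 ($0\log 0 = 0$), measuring how many axes of variation the signals
  explore. Natural log by default (a `base` argument exposes bits);
  bounded by $\log(\mathrm{rank})$.
* **Reconfiguration speed** — $s(t) = d_p(C(t), C(t-\tau))$; peaks mark
  regime transitions.
* **FCD matrix** — all pairwise (optionally strided) frame distances; for
  $p = 2$ assembled from precomputed frame norms plus pairwise Frobenius
  products rather than per-pair difference spectra.

## Tunable parameters

* `window` (frames): the estimation/resolution trade-off. Odd lengths are
  symmetric about the current frame; even lengths are accepted with a
  warning and cover one extra past frame. Only frames with a full window
  are fitted (no partial boundary windows); the fitted range is recorded.
* `taper`: `"square"` (default) or a raised-cosine taper. Weights are
  folded into the factors as $\sqrt{w_i}$ after normalising them to sum
  $T$, so tapered correlation windows keep an exact unit diagonal. A
  taper shapes the eigenvalue spectrum, so entropy values computed under
  a taper carry a warning.
* `band` (Hz): phase-based types assume narrowband oscillators; the band
  chooses the timescale the same way the window length does for
  correlation (demonstrated by `matrix_timecourse_similarity()`: lowering
  the band moves the best-matching correlation window to larger values).
* `n_eigs`: eigenpairs retained per frame. The default keeps every
  eigenvalue above tolerance (lossless); truncation is an explicit
  denoising choice.
* `tol` (relative, default `1e-10`): an eigenvalue is "non-null" iff it
  exceeds `tol` times the largest. The structural ranks in the table
  above are exact in this scale-free sense.
* z-scoring uses the sample SD (denominator $T-1$), consistent with the
  $1/(T-1)$ scale of the correlation/covariance forms; with that
  convention the static Pearson matrix equals
  $\sum_t \zeta(t)\zeta(t)^{H}/(T_\mathrm{rec}-1)$ exactly.

## Numerical choices

* **Eigenvector orientation.** The entry of largest modulus is rotated
  (real) positive, ties to the lowest index. Measures are invariant to
  this; it only pins down serialisation and cross-run comparisons. In
  degenerate eigenspaces any orthonormal basis is acceptable and tests
  compare projectors, not individual vectors.
* **Difference spectra.** The nonzero eigenvalues of $C_A - C_B$ equal
  those of the small operator product $D\,(F^{H}F)$ built from the
  stacked scaled eigenvectors with signs $D = \mathrm{diag}(+1,\dots,-1,\dots)$.
  That product is non-symmetric, and for degenerate inputs (two identical
  frames) a general eigensolver returns spurious complex pairs of
  magnitude $\sim \sqrt{\varepsilon}$. The implementation therefore
  compresses the difference onto an orthonormal basis of
  $\mathrm{span}(U_A, U_B)$ — obtained from the eigendecomposition of the
  small Gram matrix of the stacked eigenvectors, discarding directions
  below `1e-12` relative — and decomposes the resulting Hermitian matrix.
  The spectrum is exactly real and identical frames cancel to rounding
  error.
* **Filter design.** The band-pass is a zero-phase (forward–backward)
  Butterworth, default order 2, recorded in provenance; no edge trimming
  by default, with a `trim` option recommended before phase extraction.
  The analytic signal comes from the standard FFT construction; wavelet
  coefficients from an analytic Morlet ($\omega_0 = 6$) by
  frequency-domain convolution, the wavelet phase taken at the geometric
  mean of the band edges.
* **Cost-scaling estimator.** `benchmark_evd_scaling()` times the
  compiled per-frame kernels; `scaling_exponent()` fits
  $t(N) = a + b N^e$ with a nonnegative offset and reports $e$. The
  offset matters: the fixed cost of the $k \times k$ eigensolve (about
  10 µs per call for $k = 10$) dominates at $N \sim 10^2$ and would bias
  a plain log-log slope well below the true growth rate of the
  $N$-dependent work. With the offset model the Gram route measures
  $e \approx 1$ (theory: $O(NT^2)$ at fixed $T$) and the dense route
  $e \approx 2.4$–$3$ (eigendecomposition of an $N \times N$ matrix),
  stable across seeds.
* **Degenerate inputs.** Constant signal rows make z-scores and phases
  undefined and raise errors naming the row (and window); all-zero or
  non-finite rows are dropped at ingestion with a logged count. Zero
  wavelet coefficients make unit-modulus normalisation undefined and
  raise an error naming row and frame.

## The synthetic benchmark

`planted_covariance_signals()` generates the validation conditions used
throughout the tests: zero-mean unit-variance Gaussian signals (default
$N = 10$) in 5 contiguous chunks of 1000 frames, each chunk multiplied by
the Cholesky factor of a distinct random SPD matrix, planting a known
covariance per regime with switches after frames 1000–4000. The SPD draws
are well-conditioned Wishart-type matrices ($AA^{T}/N + 0.1\,I$) — the
construction is this package's choice of "random covariance", documented
here because only its existence, not its law, matters for the recovery
claims. `structured_spd()` adds near-isotropic versus dominant-axis
covariances for entropy contrasts, and `iid_gaussian_signals()` provides
white Gaussian input for oracle and scaling tests.

What the generator emulates: abrupt regime switches in the second-order
structure of otherwise stationary Gaussian signals. What it does not
emulate: autocorrelated (e.g. haemodynamic) noise, non-Gaussian
amplitudes, drifts, motion artefacts, or gradual state transitions.
Passing the recovery tests therefore shows the estimator chain is correct
and sensitive under clean switching conditions; it does not certify
performance on real recordings.

A typical analysis of the benchmark (window 121, lag 100, normalised
distances):

```{r benchmark, eval = FALSE}
bench <- planted_covariance_signals(seed = 42)
fit <- dfc(bench$signals, type = "covariance", window = 121)
speed <- reconfiguration_speed(fit, tau = 100, p = 2, normalise = TRUE)
peaks <- find_peaks(speed, min_sep = 121)
sort(as.integer(names(speed)[peaks[1:4]]))  # near 1000, 2000, 3000, 4000
fcd <- fcd_matrix(fit, p = 2, normalise = TRUE, stride = 25)
```

Peak detection is deliberately simple and stated: local maxima above the
series minimum plus half the range, separated by at least one window
length.

## Problem sizes in the test suite

The suite exercises the dense-oracle equivalence over
$N \in \{10, 50, 200\}$, $T \in \{3, 10, 21\}$ and 20 seeded repetitions
per combination for all six matrix types; measure oracles at $N \le 50$;
benchmark recovery on the full default 10 × 5000 generator (plus smaller
3-regime variants for the clustering and metastability properties); and
the cost-scaling measurement over $N = 10^2$ to $10^4$ (Gram route) and
up to $N = 2000$ (dense route, to keep dense eigendecompositions cheap).
These sizes were chosen so each property is tested in the regime where it
is meaningful while a full run stays comfortably interactive.

## Known limitations

* The general extension family of entrywise-function matrices (beyond the
  six types above) is out of scope; the factor interface is the natural
  hook for adding members whose dyadic form is known.
* Partial correlation follows the precision-direction construction
  (off-diagonals are the negatives of the partial correlations, unit
  diagonal) and needs $T - 1 \ge N$; for wide windows on large $N$ use a
  parcellation or a different variant.
* Distance-1 between two unit-diagonal matrix types is degenerate (the
  diagonals cancel); the implementation warns and suggests $p = 2$ or
  $\infty$.
* No statistical inference (significance of measure–task correlations) is
  provided; the package computes the measures themselves.
* Serialisation is plain text (CSV/JSON) — portable and diffable, but not
  the right container for voxel-scale eigenvector series; a chunked
  binary container would be the natural extension.
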