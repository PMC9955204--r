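---
title: "Methods: MSM, tICA and allosteric network analysis of Cas9 dynamics"
author: "Cas9Dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MSM, tICA and allosteric network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(Cas9Dynamics)
```

# Scope and model

Cas9Dynamics analyzes protein conformational dynamics from molecular
dynamics trajectories. The scientific target is the activation motion of
SpCas9: the HNH and RuvC nuclease domains and the L1/L2 linkers
(featurization region 718–1001 by author numbering) rearrange between
metastable conformations, and the analysis characterizes those states,
their kinetics, and the residue network that couples distant sites such
as Gln768 and Arg976.

The chain of models is the standard one in the Markov-state-model field:

1. **Torsion featurization.** Backbone φ and ψ dihedrals per residue,
   each expanded to (sin, cos) so the circular topology is respected.
   Side-chain χ1 is available behind a flag but off by default: backbone
   torsions are well defined across wild type and mutants, and whether
   side-chain torsions belong in the feature set is genuinely open — we
   chose the minimal, comparable set.
2. **tICA.** With instantaneous covariance $C_0$ and symmetrized lagged
   covariance $C_\tau$ of the mean-free features, the slow modes solve
   $C_\tau v = \lambda C_0 v$. Symmetrization $(C_\tau + C_\tau^T)/2$ is
   applied before the eigenproblem — standard practice for estimating
   reversible dynamics from finite trajectories. Components are
   $C_0$-orthonormal, so each projected coordinate has unit instantaneous
   variance and $\lambda_i$ is its autocorrelation at the lag.
   Assumption: the slow dynamics is approximately linear in the chosen
   features at the chosen lag.
3. **Discretization and MSM.** k-means (k-means++ seeding, Lloyd
   iterations) in tICA space; sliding-window transition counts; the
   reversible maximum-likelihood transition matrix on the largest
   strongly connected state set, by the usual detailed-balance
   fixed-point iteration (likelihood convergence $10^{-10}$). We chose
   the reversible estimator as the default because PCCA++ requires a real
   spectrum; equilibrium trajectories justify detailed balance.
4. **Validation.** Implied timescales $t_i = -\tau/\ln\lambda_{i+1}$ must
   be flat in $\tau$; the Chapman–Kolmogorov test compares
   $T(\tau)^k$ with a model re-estimated at $k\tau$, per macrostate set,
   and passes when the re-estimated points lie inside the Bayesian 95%
   band for at least 95% of points. Uncertainty comes from per-row
   conjugate Dirichlet posterior sampling with a uniform prior. The
   sampler is non-reversible — a deliberate simplification: the conjugate
   posterior is exact and cheap, while reversible samplers need MCMC; the
   resulting intervals are slightly conservative for reversible chains.
5. **Macrostates.** PCCA++ on the top-$m$ right eigenvectors: a simplex
   vertex search picks the $m$ most spread microstates, memberships are
   the eigenvector rows in that vertex basis, clipped to $[0,1]$ and
   row-normalized; crisp states by argmax. Mean first-passage times
   between macrostates come from the first-step linear system
   $(I - T_{BB})\,m_B = \tau\,\mathbf 1$, averaged over the source set
   with stationary weights, and are reported in ns via the frame stride.
6. **Free-energy surface.** Each frame carries weight
   $\pi(\text{microstate})/\#\{\text{frames in microstate}\}$, so binned
   weights estimate the equilibrium density even from non-equilibrium
   frame counts; $F = -kT\ln\sum w$, minimum shifted to 0, empty bins NA
   rather than zero. This per-microstate redistribution is our reading of
   "reweighted"; alternatives (e.g. TRAM-style estimators) are out of
   scope.
7. **Structure association.** Jarvis–Patrick clustering (two frames join
   iff mutually within each other's K nearest neighbours sharing at least
   kmin common neighbours; clusters are connected components) on pairwise
   backbone RMSD after Kabsch superposition; per-cluster averages by
   iterative align-and-mean (tolerance $10^{-6}$ Å); macrostate
   representatives (highest-membership frames) match to the average with
   minimal backbone RMSD, ties broken by larger cluster weight then lower
   cluster id. K and kmin are not fixed by any published protocol; we
   default to K = 10, kmin = 3 (common trajectory-clustering practice)
   and expose both. An optional maximum-RMSD acceptance cutoff exists but
   is off by default, since no published rejection threshold is
   available.
8. **Allosteric network.** Coupling is the scalar dot-product correlation
   of 3-D Cα displacement vectors after superposition onto the iterative
   mean — the common dynamical-network choice, rather than per-component
   correlation. Edges require mean Cα–Cα distance ≤ 12 Å (the 1.2 nm
   interaction cutoff expressed in Å) and carry weight $-\ln|C_{ij}|$, so
   perfect coupling is a zero-length link and Dijkstra's algorithm (ties
   broken toward lower residue numbers) yields the strongest
   communication pathway. The published analysis derived couplings from a
   trained neural relational inference model; here the estimator is the
   deterministic cross-correlation above, and the estimator slot is the
   natural place to plug an NRI back-end in later. Exact reproduction of
   a published pathway node list is therefore not expected.
9. **Markers and nucleic geometry.** Six marker groups (His840–cleavage
   site, three FRET pair distances, His983 and Arg976 to the scissile
   phosphate, Gln768 to the PAM-distal end, Arg1333/Arg1335 to the PAM).
   Protein anchors are Cα except Arg976, which uses the terminal
   side-chain carbon (CZ) as stated for that marker; nucleic sites named
   as base steps are realized as the midpoint of the named P atoms — the
   anchor point is not defined more precisely anywhere, and the midpoint
   is symmetric and stable. Distance distributions get
   Freedman–Diaconis histograms and Gaussian fits: closed-form moments
   for one component, seeded EM (best of 5 restarts) for mixtures.
   Sugar pucker uses the five endocyclic torsions:
   $\tan P = \frac{(\nu_4+\nu_1)-(\nu_3+\nu_0)}{2\nu_2(\sin 36^\circ + \sin 72^\circ)}$
   with the quadrant from the two-argument arctangent and amplitude
   $\tau_m$ recovered as the hypotenuse of $(\tau_m\sin P, \tau_m\cos P)$
   — algebraically equal to $\nu_2/\cos P$ but defined at $P = 90^\circ,
   270^\circ$. The δ torsion is C5′–C4′–C3′–O3′ (the "O" of the informal
   definition is read as O3′, the standard δ). Regimes: R-loop-associated
   above 270°, else B-form at or above 100°, else A-form — the R-loop
   window is a subset of the B-form half-plane, so precedence R-loop >
   B-form > A-form resolves the overlap.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `frame_stride_ns` | 1 | ns | one stored frame per ns |
| `tica.lag_frames` | 50 | frames | 50 ns at the default stride; chosen by VAMP2 in the original analysis |
| `tica.n_dims` | 4 | – | kinetic variance saturates at four modes |
| `tica.threshold` | 0.195 | – | contribution cutoff on normalized loadings; largest value keeping the catalytically relevant residues |
| `msm.n_clusters` | 100 | – | k-means microstates |
| `msm.n_macrostates` | 4 | – | PCCA++ target |
| `msm.n_bayes_samples` | 100 | – | posterior sample size |
| `allostery.cutoff_A` | 12 | Å | Cα–Cα interaction gate (1.2 nm) |
| `allostery.report_threshold` | 0.6 | – | display-only coupling threshold |
| Jarvis–Patrick K / kmin | 10 / 3 | – | common clustering defaults; unpublished in the original protocol |

The "contribution" behind the 0.195 threshold is not defined anywhere
precisely; we score each feature by its maximum absolute loading across
the kept components after scaling every component to unit maximum
absolute loading, and merge sin/cos partners by maximum into one
residue-level score. This is one defensible reading; it reproduces the
intended behaviour (one-hot loadings select exactly their residue, the
threshold interpolates monotonically between all and none).

# What the synthetic generators emulate

No trajectories are distributed with the package, so every stage is
validated on generated data whose ground truth is known by construction:

* `simulateMarkovChain` — exact discrete chains for the MSM estimators
  (empirical counts converge to the generating matrix).
* `simulateDoubleWell` — Euler–Maruyama overdamped Langevin dynamics on a
  piecewise-quartic multi-well potential; the simplest integrator whose
  stationary density is controlled at small timestep. The drift step is
  capped so it can never overshoot the nearest well centre, which keeps
  arbitrarily stiff barriers stable.
* `generateChainTrajectory` — Gaussian Cα displacements with a prescribed
  residue covariance (applied per Cartesian component) around an extended
  chain at 3.8 Å spacing, the typical Cα–Cα distance; ground truth for
  the coupling estimator.
* `generateBackboneTrajectory` — rebuilds N/CA/C/O coordinates from ideal
  internal coordinates and prescribed φ/ψ series, so featurization is
  validated by exact round trips and hidden-Markov-driven torsions become
  full trajectories for the end-to-end demo.
* `generateSugarRing` / `generateDistanceSeries` — exact pseudorotation
  torsion sets and seeded Gaussian mixtures.

Every generator is a pure function of its parameters and seed. Mixture
sampling uses one seeded stream per call; per-component streams were
rejected to keep reproducibility trivial.

What passing these tests shows: the estimators recover the statistical
structure they assume, at realistic sample sizes, with correct
uncertainty. What it does not show: behaviour under force-field error,
incomplete sampling of slow modes, non-Gaussian solvent-coupled
fluctuations, or featurization mismatch — properties of real MD data that
no synthetic fixture reproduces. Published state-specific kinetics (e.g.
macrostate transition times from μs-scale trajectories) are therefore not
reproduction targets of the test suite; the trajectory-independent
printed quantities (domain compositions, replica bookkeeping, closed
forms) are.

# Numerical choices

* Dihedrals: two-argument arctangent convention, IUPAC sign, degrees in
  (−180, 180]; δ reported in [0, 360) for plotting parity. Collinear
  p2–p3 raises a degenerate-geometry error.
* Kabsch: SVD with determinant correction (always a proper rotation);
  fits need at least 3 points.
* tICA: ridge default $10^{-8}$ on $C_0$; a rank-deficient $C_0$ without
  ridge raises an error that suggests regularization. Eigenvalues are
  clipped to $|\lambda| \le 1 + 10^{-6}$.
* MSM: sliding-window counting (no effective-count correction);
  disconnected microstates are dropped to the largest strongly connected
  set with a log message; infinite timescales are reported as +Inf, never
  clipped; non-positive eigenvalues give NA timescales rather than
  fabricated values.
* k-means: seeded k-means++ initialization feeding `stats::kmeans`
  (Lloyd); deterministic per seed.
* EM mixture fits: quantile-spread means jittered per restart, variance
  floor $10^{-6}$, best of 5 restarts by log-likelihood.
* Pipeline determinism: every stochastic stage derives its seed from the
  config seed and a stage tag; two runs of one config are numerically
  identical.

# Problem sizes

The shipped demo drives a 6-residue backbone with a hidden 4-state chain
(two weakly coupled 2-state blocks, within-block switching 0.02/step,
between-block 0.005/step) over 2000–3000 frames, clusters into 12
microstates and coarse-grains back to 4 macrostates; structure clustering
runs on a 60-frame stride subset because pairwise RMSD is quadratic in
frames, and the coupling analysis on up to 500 frames. Statistical tests
use $10^4$–$10^5$ samples, where Monte-Carlo error (≈ $3/\sqrt n$) is
well below the asserted tolerances. These sizes are the package's chosen
demonstration conditions; all of them scale up by configuration.

# Known limitations

* The coupling estimator is linear cross-correlation; genuinely nonlinear
  or lagged couplings that a trained interaction-inference model could
  capture are invisible to it.
* The Bayesian sampler ignores detailed balance; intervals for reversible
  systems are approximate.
* Jarvis–Patrick parameters and the macrostate-representative choice
  (highest PCCA++ membership) are conventions, not published protocol.
* PCCA++ uses the simplex-vertex construction without the subsequent
  objective optimization; adequate for well-separated metastable states,
  potentially coarse for overlapping ones.
* mmCIF input, automatic structure download, protonation assignment and
  any simulation engine functionality are out of scope.
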