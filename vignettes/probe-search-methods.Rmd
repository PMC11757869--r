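---
title: "Probe search over cardiac confidence maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe search over cardiac confidence maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Transthoracic echocardiography needs the ultrasound probe placed at the chest
position where the target heart component — here the mitral valve — is imaged
most clearly. An object detector scores each frame with a confidence in
[0, 1], so probe placement becomes the search for the grid cell with maximal
per-cell confidence `C`. Two anatomical facts make this search hard: ribs
attenuate the image at regular intervals along the body's vertical axis, so
the confidence surface carries intermittent *local* maxima, and the sternum
and lungs suppress imaging entirely in a central band. A naive hill climber
stalls on a rib-window local maximum; a full serpentine sweep of the grid
(the conventional baseline) always finds the optimum but pays the full
35-cell cost.

`echonav` implements the alternative studied here: a deep Q-network (DQN)
trained with reward shaping that makes stopping short of the optimum costly,
wrapped in a deterministic path-generation layer that repairs the three
failure modes of a greedy rollout.

# The environment

The probe tip moves on an `n_x` × `n_y` grid (default 7 × 5, 0-based indices,
origin at the xiphoid process, X caudocranial, Y lateral). The nine actions
are the eight compass unit steps plus STOP; a step off the grid leaves the
probe in place. The observed state is XYC: grid position plus the cell's
confidence, the latter the median of the per-frame detector scores while the
probe dwells in the cell.

## Reward model

All applicable terms sum per executed action:

| condition | reward |
|---|---|
| perform one move | −0.1 |
| move out of search range | −0.3 (added to the move cost) |
| stop | −3.0 |
| confidence change Δ = C_after − C_before on a move | +10.0·Δ |
| stop at the optimal cell | +5.0 |
| stop at the optimal cell after fewer than 35 moves | +20.0 |
| stop at a non-optimal cell | −m_l·(C_m − C_p) |

Here `C_m` is the confidence at the optimal cell and `C_p` the confidence at
the stopping cell; the 10·Δ term telescopes, so over any trajectory the
summed Δ terms equal 10·(C_end − C_start) exactly. The slope `m_l`
(default 40) controls local-maximum avoidance: a larger slope makes stopping
anywhere below the optimum expensive, at the price of sometimes overshooting
it.

Three compositions are not fixed by the reward table alone; the package
resolves them as follows and treats them as part of the model:

* the flat stop cost applies even when stopping at the optimal cell (rows
  are independent conditions; the ordering of outcomes is preserved, since
  −3 + 5 + 20 still dominates every non-optimal stop);
* a blocked move still consumes a move, earns the out-of-range cost on top
  of the move cost, and has Δ = 0 (the probe cannot leave the chest, so the
  penalty must not be escapable);
* the move count compared against the 35-move bonus threshold counts every
  executed action including blocked moves, but not the terminal STOP
  itself.

Training episodes are force-terminated after 100 actions without stop
rewards; untrained policies otherwise wander indefinitely.

# The agent

The action-value network is a dense MLP on base-R matrices: an input
projection 3 → 100, `D` hidden 100 × 100 blocks (rectifier activations), and
a linear 100 → 9 head. `D` is the depth parameter swept in evaluation
(default 2). Inputs are the XYC state normalised to the unit cube. The state
deliberately excludes the move counter, although the fast-stop bonus makes
the true return depend on it; the value function is therefore mildly
non-Markov in the observed state, which is accepted as part of the studied
design.

Training is standard small-scale DQN: epsilon-greedy exploration decaying
linearly from 1.0 to 0.05 over the first 60 % of episodes, an experience
replay buffer of 10 000 transitions (oldest evicted first, learning starts
at 500), minibatches of 32 regressed with Adam (learning rate 1e-3) toward
one-step TD targets at discount 0.95, and a target network synced every 200
learner steps. Only STOP transitions are treated as terminal for
bootstrapping; cap-terminated episodes are truncated without a terminal
flag. Maps are scheduled round-robin by episode index and every random draw
comes from one master seed, so training is bit-reproducible. These
hyperparameters are package defaults chosen once from common practice at
this scale; all are overridable through `train_config()`.

On a single small map the cell index is a sufficient tabular state, so a
tabular Q-learner trained against the *same* environment serves as an
independent oracle: on 3 × 3 all-positive maps its greedy rollout provably
converges to stopping at the optimal cell, and the test suite requires the
DQN's planned estimate to agree with it on at least four of five seeded
maps. Exact per-state agreement is not required — function approximation on
nine states need not be exact, and the end-to-end claims rest on rollout
outcomes.

# Path generation

A greedy rollout of the trained policy has three failure modes: it can
oscillate over already-searched cells, stop on a zero-confidence cell, and
cannot return to an optimum passed earlier. The planner applies three rules:

* **A (revisit masking)** — from the second arrival at a cell onward, the
  greedy argmax is taken over actions not yet selected there; masks persist
  for the whole search. When all nine actions are exhausted at a cell the
  search is forced to terminate with rule C (continuing could only loop).
* **B (zero-confidence stop)** — a STOP selected where `C = 0` is rejected;
  the probe travels back to the best visited cell along a Chebyshev-shortest
  8-connected path (earliest-visited among ties) and resumes from there.
  The return moves are executed and counted — a physical probe must traverse
  the chest — but their forced action choices are not charged to the rule-A
  ledger. In the degenerate case where the zero-confidence cell is itself
  the best visited cell the return path is empty; the planner counts the
  re-arrival so the rejected STOP is masked on the next pass rather than
  looping.
* **C (termination)** — an accepted STOP ends the search and the estimate is
  the highest-confidence cell on the trajectory (earliest among ties), not
  necessarily the stopping cell.

A global cap of 500 planner steps guarantees halting under adversarial
(e.g. scripted) agents; trained agents terminate far earlier. Every executed
action — movements, return moves, the terminal STOP — counts toward the
reported move total.

The conventional baseline sweeps the grid serpentine-wise (each Y column
traversed along the full X extent, alternating direction; five passes on the
default grid), visits all 35 cells in 34 moves, and estimates the global
argmax, so its loss rate is identically zero.

# The synthetic cohort

No public probe-scan dataset exists for this task, so the package generates
cohorts whose maps reproduce the structural features the search must cope
with: an isotropic squared-exponential confidence peak (height 0.9, decay
scale 1.6 cells) centred near the lower-left of the chest (population mean
cell (2, 3), per-subject spread (0.8, 0.6) cells); rib-shadow rows every 2nd
X row attenuated by a factor 0.4 with a per-subject phase; a zero-confidence
sternal column at Y = 2; cell-level noise (sd 0.02); and five detector
frames per cell at noise sd 0.05 aggregated by the median. Under these
defaults essentially every map contains at least one non-global strict local
maximum (the test suite checks ≥ 90 % over 100 seeds by exhaustive
8-neighbour comparison), which is the regime the reward shaping targets.

The squared-exponential peak is a modelling choice — the real data's shape
is unknown beyond "single clear optimum with intermittent visibility" — and
the generator does not model breathing, probe-contact physics, detector
failure modes, or inter-cell correlation of noise. Passing tests therefore
show that the method behaves as designed on landscapes with this structure,
not that the quantitative results transfer to clinical scans.

Numerical details: exact ties at the global maximum are forbidden in the
data model; the generator resolves them by bumping the lexicographically
smallest tied cell by one relative machine epsilon (nudging the others down
when the tie sits at 1.0). All-zero maps (peak swallowed by the dead band)
raise an error and are resampled with advanced sub-seeds. Maps round-trip
through CSV at 17 significant digits, losslessly for doubles.

# Evaluation

Accuracy and efficiency are measured against the full-coverage baseline on
the same maps with Cohen's d (pooled-SD form — the classical estimator
matching the usual interpretation bands): `d_C` on stop confidences, where
values below 0.5 mean accuracy is maintained, and `d_A` on action counts,
where values above 0.8 mean efficiency is improved. The loss-of-confidence
rate `L_c = 1 − C_s/C_m` summarises how much image quality a non-optimal
stop sacrifices. Outcomes are banded into a 3 × 2 table (stop confidence
`C = C_m` / `0 < C < C_m` / `C = 0`, equality at tolerance 1e-12 on stored
confidences, against move count < 35 or not). Inspection time is modelled,
not measured: a constant dwell of 2.45 s per visited cell, calibrated so a
full 35-cell sweep costs ~86 s; it is reported only as a model.

Cross-validation is subject-wise and three-fold at a 2:1 train:test ratio:
contiguous groups A, B, C; model α trains on A∪B and searches C, β trains
on B∪C and searches A, γ trains on A∪C and searches B. Parameter sweeps
re-run this procedure over `D`, `m_l`, or the start cell and report
(`d_C`, `d_A`) per value; the selection helper is accuracy-first (minimal
`d_C`, ties to maximal `d_A`), because in a healthcare setting a slightly
longer scan is cheaper than a misplaced view.

## Problem sizes

The shipped experiments use a 24-subject cohort on the 7 × 5 grid with
5000 training episodes per fold and the defaults above; the oracle
comparisons use five 3 × 3 maps with 2000-episode DQN runs. These sizes give
stable qualitative behaviour (attainment well above half, mean path length
well below full coverage, low non-optimal loss rates) while keeping a full
run in the minutes range on one CPU.

# Known limitations

* The synthetic landscapes are far smoother than real detector output; the
  attainment and effect sizes reported by the package characterise the
  algorithmic behaviour, not clinical performance.
* The XYC state cannot distinguish subjects whose optima differ but whose
  local appearance coincides; some near-miss stops one cell from the true
  optimum are inherent to the studied design, not implementation error.
* Probe angles, the Z axis, breathing and patient motion are out of scope;
  the grid is dimensionless (no millimetre pitch is modelled).
* Cohen's d is reported without significance testing, mirroring the
  evaluation design the package implements.
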