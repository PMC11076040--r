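---
title: "Chase-and-escape: model, learners, and behavioral statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chase-and-escape: model, learners, and behavioral statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collabhunt)
```

# The world

`collabhunt` simulates a pursuit–evasion game between one to three
predator disks and a single prey disk in a bounded square arena.
Space is continuous, time is discrete (`dt = 0.1` s, 30 s episode cap),
and every agent controls only its acceleration: a discrete choice of 12
directions spaced 30° apart in the agent's *relative frame*, plus a
13th "do nothing" action. Velocities retain a fraction `damping = 0.75`
per step (viscous resistance), so the semi-implicit Euler update is

$$v' = 0.75\,v + a\,\Delta t, \qquad p' = p + v'\,\Delta t .$$

A predator captures the prey when the centre distance falls to the disk
diameter (0.1). Capture pays the catcher +1 (every predator +1 under
*shared* reward), the prey −1; any agent leaving the arena
($|x|>1$ or $|y|>1$, centre test, boundary inclusive) is punished −1 and
ends the episode; a 30-s timeout pays nothing and counts as prey
success. Initial positions are i.i.d. uniform on $[-0.5, 0.5]^2$ with
zero velocity; draws that start in contact are redrawn. The design grid
crosses predator count (1–3), relative mobility — predator acceleration
at 120 % (*fast*), 100 % (*equal*) or 80 % (*slow*) of the prey's — and
reward sharing, giving 15 cells after collapsing sharing for a lone
predator.

Two constants are not pinned down by the physics above and are fixed
here as package defaults: the prey's acceleration magnitude
(`prey_accel = 4` length units/s², which lets an unopposed agent cross
the arena in roughly 2 s) and the per-step damping (0.75, the
convention of the particle-world family this environment belongs to).
Both are exposed in `condition_config()`.

## The relative frame and the clockwise angle convention

An agent's u axis points at its reference opponent — the prey for a
predator, the *nearest* predator for the prey (ties to the lowest
index) — so action 1 always accelerates straight at the opponent and
action 7 straight away. Action angles are measured **clockwise** from
u (the v axis is u rotated 90° clockwise). The direction of measurement
is not observable from the "action 1 toward / action 7 away" anchors,
but it is forced by the rule-based module: its edge-avoidance turns
(actions 3/2 for a clockwise chase, 11/12 counterclockwise) only point
*into* the arena, and its "shortcut" (2/12) only cuts *inside* the
chase's turning circle, under the clockwise convention. Under the
opposite convention those same action assignments steer outward at
walls for both orientations and the predators eliminate themselves
within seconds — so the clockwise convention is the only
self-consistent one, and the state featurization uses the same frame
so that inputs and outputs agree.

# Independent deep Q-learners

Every agent — predators *and* prey — owns a private dueling Q-network,
target network, Adam optimizer and prioritized replay memory; nothing
is shared, and each agent treats the others as part of the environment
(independent learning). The network takes the agent's absolute
position, its own velocity in its relative frame, and the relative
position and velocity of every other agent in the same frame
(4 + 4·(n−1) inputs), passes them through two 64-unit ReLU layers, and
splits into a 32-unit advantage stream with 13 outputs and a 32-unit
value stream with one output, merged as

$$Q(s,a) = V(s) + \Big(A(s,a) - \tfrac{1}{|A|}\sum_{a'}A(s,a')\Big),$$

which pins $\operatorname{mean}_a Q = V$ and removes the constant-shift
ambiguity of the advantages. Learning uses double-DQN targets (online
argmax, target evaluation), proportional prioritized replay
($P(i) \propto p_i^{0.6}$, $p_i = |\delta_i| + 10^{-6}$, new items at
the running maximum priority), importance weights
$w_i = (N P(i))^{-\beta}$ normalized by the batch maximum, and a
Huber loss (threshold 1) weighted by $w_i$. Constants: discount 0.9,
replay capacity $10^4$, minibatch 32, Adam at $10^{-6}$, target sync
every 2000 episodes, ε-greedy behavior annealed linearly from 1 to 0.1
over the first $10^4$ episodes. One gradient step per agent per
environment step once the memory holds a full minibatch — the natural
cadence given that experiences are defined per time step. The
importance-sampling exponent is unobservable from the constants above;
the package fixes β = 0.4, constant, exposed in `learner_config()`.

The training loop, bulk rollouts and the rule-based/scripted policies
are mirrored in C++ (float32 network arithmetic) because a per-step,
batch-32 learner over millions of environment steps is not feasible in
interpreted R; the exported R functions are the reference semantics,
and the test suite checks the two routes against each other (logged
C++ trajectories replay exactly through the R `step_world()`, R and
C++ rule actions agree on logged states, forwards agree to float
precision). All randomness flows through R's RNG, so `set.seed()`
makes training, rollout and evaluation bit-reproducible.

Full-scale training is $10^6$ episodes per condition — far outside an
interactive session. The package's scaled-down reference run, used by
the test suite and the acceptance script, is $2\times10^4$ episodes of
the one-predator *fast* cell (about 7 minutes of CPU): long enough for
the predator to learn wall avoidance and pursuit and lift greedy
success from the untrained baseline (≈ 0.2) to ≈ 0.99, which is the
desk-scale signature of the full-scale result. Checkpoints at thirds of
the run let the suite verify that greedy performance does not degrade
over training.

# Rule-based chaser and blocker

The two-predator rule agents are pure functions of the current world
state. Each predator first asks who is closer to the prey (ties:
predator 1). The closer one *chases*; the farther one branches on
whether the chase is tight — the closer predator within 0.4 of the
prey: predator 1 then takes a *shortcut* (cut inside the turn),
predator 2 *ambushes* (hold a reference point); in a loose chase
predator 1 *approaches* directly and predator 2 joins the chase. The
text defining which distance drives this branch is ambiguous; the
package uses the closer predator's distance because the alternative
(the decider's own distance) makes the ambush disengage the moment the
blocker leaves the prey, contradicting the blocker's defining
"remain there until the situation changes" behavior. The choice is
isolated in `assign_roles()`.

*Chase* is a cascade: own edge-avoidance bands (outside the 0.9 square:
hard turn 3/11; the 0.8–0.9 ring: soft turn 2/12), prey drive-out bands
(prey inside the central 0.5 square: 11/3; the 0.5–0.6 ring: 12/2), and
otherwise a velocity-alignment rule binned on the signed angle ψ
between predator and prey headings ((−∞,−50], (−50,−15], (−15,15],
(15,50], (50,∞) degrees → actions 3, 2, 1, 2, 3). Band membership is
tested on the max coordinate, i.e. on square rings about the centre:
conjunction tests on the two coordinates separately would guard only
the four corners, leaving every mid-wall approach unprotected (the
predators then exit the arena within two seconds of play), so the
rings are the only coherent reading of the band geometry.

Clockwise vs counterclockwise is decided from the prey's quadrant and
the dominant component of the closer-predator→prey vector
(ties to x). The full quadrant-by-direction lookup is frozen as the
sign of the cross product of the prey's quadrant sign vector with the
dominant-axis direction — geometrically, the rotation sense of the
drive direction about the arena centre — anchored by the regression
tests at a reference configuration (closer predator (0.2, 0.3), prey
(0.5, 0.2) is clockwise), flipping correctly under mirror reflection,
and labelling ring tail-chases consistently.

*Ambush* heads for the bottom-centre reference (−0.1, −0.5) while the
prey's y ≤ 0, else the top-centre (0, 0.6); selecting the reference by
the prey's side of the arena is what places the blocker on the prey's
escape route (the tests anchor this at a reference configuration:
blocker at (−0.2, 0.8) against prey at (−0.2, −0.8) selects action
12). Among the 120°-spaced actions {3, 8, 12} the blocker picks the
one minimizing next-step distance to the reference point (ties to the
lowest action): a one-step lookahead that makes the blocker hover once
it arrives, while remaining a memoryless function of the current
state.

# The scripted evasive prey

The behavioral corpora and rule-based evaluations need a prey, and the
trained prey of the full-scale study is not reproducible at desk scale.
The stand-in (`scripted_policy("evasive")`) is a forage–flee
controller: while no predator is within the flight-initiation distance
(0.45) it idles, drifting back inside a ring of radius 0.8 if outside
it; when pressed it sprints along the tangent direction that increases
distance to the nearest predator, with a radial correction
(gain 4) holding it near the ring, and its heading is rotated by
Gaussian noise (sd 0.35 rad). The design emulates three qualitative
features of a trained prey: edge-ring occupancy (its heat map is a ring
along the walls), intermittent flight that keeps the chase tight enough
for the blocker branch to engage, and enough heading noise to be
catchable by a cooperating pair but not by a lone slow pursuer.
What it does not emulate: adversarial anticipation of a specific
predator policy, learned exploitation of the predators' blind spots,
or any adaptation over episodes — so rule-based results against it
demonstrate the *mechanics* of role division, not the equilibrium
behavior of co-trained agents.

# Behavioral cloning

`train_clone()` fits one-hidden-layer softmax networks (32 hidden
units; a linear variant without activation and a nonlinear ReLU
variant) to a predator's state→action pairs by cross-entropy with Adam
(lr 10⁻⁴, batch 32; 2000 epochs at full scale), keeping the weights of
the best validation epoch. Corpora are regenerated by simulation with
episode-disjoint splits sized 1000/100/100 episodes; step counts vary
with the stochastic rollouts (≈ 10⁵ training steps). The desk-scale
runs in the tests and acceptance script use 4 epochs — at ~3×10³
minibatch updates per epoch the held-out accuracy is already far above
the 1/13 chance level (≈ 0.6 against ≈ 0.077), which is the sanity
property of interest; squeezing out the last few accuracy points with
the full 2000 epochs adds nothing to that check.

# Analysis statistics

* **Success proportion** `summarize_outcomes()`: captures plus prey
  exits, over episodes; predator exits and timeouts are prey successes,
  so the two sides partition every episode. Reported as mean ± SEM
  across evaluation seeds (100 episodes × 10 seeds at full scale).
* **Independence prediction** `theoretical_prediction()`:
  $H_n = 1-(1-H_1)^n$; observed group success above this curve signals
  synergy between predators.
* **Occupancy heat maps** `heat_map()`: 40×40 equal-width bins over
  $[-1,1]^2$, half-open except the last bin; positions logged at
  action time (always in-arena), with defensive clamping so counts
  always equal logged steps. Map similarity is the product-moment
  correlation of flattened counts (`heatmap_correlation()`), which is
  scale-invariant, so counts vs frequencies is immaterial.
* **Concordance** `concordance_rate()`: for every logged multi-predator
  step, delete the other-predator feature blocks (the prey block sits
  last in the layout precisely so this projection is well-formed),
  query the solo policy greedily, and report the fraction of matches.
* **Circular correlation** `circular_correlation()`: actions 1–12 map
  to angles (a−1)·30°; pairs containing action 13 are dropped. The
  estimator is the angular-deviation product form
  $r = \sum\sin(\theta_i-\bar\theta)\sin(\phi_i-\bar\phi) /
  \sqrt{\sum\sin^2(\theta_i-\bar\theta)\sum\sin^2(\phi_i-\bar\phi)}$
  with circular means, chosen for its rotation invariance and
  reflection antisymmetry; it is isolated behind one function so an
  alternative estimator can be swapped in.
* **Hidden-representation embeddings** `embed_representations()`: the
  two post-ReLU 32-unit stream activations are embedded in 2-D with an
  exact (O(n²)) t-SNE implemented in the package (no t-SNE package is
  available in the target environment): Gaussian affinities calibrated
  to the target perplexity (default 30) by bisection, Student-t
  low-dimensional kernel, early exaggeration and momentum. Coloring
  channels (state value V, SD of Q across actions, predator–prey
  distances) are clipped to their 5th–95th percentiles.
* **Distance-moved shares** `distance_moved_ratio()`: each predator's
  summed path length as a share of the pair's total.

# Numerical and degenerate-input choices

Greedy action selection breaks ties toward the lowest action index;
ε = 0 draws no random numbers, so greedy evaluation is deterministic
given initial positions. When an agent coincides with its reference
opponent the relative frame falls back to the absolute axes. Heading
angles of zero-velocity agents are taken as 0 (so ψ of two resting
agents is 0 → straight pursuit). Simultaneous boundary exits resolve in
agent index order, predators before prey; simultaneous captures credit
the lowest predator index. Weight initialization is fan-in-scaled
uniform on both weights and biases. The C++ learner keeps physics in
double precision and network arithmetic in float32; R-side forwards are
double, and cross-route tests use a 10⁻⁵ tolerance.

# Limitations

The scaled-down training run shows learning *above a random baseline*
in the easiest cell, not the full-scale result grid; the rule-based
role-division statistics are demonstrated against a scripted, not a
co-trained, prey; and the 15-cell grid runner at full-scale settings
(`run_condition_grid()` with the default `learner_config()`) is
provided but takes CPU-days per cell. Obstacles, predator–predator
collisions, more than three predators, multiple prey, and continuous
action spaces are out of scope.
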