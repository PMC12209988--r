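---
title: "Sender and Receiver models for the Tacit Communication Game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sender and Receiver models for the Tacit Communication Game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcgsim)
```

## The game

The Tacit Communication Game (TCG) is a two-player cooperative game on a
rectangular grid. A trial is a *goal configuration*: a start cell `A`, the
Sender's goal `Gs`, and the Receiver's goal `Gr`, all distinct. The Sender
sees all three; the Receiver sees only `A` and `Gs`. The Sender moves a token
from `A` to `Gs` in orthogonal steps, and her whole trajectory — the
*message* `m = [s1, ..., sn]` — is the only channel through which the
Receiver can learn where `Gr` is. Both players score the trial's endowment
(10 points by default) minus one point per Sender step, so good messages are
informative *and* short.

Two quantities of a message matter throughout. Its length `L(m)` counts
states, revisits included; the step cost is `L(m) - 1`. Its unique-state set
`U(m)` ignores revisits, so `|U(m)| <= L(m)` with equality exactly for simple
paths. A trial is *direct* when `Gr` lies on some shortest `A -> Gs` path
(equivalently `d(A, Gr) + d(Gr, Gs) = d(A, Gs)` in manhattan distance) and
*indirect* otherwise.

Messages fall into three recurring shapes, which the classifier
operationalises on revisit structure with precedence wiggly > enter-exit >
pass-by: **wiggly** if `Gr` occurs at least twice, **enter_exit** if any
other state repeats, **pass_by** if the path is simple. The shapes are
described pictorially in the literature; this operationalisation is a
package decision (it classifies the canonical examples of each shape
correctly), and the classifier is the single point to change for sensitivity
analyses.

## Mentalizing Senders and Receivers

The three Theory-of-Mind (ToM) agents *select* a message from the set `M` of
valid messages (start `A`, end `Gs`, pass `Gr`). `M` is infinite, so every
selection works on the truncation to `L(m) <= cap`; the default cap is the
minimal valid length plus 4 extra states, which contains all the shapes
above while keeping enumeration small. Enumeration is exhaustive,
depth-bounded, and ordered lexicographically on move sequences
(north < east < south < west), so uniform draws are reproducible.

* **ToM-0** economises steps: `build_M0()` returns all messages of minimal
  length, and the Sender draws uniformly.
* **ToM-1** models a ToM-0 Receiver, who guesses uniformly among the visited
  states; fewer distinct states mean better odds, so `build_M1()` returns
  all capped messages attaining the minimal `|U(m)|`.
* **ToM-2** models a ToM-1 Receiver, who eliminates states reachable by
  cheaper routes. `build_M2()` first builds the *goal-avoiding* baseline
  (shortest messages that skip `Gr` entirely, found by breadth-first search
  plus exhaustive enumeration at that length), then returns the messages
  that do visit `Gr` with exactly one more unique state than the baseline:
  the surplus state marks the goal.

Two decisions here were genuinely open. First, the minimisers in the set
definitions are read as "minimiser of the stated quantity *within the stated
set*", the only reading under which all the definitions are well-formed.
Second, neither the ToM-1 set nor the ToM-2 marked set is additionally
length-minimised: the uniform draw ranges over every shape achieving the
unique-state optimum (simple sweeps, side trips, zigzags), which is what
produces a mixed emitted-class distribution for ToM-1; a
`tiebreak = "min_length"` switch provides the alternative reading. Because
the cap shapes these sets, session logs record the set sizes so
cap-sensitivity is visible.

Two consequences of the definitions are worth knowing because they are easy
to mistake for bugs:

* On some indirect layouts (e.g. `A = (1,1)`, `Gr = (1,2)`, `Gs = (1,0)`)
  every shortest leg to `Gr` overlaps every shortest leg onward, so *all*
  length-minimal messages revisit a cell and classify enter_exit. A pure
  length-minimiser therefore does **not** emit 100% simple passes over
  unrestricted configuration sweeps (the default study sweep yields 26/30
  simple passes), and any empirical ToM-0 pass-by rate below 1 is expected,
  not a classifier fault.
* On direct trials the ToM-2 marked set can be empty: when `Gr` sits far
  off every short route, no message attains "baseline plus one unique
  state". `build_M2()` signals this and the session harness records the
  trial as a sender failure rather than aborting.

The Receivers invert these strategies. A level-0 Receiver takes the visited
states minus `A` and `Gs` (removed as cells, since sequence positions are
ill-defined under revisits) and guesses uniformly. A level-1 Receiver also
discards any state that lay on some strictly shorter `A -> Gs` walk; a
level-2 Receiver discards states lying on walks with strictly fewer unique
states than observed. Each rule is implemented twice:

* `mode = "union"` enumerates the simulated walks explicitly (up to
  `L(m*) - 1` states, which makes the sets finite) and subtracts the union
  of their states — the defining computation;
* `mode = "closed_form"` removes a state `s` when
  `min_via_states(s) = d(A, s) + d(s, Gs) + 1` is below the observed length
  (level 1) or the observed unique count (level 2).

For level 1 the two are provably identical — a state lies on a shorter walk
exactly when its minimal via-length is shorter — and the suite verifies the
identity exhaustively. For level 2 they are **not** equivalent in general:
a walk through `s` can use fewer unique states than `min_via_states(s)`
whenever its two legs can share cells (the minimal connected set containing
`A`, `s`, `Gs` — a Steiner set — can be smaller than the via-path). The
divergence needs a revisit-heavy observed message, first occurring at
`L(m*) = 7` on the 3x3 board; on simple observed messages the modes agree,
which the suite also verifies. The closed form is the stricter,
better-behaved decoder and is the default; the acceptance suite reports the
exhaustive disagreement count for the union mode rather than hiding it.

Level-2 elimination has a structural blind spot on direct trials: the true
goal lies on cheap routes, so the rule always discards it, and for some
marked messages it empties the candidate set entirely. The decoder then
degrades level 2 -> 1 -> 0 and records the level actually used; abstention
would break accuracy bookkeeping.

## The Surprise Sender

The fourth Sender does not select from a set; it *constructs* the message
step by step by violating expectations. Expectations come from two priors.
The movement prior over relative moves is parameterised by the backward
probability `lambda` and the forward-to-turn odds `gamma`:

    p(back) = lambda
    p(forward) = (gamma / (gamma + 1)) (1 - lambda)
    p(left) = p(right) = 0.5 (1 - gamma / (gamma + 1)) (1 - lambda)

(`gamma` is read as the *ratio* `p(f) / (p(l) + p(r))`, the only reading
under which `gamma = 2` gives the worked values 2/3 and 1/6.) The state
prior weights a cell at manhattan distance `d` from `Gs` by `alpha^-d`.
The action posterior at a state multiplies the movement prior of each
available action by the state prior of its landing cell and normalises over
the on-board actions; off-board actions get zero weight and are dropped
(surprise of an impossible action is undefined). Before the first move there
is no heading, and the movement term is uniform — an alternative (initial
heading toward the goal) would be a one-line change in
`action_posterior()`. The Shannon surprise of an action is
`h = -log2 p(a|s)`.

Planning is a finite-horizon policy tree of depth `horizon`. An edge at
depth `i` scores `base * discount^(i-1) * reward` with the immediate step
undiscounted. While the planned path is still *signalling*, `base` is the
surprise `h` and the reward is the points that would remain under optimal
completion of the remaining task — crucially, while the communicative visit
is pending the completion routes *via the Receiver's goal*:
`endowment - steps - (d(s', Gr) + d(Gr, Gs))`, floored at zero. Without that
routing the planner has no reason to approach `Gr` at all and degenerates
into reversal loops; with it, the worked configuration
(`A=(0,0), Gr=(1,1), Gs=(2,0)`) gives the intended behaviour: at the goal's
neighbour the argmax is the turn *into* the goal, not the prior-favoured
straight move. Once the planned path has completed its visit(s) to `Gr`
*and taken one further, still surprise-scored action leaving it* — the step
that makes a backtracking exit available, and hence the canonical
enter-exit shape — deeper edges switch to the homing rule: state-prior
probability times the plain goal-distance reward. The value of an immediate
action is its edge score plus the best continuation sum (a finite-horizon
backup); an `aggregate = "sum_all_paths"` variant adds the whole subtree
instead, and both compound the discount placement identically under the
default aggregation. Action probabilities are a max-shifted softmax with
inverse temperature `tau`; generation uses deterministic argmax for tests
and seeded softmax sampling for distribution experiments.

Generation mirrors the tree: signalling until the token has visited `Gr`
`switch_after_visits` times (values above 1 permit deliberate goal
wiggling) and taken one exit action, then homing — greedy single-step
state-prior-times-reward, ties broken toward the goal and then in
north/east/south/west order, which guarantees the homing suffix is a
shortest route whenever points remain. A hard budget of `endowment` steps
truncates runaway trajectories; truncated messages are flagged and excluded
from scoring.

The two diagnostic ablations are asymmetric by design. `movement_only`
keeps the expectancy channel but drops the goal-distance prior: with
rewards off the planner chains maximally surprising reversals and fails to
terminate efficiently. `state_only` removes the kinetic expectations — and
with them the entire expectancy-violation channel — so the agent is purely
navigational (probability-following); it walks a minimal direct path with
no unexpected moves and, tellingly, fails to communicate. Making
`state_only` surprise-*seeking* instead would provably wander toward
low-prior cells, contradicting the direct-path diagnostic; the asymmetry is
therefore intrinsic to what each component contributes.

Defaults are `lambda = 0.05`, `gamma = 3`, `alpha = 2`, `tau = 5`,
`discount = 0.9`, `horizon = 2`, `endowment = 10`. These are package
defaults chosen inside the published guidance bands (`lambda` in
[0.001, 0.3], `gamma` in [2, 10]); they are not fitted values, and
parameter files can override any of them.

### A known, measured limitation

Under the literal value `surprise x reward`, surprise is *spatially
unanchored*: a reversal is worth ~5 bits anywhere on the board, while the
reward gradient that should discourage dawdling moves only one or two
points per step. On configurations with slack (endowment minus minimal
completion cost), the argmax planner therefore harvests surprise away from
the goal before entering it: messages remain valid and overwhelmingly
enter-exit/wiggly (365 of 368 on the exhaustive 3x3 indirect sweep), but
the *largest* per-step surprise coincides with a goal entry or exit on only
about a third of layouts. The rate is insensitive to `lambda` across its
band and decreases with deeper horizons (more remote surprise chains become
visible). The acceptance suite asserts the strong per-layout form of the
spike property and reports these violations rather than masking them;
treat the spike as a near-goal-layout property, not a general theorem of
the model.

## The session harness and the synthetic study

`generate_configurations()` defines the study conditions: 20 direct and 10
indirect configurations drawn uniformly without replacement from all
distinct-cell triples of a 3x3 board under a fixed seed. The 3x3 default is
the smallest board expressing all message shapes; the published study sized
sessions at 30 trials with the same 20/10 split, and its exact trial set is
unpublished, so class frequencies should be compared qualitatively, not
digit by digit. `run_session()` plays each configuration with one Sender
model and one model Receiver, shuffles trial order per replication, derives
per-trial RNG substreams from the master seed (the whole artifact set is
byte-identical under a repeated seed), records failures as rows, and
reports both the realised decoding outcome and the analytic uniform-guess
probability `1/|candidates|` (or 0 when elimination discarded the true
goal). Model Receivers stand in for the human partners of the original
task; nothing in the harness estimates human accuracy or reaction times.

What passing tests do show: the agents' set definitions, the elimination
identities, the planner's tree mathematics, and the structural class
patterns (ToM-2 concentrating on enter-exit, ToM-1 mixing classes) under
the synthetic conditions above. What they do not show: anything about
human play — individual parameter fits, reaction times, or the exact
published frequencies, which depend on an unpublished configuration set and
fitted parameters.

## Numerical and scale choices

Enumeration is exact (integer cell ids, bitmask unique-state tracking for
boards up to 30 cells) with an admissible manhattan bound for pruning and a
node budget guarding pathological caps. Probability normalisations are
checked to 1e-12; the softmax is max-shifted. Exhaustive sweeps in the
suite use every distinct triple of the 3x3 board (504 configurations;
13,940 capped messages for the decoder-equivalence sweep), which keeps the
full suite under a minute for the heavy blocks while remaining genuinely
exhaustive at the board size the models were designed for. Larger boards
work throughout but sweeps over them are the user's responsibility.
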