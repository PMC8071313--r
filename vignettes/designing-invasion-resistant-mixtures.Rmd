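---
title: "Designing invasion-resistant seed mixtures: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing invasion-resistant seed mixtures: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Some native plants behave like invaders in their own region: *Jacobaea
aquatica*, a poisonous short-lived perennial of Central European wet
grasslands, spreads fast, becomes overabundant, and contaminates fodder. One
pesticide-free control strategy is to sow grassland communities *designed* to
suppress it: choose species and relative abundances so that the community
either pre-empts the invader's niche (high functional diversity) or matches
its traits (limiting similarity). traitmix implements that design engine, the
community descriptors used to explain suppression, and the inference pipeline
of the accompanying greenhouse-style experiment: two base communities (mesic
and wet grassland), three manipulated traits (plant height, leaf area, seed
mass), twelve designed mixtures, two references (a grass-dominated commercial
mixture and an invader monoculture), six replicate trays each, and three
harvest periods separated by cutting events.

Because the underlying greenhouse data are not deposited in a machine-readable
archive, the package ships a synthetic-experiment generator with the same
layout and the reported effect-sign structure. Every stage of the pipeline is
exercised against that generator or against closed-form oracles.

## Mixture design: constrained maximization of Rao's Q

For a candidate pool of $n$ species (three grasses and five forbs, chosen by
the caller; composition is deliberately not optimized), the design problem is

$$
\max_{p} \; Q(p) = \sum_{i}\sum_{j} p_i p_j d_{ij}
\quad\text{s.t.}\quad \sum_i p_i = 1,\; p \ge 0,\;
\sum_i p_i t_i = t^{\ast},
$$

where $d_{ij} = |x_i - x_j|$ is the pairwise distance on the *diversified*
trait, $t_i$ the *constrained* trait, and $t^{\ast}$ the invader's value on
the constrained trait. $Q$ is Rao's quadratic entropy: the expected trait
distance between two random draws from the community.

Design choices, with reasons:

* **Everything runs on the standardized scale.** Each trait is (optionally
  log-transformed and) centered and scaled to unit sample SD within the
  candidate pool; the invader's target is standardized with the same pool
  parameters. Seed mass and leaf area are log-transformed by default because
  they span orders of magnitude (fractions of a mg to tens of mg; tens to
  thousands of mm²); the toggle is `log_transform`. Plant height is left on
  its natural scale.
* **The constraint is an equality with tolerance `1e-6`.** The study's
  description ("threshold values" set by the invader) is ambiguous between an
  equality and a band; we implement the equality and expose the tolerance, so
  a band can be emulated by relaxing it. A design whose residual exceeds the
  tolerance is flagged `infeasible`, never silently returned.
* **One trait is diversified at a time**, so the distance is 1-D Euclidean;
  Gower-type multi-trait machinery is intentionally out of scope.
* **The solver is a primal active-set quadratic program**, not a generic
  nonlinear optimizer. For a 1-D distance matrix, $D$ is a matrix of negative
  type: $z^\top D z \le 0$ whenever $\sum_i z_i = 0$, so $Q$ is concave on the
  affine set $\{\sum p = 1\}$ and every local maximum on the polytope is
  global. The active-set method starts from a deterministic feasible vertex
  (the two constrained-trait extremes mixed to hit $t^{\ast}$), solves the
  KKT system on the current support, and adds/releases bound constraints until
  the multipliers certify optimality. It terminates in finitely many steps and
  is exactly reproducible: no random starts, no step-size tuning.
* **Abundances below `1e-8` are clipped to zero** and the vector renormalized,
  so downstream sowing plans do not carry solver dust.

### Verification: the feasible-grid oracle

`rao_constrained_oracle()` is an independent brute-force reference: it
enumerates every support subset of the pool and grids the *feasible* polytope
$\{\sum p = 1,\ \sum p_i t_i = t^{\ast},\ p \ge 0\}$ — including each of its
faces and exact vertices — at step 0.001, solving two pivot coordinates in
closed form so that every evaluated point satisfies the equality constraints
to machine precision. Gridding the feasible set rather than the raw simplex
matters: raw simplex grid points essentially never satisfy the CWM equality,
and accepting nearly-feasible points would let the oracle "beat" the true
constrained optimum by the constraint multiplier times the feasibility slack.
Gridding each face separately keeps the comparison honest at boundary optima,
where the full-dimensional grid alone would undersample. On random pools of
2–4 species the solver matches the oracle within $10^{-4}$ in the objective
with residuals at machine precision; the test suite and the acceptance script
re-run this comparison on 50 random pools.

## Community descriptors

* **CWM** is the plain abundance-weighted mean on raw trait units,
  $\sum_i p_i t_i$.
* **Cutting-tolerance update.** Individual species biomass could not be
  separated at harvest in the motivating experiment, so realized abundances
  after each cutting event are estimated by re-weighting the sown abundances
  with the Briemle–Ellenberg cutting-tolerance score $c_i \in \{1,\dots,9\}$
  (5 = unaffected): $p_i' \propto p_i c_i$. We apply the update
  *cumulatively*: period 2 uses one event ($p c$), period 3 two events
  ($p c^2$), because abundance was estimated "after each cutting event" and
  cumulative application realizes the trait-maturation idea; the
  single-multiplication reading is available via `cumulative = FALSE`. The
  update is idempotent under constant $c$ and composes multiplicatively,
  which the tests check as algebraic properties.
* **Faith's PD** is the sum of branch lengths of the minimal subtree
  connecting the community's species, computed directly on the `ape` edge
  table. We adopt the *rooted* convention (the subtree includes the path to
  the tree's root) as the default: it keeps PD strictly monotone under taxon
  addition and nonzero for monocultures; `include_root = FALSE` cuts at the
  MRCA instead, so both conventions are reproducible. PD depends only on the
  species set, never the abundances, so it is constant across periods for a
  fixed mixture. The invader is excluded from all native-community
  descriptors (CWMs and PD are used as predictors of invader biomass, and the
  study's result tables describe the community "without the invasive plant");
  whether the original analysis included it is unknowable from the text, so
  the exclusion is recorded here as our reading.

## Inference

1. **Per-week standardization.** Periods last 10, 15 and 22 weeks; biomass is
   divided by period length before any comparison.
2. **Outlier screen.** Within each mixture × period group (six replicates),
   both per-week biomasses are screened with a two-sided Grubbs test at
   $\alpha = 0.05$, iterated at most twice per group; flagged values are
   replaced by the group mean over the *retained* members. The original
   description does not state sidedness, iteration count, or whether the
   outlier enters its own replacement mean; we default to
   two-sided/iterative/retained-members (a replacement mean that includes the
   outlier would leave its influence in place) and expose all three choices
   (`alpha`, `max_iter`, `mode`). The critical value uses the closed form
   $G_{\mathrm{crit}} = \frac{n-1}{\sqrt n}\sqrt{t^2/(n-2+t^2)}$ with
   $t = t_{\alpha/(2n),\,n-2}$, which the tests pin against a $10^5$-draw
   Monte-Carlo null for $n \in \{4, 6, 10\}$.
3. **Rescaling.** Continuous model inputs are centered and divided by their
   sample SD. The motivating description mentions only the division, but the
   conventional `scale()` default also centers, and centering is almost surely
   what happened; `center = FALSE` reproduces the literal reading. Slope Wald
   statistics are invariant to this choice, which a test verifies.
4. **Mixture comparison.** `invader_pw ~ mixture + period` (period as a
   numeric covariate), an omnibus Wald chi-square over the mixture factor
   (df = levels − 1, i.e. 11 for the twelve designed mixtures), and pairwise
   Tukey contrasts with a compact letter display at family-wise 0.05. The
   multivariate-t adjustment consumes random numbers, so the letters are
   computed under a locally fixed seed and the caller's RNG state is restored
   — this keeps the end-to-end pipeline byte-reproducible.
5. **Predictor model.** `lmer(invader_pw ~ native_pw + cwm_seed_mass +
   cwm_leaf_area + cwm_height + pd_faith + (1|tray) + (1|period))`, each term
   tested with a type III Wald chi-square $(\hat\beta/\mathrm{SE})^2$ on 1 df.
   With only three period levels the period variance component is frequently
   estimated at zero; a singular fit triggers a documented fallback with
   period as a fixed factor (the flag is carried in the result, and the
   continuous-term Wald statistics are coding-invariant). The source text uses
   period both as a random factor and as a covariate in different models; we
   provide both roles (the mixed model above and the fixed-covariate
   comparison model) rather than guessing a single "correct" one, plus
   `fit_treatment_model()` for the factorial treatment structure (community
   type × diversified + constrained, sum-to-zero contrasts).
   The monoculture has no native community, hence undefined predictors: it is
   excluded from the predictor model; the commercial reference has all
   predictors and is included.

## The synthetic generator

`generator_config()` fixes the study conditions: 36 species in 15 families,
split into a mesic and a wet half, each half supplying a 3-grass + 5-forb
design pool; germination Beta-distributed with mean 0.65 and SD 0.218;
log-normal traits (height around 0.5 m, leaf area around 600 mm², seed mass
around 1 mg, the latter two with sdlog 1 so they span orders of magnitude);
cutting tolerances drawn on 1–9 with mid-heavy weights; periods of 10/15/22
weeks and six replicates. The phylogeny is a random coalescent backbone over
families with shallow within-family subtrees (15% of backbone depth), so
confamilials are closer than cross-family pairs — enough structure for PD to
vary meaningfully across mixtures without pretending to reproduce any real
megatree.

Invader biomass per week follows a linear predictor on internally
standardized predictors with the reported sign structure — native biomass
−0.4, CWM seed mass +0.25, CWM leaf area −0.15, CWM height 0, PD +0.2
restricted to period 1 (the PD effect was an early-only signal; a
constant-PD mode exists for null testing) — plus tray and period random
intercepts, Gaussian noise, and truncation at zero (a log-normal response is
available behind `response_dist`). The CWM and PD predictors are centered
and scaled; the native predictor is scaled to unit SD but keeps its natural
zero, so the intercept (default 1.6 g/week) is the invader's
*competition-free* biomass. Native biomass is drawn around 1.33 g/week for
designed mixtures, 2.25 g/week for the commercial reference, and zero for
the monoculture. Two consequences fall out structurally rather than being
pasted in: the monoculture sits at the competition-free baseline and carries
the largest invader biomass in every period (and the grass-dominated
reference the smallest), and making the native coefficient more negative
strictly lowers simulated invader biomass in the mixtures — both of which
the suite asserts. Anchoring at zero is also what makes the second property
possible at all: with a centered native term, the coefficient would not move
the mixture-level mean, and zero-truncation would even push it the wrong
way.

**On noise magnitudes.** Effect signs are anchored to the reported results;
magnitudes and noise are generator choices. We set residual SD 0.25 g/week,
tray SD 0.10 and period SD 0.08 a priori as realistic greenhouse variation on
this biomass scale. Two published desiderata for the defaults — a
"meaningful but not saturated" regime for the strongest term and ≥90% sign
recovery for the weakest — cannot both bind at once: at 80% power for the
native term the implied SE would leave the leaf-area term below 90% sign
recovery. We resolved this in favour of the recovery contract: under the
defaults the weakest term (leaf area, |β| = 0.15) sits in the informative
regime while the native term is effectively always detected.

What the generator does **not** emulate: mechanistic competition or growth
(no resource dynamics, no density dependence), species-level biomass (the
motivating experiment could not separate it either), germination-driven
establishment differences (exposed only as an optional re-weighting hook,
off by default), greenhouse covariates (temperature, irrigation,
fertilization), and any real phylogeny. Passing tests therefore demonstrate
that the *pipeline* is correct and calibrated under its own assumptions, not
that the biological conclusions transfer to new data.

## Numerical and reproducibility choices

* Feasibility of the CWM target is checked with slack `1e-8` on the
  standardized scale; boundary targets return a degenerate design with status
  `"boundary"`.
* KKT systems are solved directly, with a pseudo-inverse fallback for the
  degenerate supports that arise from tied trait values.
* All randomness flows from one run seed through `derive_seed()` (a fixed
  affine map, kept below $2^{31}$), so stages can be re-run in isolation;
  `run_all()` writes an MD5 manifest and two runs with one seed are
  byte-identical, which the suite asserts.
* Simulation sizes in the tests: 50 random pools for the solver-vs-oracle
  comparison, $10^5$ Monte-Carlo draws per sample size for the Grubbs
  calibration, 1000 re-simulated observation sets on a fixed null design for
  Wald calibration (the design is held fixed because calibration is a
  property of the test given the design; regenerating pools each time only
  adds Monte-Carlo noise), and 200 full experiments for sign recovery. These
  sizes give Monte-Carlo standard errors comfortably inside the asserted
  bands.

## Known limitations

* Species selection (which 3 grasses + 5 forbs form a pool) is caller-supplied;
  cardinality optimization is out of scope.
* Only one trait is constrained and one diversified per mixture; simultaneous
  multi-trait constraints are not implemented.
* The tray area default (0.1584 m², a 48 cm × 33 cm tray) papers over an
  internal unit inconsistency in the motivating description (which prints
  "0.158 cm²" and reports biomass per 1.5 dm²); it is a config value, not a
  resolved fact.
* Wald chi-square tests on 1 df are the study's own inferential tool and are
  kept as the contract; with very few clusters for a mixture-level predictor
  they can run mildly anticonservative, which the calibration test bounds
  empirically for the default design.
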