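# hgflearn

Behavioural modelling of a volatile audio-visual associative-learning task
with dual (prediction + perception) reports, for researchers studying
hierarchical Bayesian perception — e.g. predictive-processing accounts of
perception in clinical and neurotypical populations.

In the task, a low or high tone probabilistically announces a clockwise
(CW) or counterclockwise (CCW) rotation of a dot pair. The hidden
tone-rotation contingency reverses every 16, 24 or 32 trials, and one
trial in eight is an ambiguous probe with no objective rotation, so the
reported percept reveals how strongly prior beliefs bias perception.
Participants predict the rotation after the tone and then report what
they saw; runs have 72 trials (nine 8-trial blocks of 6 expected /
1 unexpected / 1 ambiguous trials) and sessions five runs.

## The model

A three-level **Hierarchical Gaussian Filter** tracks the contingency:

- level 1: the trial outcome `u` (1 if the tone-rotation pair is
  congruent with contingency state `c1`), predicted by
  `muhat1 = σ(muhat2)`;
- level 2: the log-odds tendency `mu2` of the association, updated by
  `mu2 = muhat2 + δ1/π2` with `π2 = πhat2 + muhat1(1 - muhat1)` and
  `πhat2 = 1/(σ2 + exp(κ·mu3 + ω2))`;
- level 3: the log-volatility `mu3` of the association, whose update
  uses the volatility weight `w2` and volatility prediction error;
  `ω2`, `ω3` are the tonic log-volatilities (learning rates) of the two
  levels, `κ = 1` the fixed coupling.

Ambiguous probes enter as missing inputs (beliefs frozen). The
tone-conditional CW probability `μ_a` drives the prediction report
(unit-square sigmoid, noise `ν`) and, in the **eight perceptual model
variants** `{0, A, P, S, AP, AS, PS, APS}`, biases the percept: the
posterior CW-percept probability is
`P(θ1) = σ(stimulus evidence + π_a·logit(μ_a) + w_P·s(prev percept) +
w_S·s(prev ambiguous percept))`, with `π_a` the associative-learning
precision and the priming / sensory-memory terms switched per variant.

Each run × variant is fitted by multi-start MAP estimation with a
Laplace log-model evidence; group inference uses random-effects Bayesian
model selection (protected exceedance probabilities,
`PXP = EP·(1−BOR) + BOR/K`) and Bayesian model averaging of the
parameters. Scoring, t tests with Cohen's d, FDR-corrected correlation
families, parameter/model recovery studies and the nine-modulator table
for event-related GLMs (`πhat3, |μhat3|, πhat2, |μhat2|, μ_a` tone-locked;
`|ε3|, |ε2|, |δ_q|, P(θ1)` rotation-locked, with
`δ_q = P(θ1) − y_perception`) complete the pipeline.

## Worked example

```r
library(hgflearn)

sess  <- generate_session(seed = 7)                       # 5 runs, 360 trials
agent <- simulate_agent(sess, hgf_params(omega2 = -1, omega3 = -6),
                        response_params(pi_a = 1.4), model_config("A"),
                        seed = 8)
score_behavior(agent, sess)
#>   prop_correct_prediction prop_ambiguous_congruent prop_correct_perception_unambiguous
#> 1                   0.722                    0.711                                   1

fits <- fit_subject(agent, sess, opts = invert_control(n_restarts = 3, seed = 1))
round(fits$evidence - max(fits$evidence), 2)
#>      0      A      P      S     AP     AS     PS    APS
#>  -4.81   0.00  -7.22  -6.66  -0.75  -0.87 -11.45  -1.41
```

The agent predicts the rotation correctly on 72% of trials and perceives
71% of ambiguous probes in the contingency-congruent direction — the
prior bias the probes are designed to expose. Summed across runs, the
generating variant `A` carries the highest log evidence; its nested
extensions trail by the Occam penalty and the remaining variants by far
more. Trial-wise model quantities export directly for GLM use:

```r
traj <- hgf_filter(hgf_inputs(sess[sess$run == 1, ]), hgf_params())
export_modulators(traj, agent[sess$run == 1, ], sess[sess$run == 1, ])
#>   trial trial_type pihat2 abs_muhat2  mu_a abs_eps2 P_theta1
#> 1     1   expected  4.249      0.000 0.500    0.111        1
#> 2     2   expected  2.797      0.111 0.472    0.155        0
#> 3     3   expected  2.159      0.266 0.566    0.180        1
#> ...
```

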