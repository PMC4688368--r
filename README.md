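# clsecretion

Modeling transcellular chloride secretion in epithelia, and estimating the
activity of the electro-neutral chloride transporter from Ussing-chamber
measurables.

## The problem

Secretory epithelia move Cl⁻ from blood to lumen in two steps: uptake
across the basolateral membrane by an electro-neutral cotransporter
(NKCC1-type) and conductive release across the apical membrane through Cl⁻
channels (CFTR-type), with a third, counterproductive route — conductive
back-flux through basolateral Cl⁻ channels — recycling part of the uptake.
Short-circuit current measurements see only the net result. Two questions
follow that measurement alone cannot answer:

1. When a stimulus changes channel and transporter activities, how does the
   secretion time course decompose into those changes?
2. The uptake transporter carries no net charge, so it is invisible to
   conductance measurements. Can its activation still be quantified?

`clsecretion` answers both with a minimal kinetic model. Intracellular
chloride `f(t)` obeys `Cv·df/dt = J_C − J_A − J_B`, the conductive currents
take the chord form

    I_X = G_X · V · (f − [Cl⁻]o·e^u) / ([Cl⁻]o·(1 − e^u)),   u = FV/RT,

and the uptake flux `J_C = j·CT_Act` follows two-state activation kinetics
with time constant `τ2 = 1/(α+β)`. After a step stimulus the solution is a
biexponential in the conductive time constant
`τ1 = Cv·F·(e^u−1)·[Cl⁻]o / (V·(G_A+G_B))` and `τ2`. At steady state the
model inverts: six measurables (baseline and stimulated apical current, and
the four blocker-sensitive conductances) determine the transporter's
fold-activation,

    J_C(∞)/J_C0 = [I_A(∞)·(G_A∞+G_B∞)/G_A∞] / [I_A0·(G_A0+G_B0)/G_A0].

The package provides the closed-form simulator (`analytic_solution()`), an
independent stiff-ODE twin (`integrate_protocol()`), eight canned
stimulation scenarios (`build_scenario()`, `list_scenarios()`), the
measurement-side toolkit (`conductance_from_pulse()`,
`nppb_sensitive_conductance()`, `estimate_transporter_activation()`,
`fit_biexponential()`), synthetic-data generators with seeded noise, ggplot2
`autoplot()` methods, and a command-line interface
(`inst/exec/clsecretion`).

## Worked example

A genistein-like stimulus: apical conductance ×5, basolateral ×4, uptake
eventually ×3.

```r
library(clsecretion)
tis <- tissue_params()                      # A6 monolayer defaults
prot <- build_scenario("genistein", tis)
scenario_summary(prot, tis)
#> # A tibble: 1 × 10
#>   name      fold_initial fold_steady tau1_pre_s tau1_post_s tau2_s cl0_mM
#> 1 genistein            5        3.72       304.        75.5   755.   32.0
#>   cl_inf_mM i_a0_uApercm2 i_a_inf_uApercm2
#> 1      30.7          0.08            0.298
```

Secretion jumps 5-fold the instant the apical conductance rises (the jump
depends on `G_A` alone), dips as intracellular chloride (initially ~32 mM)
is depleted with `τ1 ≈ 75 s`, then rises to a 3.72-fold steady level as the
transporter activates with `τ2 = 10·τ1 ≈ 755 s`. Fitting the trace recovers
the programmed components:

```r
tr <- analytic_solution(tis, prot)
fit_biexponential(tr)
#> <biexp_fit>
#>      y_inf         A1       tau1         A2       tau2
#>   0.297600   0.322844  75.473560  -0.220444 754.735602
#> components: 2, sigma = 9.52e-17, R^2 = 1
```

And the estimator recovers the invisible transporter's activation from the
bundled reference measurement set (a forskolin-stimulated A6 monolayer):

```r
f <- system.file("extdata", "forskolin_ussing_measurement.tsv",
                 package = "clsecretion")
cli_estimate(f)
#> inputs: I_A0=0.08 I_Ainf=6.4 G_A0=12.87 G_B0=360 G_Ainf=689.04 G_Binf=480.47
#> activation_fold=4.69
```

A 4.7-fold activation of NKCC1, obtained without ever measuring a
transporter current.

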