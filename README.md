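# tumorpkpd

Mechanistic pharmacokinetic–pharmacodynamic (PK/PD) modelling of breast
tumor growth under targeted peptide therapy and ligand-directed suicide
gene therapy with ganciclovir (GCV).

The package is aimed at quantitative pharmacologists and systems
biologists who want to (i) simulate tumor response to a
macrophage-targeting peptide given as a bolus, an infusion, or displayed
on a gene-delivery vector combined with GCV; (ii) calibrate the model
sequentially against longitudinal cohort measurements; and (iii) run
in-silico experiments — a bolus-versus-infusion trial projection and a
sensitivity analysis of the peptide–receptor dissociation constant.

## The model

Tumor volume V (mm³) follows a balance of logistic growth against two
drug-induced death processes,

    dV/dt = G − S − N
    G = σ·V·(1 − V/K)                      logistic proliferation
    S = V·D_pep·C_pep/(C_pep + K_d)        saturable peptide kill
    N = V·λ·C_GCV                          GCV kill (vector arms only)

coupled to one-compartment pharmacokinetics: first-order renal clearance
of the iv peptide (C(t) = C₀·e^(−kex·t), with distinct rates for the
vector-displayed and soluble forms), first-order peritoneal absorption
plus renal excretion for ip GCV (the Bateman function), and a
constant-rate infusion option dC/dt = μ·kex − kex·C whose asymptote is
the infusion constant μ. Doses are impulsive state jumps (vector bolus
0.8 mM on day 5; daily ip GCV 0.008 mg/mm³ — 80 mg/kg in a 20 g mouse —
on days 12–21). Competitive antagonism by active vitamin D is represented
implicitly through K_d. The methods vignette
(`vignettes/tumor-pkpd-model.Rmd`) derives every term, documents the
reference parameter set and which of its entries are placeholders, and
discusses identifiability.

## Worked example

Simulate the projected patient trial, probe the dissociation constant,
then generate a noisy synthetic cohort (10 subjects per arm, 10%
multiplicative noise) and recover the parameters by sequential
calibration:

```r
library(tumorpkpd)
params <- default_parameters()

compare_bolus_vs_infusion(params, mu = 0.75, horizon = 60)
#> $difference_mm3
#> [1] 401.2847        # infusion arm ends ~400 mm^3 smaller than bolus
#> $v_bolus
#> [1] 9996.989
#> $v_infusion
#> [1] 9595.704

kd_sensitivity(params)
#>   perturbation   Kd final_volume_mm3
#> 1         -0.2 0.60         9551.088   # stronger binding, more kill
#> 2          0.0 0.75         9595.704
#> 3          0.2 0.90         9632.204   # antagonism weakens the therapy

coh <- generate_cohort(params, n_subjects = 10, seed = 1)
pk  <- generate_gcv_pk_samples(params$ka_gcv, params$kex_gcv,
                               noise = noise_model(scale = 0.05), seed = 2)
cal <- sequential_calibration(coh, pk_data = pk, seed = 1)
cal$stages$growth_rate
#> Fit stage 'growth_rate': RSS = 1.076e+04
#>   sigma        0.194645        # generator used sigma = 0.2
cal$stages$gcv_death
#> Fit stage 'gcv_death': RSS = 1.407e+04
#>   lam          65.4827         # generator used lambda = 60
cal$quality
#> pooled Pearson R = 0.9982 (p = 2.8e-28, n = 24)

half_life(38)
#> [1] 26.26663       # minutes: the soluble peptide is cleared within hours
```

The fitted growth rate and GCV kill constant land within a few percent of
the generating values despite 10% measurement noise; the pooled Pearson
correlation between model predictions and observed per-day arm means
summarises overall agreement. `run_pipeline()` chains these steps
(synth → fit → simulate → trial → sensitivity → report) from a single
YAML config and seed, and `inst/cli/tumorpkpd.R` exposes the same stages
from the shell.

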