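# contactdose

Electro-quasi-static dosimetry for electric contact currents (DC to 1 MHz)
on labeled voxel body phantoms, in R.

When a body part touches an energized conductor, a contact current flows
through the body; the risk of ventricular fibrillation scales with the
electric field the current induces in the ventricular myocardium, and that
field depends strongly on the current path. Safety standards encode the
path dependence as *heart current factors* (HCFs). `contactdose` implements
the full numerical chain behind such factors, for engineers and researchers
in electrical-safety dosimetry:

* a **parametric synthetic voxel phantom** (closed skin envelope,
  subcutaneous fat, isotropic longitudinal-conductivity skeletal muscle,
  bone, lungs, a ventricular-myocardium shell around a blood lumen, and
  blood-vessel channels connecting arms and lower trunk to the heart — the
  structure responsible for current channeling), plus NIfTI import for
  licensed anatomical models;
* a **tissue dielectric table** with Cole–Cole dispersion,
  `σ*(f) = σ(f) + j·2πf·ε₀·εᵣ(f)`;
* the **two-body-model contact framework**: regime classification by
  frequency and touch voltage (Total-BM with a 2-mm voltage-dependent skin
  slice at the contact vs. Intern-BM with the skin removed), and
  least-squares fitting of skin-slice properties to reference |Z| curves;
* a **finite-volume electro-quasi-static solver** for
  `∇·(σ*∇φ) = 0` with Dirichlet electrodes (harmonic-mean face
  admittances; sparse Cholesky at DC, preconditioned conjugate-orthogonal
  CG for the complex-symmetric system at AC);
* **dose post-processing**: total body current from cross-section surface
  integrals, body impedance via Ohm's law, the 99th-percentile myocardial
  field `E99Heart`, three orthogonal trans-cardiac line integrals
  (`E_Sam`), and HCF tables

  `F(p, f) = [E(p,f) / |I_Body(p,f)|] · [|I_Body(LH-BF,f)| / E(LH-BF,f)]`

  over the 16 standard current paths at DC, 50 Hz, 1 kHz, 10 kHz and
  100 kHz.

## Worked example

```r
library(contactdose)

ph      <- build_phantom(phantom_config())   # 4 mm synthetic body
tissues <- default_tissue_table()
scen    <- contact_scenario("LH-BF", frequency = 50,
                            touch_voltage = 100, mode = "INTERN")
sol  <- solve_scenario(ph, tissues, scen)
sol
#> <field_solution> path LH-BF @ 50 Hz, INTERN mode, U_t = 100 V
#> residual 2.77e-10 after 6 iteration(s) [cocg]

compute_dose(sol)[, c("i_body_a", "z_total_ohm", "e99_heart",
                      "e_sam", "current_spread")]
#>   i_body_a z_total_ohm e99_heart   e_sam current_spread
#> 1   0.0921    1086.305   75.0925 32.8089              0
```

A 100 V left-hand-to-both-feet contact at 50 Hz drives 92 mA through the
body (internal impedance ≈ 1.09 kΩ — the skin layer is excluded in
Intern-BM mode). The 99th percentile of |E| over the ventricular
myocardium is 75 V/m; the trans-cardiac line-integral estimate, which
averages over the heart the way cadaver voltage probes did, is smaller
(33 V/m) because it cannot see local hot spots. The cross-plane current
spread (the conservation diagnostic over four surface integrals) is at
rounding level.

The voltage-dependent contact-skin properties used by the Total-BM:

```r
skin_props(c(25, 100, 220))
#>   touch_voltage   sigma  eps_r
#> 1            25 0.00014  24000
#> 2           100 0.00027  64000
#> 3           220 0.00085 132000
```

Campaigns chain the whole pipeline — `campaign()` + `run_campaign()`
enumerate paths × frequencies × voltages, pick the body model per the
frequency/voltage regime table (HCF campaigns force Intern-BM), and return
tidy dose and HCF tables with `autoplot()` methods and idempotent on-disk
caching.

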