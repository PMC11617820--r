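# dermtex

Silver-nanoparticle (Ag NP) coatings make textiles antimicrobial, but the
particles leach onto the skin during wear, and the lowest derived-no-effect
level for nano-silver (0.01 mg/kg-bw/day) is small enough that even modest
exposures deserve quantitative assessment. `dermtex` is an R package for
exposure scientists and risk assessors that turns bench release experiments
into wear-scenario risk estimates:

1. **Release estimation** — first-order release-rate constants from
   abrasion, sweat-immersion or washing experiments,
   `k = -(1/t) ln(1 - m_x/m_0)`, with replicate aggregation.
2. **Mass-balance simulation** — the skin-surface compartment
   `dm/dt = S_p(t) - (k_sc + k_o + k_ww) m(t)` with a first-order donor
   textile `S_p(t) = k_p m_p0 e^(-k_p t)`, integrated with a fixed-step RK4
   scheme that conserves total mass across textile, skin surface, stratum
   corneum, oral and wear/wash compartments to ~1e-15 relative.
3. **Risk characterisation** — body-weight-normalised daily intake against
   a DNEL: `RCR = (intake / bw) / DNEL`, for the stratum-corneum and
   inadvertent-oral routes.

Bundled measurements parameterise three coated textile families (AgCur,
AgHEC6.4, AgHEC: 15 batches, 849–2651 ng-Ag/cm²), five skin preparations
(Franz-diffusion-cell fluxes for fresh, cryopreserved, glycerolized,
intact and damaged human skin grafts), and standard wear scenarios (555 cm²
face mask, 20 000 cm² full body, gloves with fingertip mouthing). A
synthetic-data generator produces release experiments with known ground
truth for validating parameter recovery.

## Worked example

```r
library(dermtex)

# abrasion release constants per coating family (10-s crock-meter tests)
fit_release_rates(abrasion_release_data())$by_family
#>     family n k_mean   k_sd fraction_mean fraction_sd
#> 1    AgCur 6 0.0863 0.0240        0.0143     0.00394
#> 2 AgHEC6.4 6 0.1228 0.0337        0.0202     0.00551
#> 3    AgHEC 3 0.1531 0.0476        0.0252     0.00774

# 8-h face-mask wear on glycerolized (necrotic-like, worst-case) skin
mask <- face_mask_scenario("AgCur", "glycerolized")
traj <- simulate_exposure(mask)
traj
#> Mass trajectory 'AgCur face mask, glycerolized skin, 8-h wear': 4801 time points over 480 min (dt = 0.1 min)
#>   m_p0 = 849150 ng; conservation residual 3.43e-15
#>   at horizon: textile 1.003e-12, skin 8.489e+05, sc 225.3, oral 0, ww 0 ng

rcr(sc_intake(traj))
#> Risk result (stratum_corneum route):
#>   intake: 225.3 ng/day = 3.756 ng/kg-bw/day
#>   RCR = 0.00038 (DNEL 0.01 mg/kg-bw/day)
```

Reading: of the 849 µg of silver initially on the mask, essentially all
leaves the textile within the first hour (`k_p = 0.086` 1/min ⇒ 99 % in
60 min), but only 225 ng crosses into the stratum corneum over 8 h even
through the most permeable skin preparation — an RCR around 4e-4, far
below the risk threshold of 1. For fresh healthy skin the intake drops to
~12 ng (0.0014 % of the load).

File-based workflows mirror the same functions: `run_scenario_file()`
simulates a YAML-configured scenario (example in
`inst/extdata/face_mask_fresh.yaml`) into trajectory/risk CSVs plus a run
manifest, `fit_k_file()` estimates constants from a release-experiment
CSV, and `inst/cli/dermtex.R` exposes both from the shell.

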