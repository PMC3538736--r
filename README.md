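# renperf

Quantitative renal blood flow (RBF) mapping from two perfusion-MRI
modalities, and the statistics to compare them.

Renal cortical perfusion drops sharply in acute kidney injury (AKI), so a
reliable non-invasive perfusion readout is a diagnostic tool in its own
right. Two MRI techniques provide one: **arterial spin labelling (ASL)**,
which needs no contrast agent (important when gadolinium is
contraindicated), and **dynamic contrast-enhanced (DCE) MRI**, the more
established bolus-tracking approach. `renperf` is for researchers who want
to quantify both, compare them in a paired (left/right kidney) design, and
validate every processing step against synthetic ground truth.

## What it computes

**FAIR ASL** (flow-sensitive alternating inversion recovery): frames are
averaged by magnetic preparation (equilibrium `M0`, slice-selective control
`ssIR`, non-selective tag `nsIR`), the perfusion-weighted difference
ΔM = ssIR − nsIR is formed, and perfusion follows the single-compartment
model, pixel by pixel:

    f = 6000 · λ · ΔM · exp(TI/T1) / (2 · M0 · TI)   [ml/100 g/min]

with partition coefficient λ = 0.8 ml/g, tissue T1 = 1.14 s and inversion
time TI = 1.2 s.

**DCE-MRI**: after subtracting the 15-volume pre-contrast baseline and
truncating to the bolus first pass (50 volumes at 0.9 s), the tissue curve
C_T is deconvolved against the aortic arterial input function C_A through
the discrete system

    C_T = A · h,   A[i,j] = dt · C_A[i−j+1]   (truncated SVD),

and RBF is the peak of the tissue impulse response, f = 6000 · max h.

**Statistics**: healthy/diseased group summaries, two-sided paired t-tests,
Bland–Altman limits of agreement (mean ± 1.96 population SD), left/right
RBF ratios and repeated-scan summaries.

**Synthetic phantom**: a two-kidney digital slice with known cortical,
medullary and aortic compartments; the ASL simulator is the exact algebraic
inverse of the quantification formula and the DCE simulator uses the same
rectangle-rule convolution the solver assumes, so noise-free round trips are
exact and noisy recovery is a meaningful test.

## Worked example

```r
library(renperf)

truth <- make_phantom(phantom_spec())   # 128x128, left-sided injury
asl   <- simulate_asl(truth)            # 90 frames: 30 tag/control pairs + 30 M0
map   <- asl_quantify(asl)

roi_mean(map, truth$cortex_left)        # 316
roi_mean(map, truth$cortex_right)       # 416

dce <- simulate_dce(truth)              # 50 volumes, dt 0.9 s, 3 slices
dce_roi_rbf(dce, truth$cortex_left,  truth$aorta)   # 316
dce_roi_rbf(dce, truth$cortex_right, truth$aorta)   # 416
```

Both chains recover the ground-truth cortical perfusion (316 diseased / 416
healthy, ml/100 g/min) exactly on noise-free input; set
`phantom_spec(noise_sigma = 0.3)` for realistic frame noise.

The statistics stage reproduces the packaged per-animal tables:

```r
rep <- table_report(read_rbf_table(), read_repeats_table())
# ASL: diseased 316 +/- 102, healthy 416 +/- 124 ml/100 g/min, p = 0.34%
# mean difference 147 +/- 47, limits of agreement [55, 240] (zero excluded)
rep$ASL$lr_ratios
#    1    2    3    4    5    6
# 0.97 0.72 0.56 0.57 0.81 0.73
```

## Analysis workflow

The `analysis/` scripts run the full study as numbered steps, writing all
artefacts under `results/`:

    Rscript analysis/01_simulate.R        # phantom + both series (NIfTI + CSV)
    Rscript analysis/02_quantify_asl.R    # ASL RBF map + cortical ROI summary
    Rscript analysis/03_quantify_dce.R    # DCE RBF map, AIF, ROI summaries
    Rscript analysis/04_agreement_stats.R # t-tests, Bland-Altman, ratios, plots
    Rscript analysis/05_validation.R      # round-trip and Monte-Carlo checks

Equivalently, `run_pipeline(run_config(), out_dir)` chains
simulate → quantify → compare in one call; a YAML configuration template
ships at `inst/extdata/config.yaml`.

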