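# smstoich

Single-molecule brightness stoichiometry for membrane-protein oligomers.

`smstoich` infers how many subunits make up each fluorescently tagged protein
complex imaged by single-molecule TIRF microscopy. Diffraction-limited spots on
a supported lipid bilayer are detected and photometered; the spot-brightness
distribution is decomposed into integer multiples of a calibrated
single-fluorophore brightness; and the resulting label-count fractions are
corrected for partial fluorophore labeling (a subunit carries a mature
fluorophore only with probability *p*, so trimers appear as 1-, 2- or 3-step
spots and some particles are entirely dark). The package also ships a synthetic
movie generator with a full EMCCD noise model and ground truth, single-particle
track linking with mobile/immobile classification, particle-density
quantification, and the calcein-release statistic for liposome leakage assays.

The methods vignette (`vignettes/methods.Rmd`) documents the image-formation
model, every algorithm, parameter defaults and rationale, and limitations.

## Worked example

Simulate a 50/50 dimer/trimer field under the reference acquisition conditions (100 nm pixels,
EMCCD offset 170 / EM gain 65.4, 30 ms frames, labeling probability 0.7) and
run the full analysis:

```r
library(smstoich)

sc <- generate_scene(scene_config(field_size_um = 25.6, n_emitters = 260,
                                  oligomer_fractions = c(0, 0.5, 0.5),
                                  labeling_p = 0.7, min_separation_nm = 800),
                     seed = 11)
mv  <- render_movie(sc, n_frames = 200, seed = 12)

# monomer calibration normally comes from calibrate_monomer() on a
# purified-fluorophore movie; here we pass the known simulation truth
cal <- structure(list(mu1 = 300, sigma1 = 75, n_particles = 1000L),
                 class = "monomer_calibration")

res <- run_pipeline(mv, calibration = cal)
#> [input] 200 frames of 256 x 256 px
#> [detect] detected=245 accepted=245 rejected=0
#> [density] 245 particles / 655.4 um^2 = 0.3738 per um^2
#> [stoich] n=245 rms misfit=5.98e-05

round(res$stoich$observed_fractions[1:4], 3)   # label counts k (what you see)
#>     1     2     3     4
#> 0.324 0.570 0.106 0.000
round(res$stoich$corrected_fractions[1:4], 3)  # oligomer orders n (the answer)
#>     1     2     3     4
#> 0.000 0.647 0.353 0.000
```

The correction removes the monomer-looking spots (singly labeled dimers and
trimers) entirely. With only ~245 particles the corrected fractions scatter
around the true 0.50/0.50; at full scale (1500 frames, ≥ 1500 accepted
particles) they recover the truth to within ±0.07 (see the acceptance tests).

Mobility analysis runs per frame instead of on the frame average:

```r
res <- run_pipeline(mv, config = pipeline_config(max_disp_px = 6),
                    run_stoich = FALSE, run_track = TRUE)
res$mobility$percent_immobile
```

A command-line interface with `simulate`, `detect`, `track`, `stoich`,
`leakage` and `run` subcommands is installed at:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "smstoich.R", package = "smstoich"))')" \
    simulate --seed 3 --out /tmp/demo --field-um 12.8 --n-emitters 40 --n-frames 50
```

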