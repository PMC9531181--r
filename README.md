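# tirfdwell

Single-molecule TIRF dwell-time analysis for substrate capture by
surface-immobilized AAA+ unfoldases (ClpX), with a ground-truth movie
simulator, bulk degradation / ATPase kinetics, and compositional
sequence-complexity scoring.

## The problem

When a degron-tagged substrate is captured by coverslip-anchored ClpX
under TIRF illumination, it appears as a diffraction-limited fluorescent
punctum that survives until the substrate dissociates.  With unfolding
blocked (methotrexate-stabilized DHFR), dissociation is the only exit, so
punctum lifetimes are exponential and their mean τ measures how firmly
the pore grips a given substrate tail sequence.  The analysis chain is:

1. **detection** — scale-normalized Laplacian-of-Gaussian blob search per
   frame, sub-pixel refinement with the 2D Gaussian
   `I(x,y) = A·exp(−((x−x₀)²/2σₓ² + (y−y₀)²/2σᵧ²)) + b`, and rejection of
   over-bright (aggregate) or non-circular fits;
2. **tracking** — greedy nearest-neighbour linking of detections into
   traces with a 3-frame gap tolerance (blinking), then four censoring
   filters: movie-boundary traces, single-frame traces, births within
   1 μm of a concurrent trace, and repeated use of the same site;
3. **dwell model** — dwells under 120 s are compiled into an ECDF at
   unique dwell values and fitted with `F(t) = 1 − e^(−t/τ) + c`,
   |c| ≤ 0.025, by least-absolute-residual regression (IRLS with a
   simplex fallback);
4. **bulk kinetics** — photobleach-corrected degradation
   (`F(t) = −k·t + B` on `(F_t/F₀)/(F_t^ctrl/F₀^ctrl)`), NADH-coupled
   ATPase rates (`rate = ΔAbs340/Δt / (6.22·lightpath)`, pathlength
   calibrated from an NADH standard), and the ATP cost
   `= ATPase rate / degradation rate`;
5. **sequence complexity** — the SEG-style entropy score
   `K = −Σ (nᵢ/L)·log₂(nᵢ/L)` in bits over the 20-letter amino-acid
   alphabet, classified low/high at 2.5 bits.

No raw imaging data are publicly deposited for this kind of experiment,
so the package ships a simulator (`simulate_movie()`, `simulate_plate()`)
that generates movies and plate tables with the statistical structure the
analysis assumes — Poisson arrivals, exponential dwells, Gaussian PSFs
over Poisson + read noise, capped blinking — with the ground truth
attached, making every stage testable end to end.

## Worked example

The numbered scripts under `analysis/` run a complete demonstration and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate_movie.R      # synthetic 256 px, 300 frame movie
Rscript analysis/02_detect_and_track.R    # detections -> traces -> dwells
Rscript analysis/03_fit_dwell_model.R     # ECDF + exponential fit
Rscript analysis/04_bulk_kinetics.R       # degradation, ATPase, ATP cost
Rscript analysis/05_sequence_complexity.R # tail motif complexity table
```

The demonstration movie holds 161 true events with mean dwell 10 s.  The
pipeline reports:

```
detections: 1509 candidates, 1507 kept
traces: 154 linked, 126 kept   (boundary 7, concurrent 9, single_frame 12)
dwell ECDF: 126 events (0 truncated), 29 unique values
exponential dwell fit: tau = 10.530 s, c = +0.0060, r2 = 0.9790 (n = 126)
```

i.e. τ is recovered to +5% (a one-frame quantization inflation analysed
in the methods vignette), with the fit quality (r² > 0.97) typical of
exponential dwell ECDFs at replicate scale.  The kinetics step prints

```
degradation k: 0.0197 +/- 0.0005 /min   (true 0.02)
calibrated pathlength: 0.2999 cm        (true 0.30)
ATPase: 0.0100 mM/min -> 100.5 ATP/min/hexamer
ATP cost: 509 ATP per substrate degraded
```

and the complexity step classifies the benchmark tail motifs:

| motif  | sequence    | score (bits) | class |
|--------|-------------|--------------|-------|
| Ref11  | GLGARSAGITH | 2.85         | high  |
| GA11   | AGAGGAAGAGG | 0.99         | low   |
| GS11   | SGSGGSSGSGG | 0.99         | low   |
| SUMO11 | AKPSTEDLGDK | 3.10         | high  |
| polyG11| GGGGGGGGGGG | 0.00         | low   |

Scrambled and reversed variants of SUMO11 score identically — the measure
depends only on composition.

See `vignettes/dwell-time-analysis.Rmd` for the models, parameter
defaults, numerical choices, and known limitations (including the
one-frame dwell inflation and the 120 s truncation bias).

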