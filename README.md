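# fdflim

Analysis tools for **widefield frequency-domain fluorescence lifetime
imaging (FD-FLIM)** of metabolic autofluorescence (NADH, FAD), built for
researchers who need a transparent, fully testable alternative to vendor
FLIM software — from raw phase-stepped homodyne image stacks to
calibrated lifetime maps, masked summaries, photon-economy figures of
merit, resolution measurements and cross-group statistics. A
ground-truthed synthetic-data generator stands in for the microscope, so
every stage of the pipeline is verifiable at desk scale.

## The model

Under intensity-modulated excitation at frequency *f* (ω = 2π·f), a
fluorophore's emission is phase-delayed and demodulated. Per pixel, the
two independent lifetime estimates are

    tan Φ = ω·τ_Φ           (phase lifetime)
    m = 1 / sqrt(1 + (ω·τ_m)²)   (modulation lifetime)

In the phasor representation (G, S) = (m·cos Φ, m·sin Φ),
monoexponential decays lie on the universal semicircle G² + S² = G and
mixtures lie on chords, with intensity-weighted fractions as linear
coordinates. The pipeline:

1. **simulate** — homodyne forward model: frame k expectation
   I·L·[1 + m_inst·m·cos(θ_k − Φ − φ_inst)], Poisson shot noise,
   vignetting, Gaussian PSF, solution/edge/cell-scene phantoms with
   ground truth in metadata;
2. **demodulate** — exact first-harmonic DFT projection over K ≥ 3
   uniform phase steps;
3. **calibrate** — reference a fluorophore of known lifetime
   (fluorescein, 4.0 ns) to cancel the instrument response, convert to
   τ_Φ / τ_m maps with NA sentinels for nonphysical pixels;
4. **mask & summarize** — flat-field normalization, Otsu foreground
   masks, image-level mean ± SD, and the photon-economy F-score
   F = (Δτ/τ)/(ΔI/I) (ideal shot-noise-limited system: F = 1);
5. **resolution** — ESF → LSF → FWHM from a line profile across a
   light-dark edge;
6. **group stats** — image-level one-way ANOVA with Tukey-Kramer post
   hoc tests (α = 0.05).

## Worked example

Simulate a free/bound NADH solution phantom (bound fractional intensity
0.6) at 20 MHz with 25 phase steps, calibrate against a noiseless
fluorescein reference, and summarize:

```r
library(fdflim)

acq  <- flim_acquisition()                 # 20 MHz, 25 phases, 4.0 ns reference
inst <- flim_instrument(phase_offset = 0.6, mod_factor = 0.8)

ref <- reference_stack(acq, inst, photons = 400, dim = c(64, 64),
                       noiseless = TRUE)
smp <- simulate_stack(uniform_scene(nadh_mixture(0.6), 400, c(64, 64)),
                      acq, inst, seed = 1)
rec <- flim_reconstruct(smp, ref)
summary(rec, mask = "all")
#> <masked_summary> NADH, 4096 px
#>   tau_phi 1.6108 +/- 0.1513 ns   tau_mod 2.1335 +/- 0.4987 ns
#>   intensity 400 +/- 4.014 counts
#>   F-score: phase 9.359, modulation 23.29
```

The phase lifetime (1.61 ns) sits below the modulation lifetime
(2.13 ns) — the frequency-domain signature of a two-component decay —
and both match the generating mixture (true τ_Φ = 1.613 ns,
τ_m = 2.185 ns) within shot noise. The phase channel's smaller F-score
shows it is the more photon-efficient estimate. The bound fraction can
be read back off the phasor chord:

```r
cal <- calibrate(demodulate(smp), demodulate(ref))
phasor_chord_fraction(mean(cal$g, na.rm = TRUE),
                      mean(cal$s, na.rm = TRUE), c(0.4, 2.5), 20e6)
#> [1] 0.5984074
```

A command-line surface over the same functions lives at
`inst/cli/fdflim.R` (`simulate | reconstruct | resolution | stats |
pipeline`).

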