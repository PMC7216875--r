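# mtellipse

Quantitative magnetization transfer (qMT) mapping from phase-cycled
balanced SSFP data, using the elliptical signal model — no external T1
map, no banding artifacts.

MRI physicists and neuroimaging researchers use qMT to probe the
macromolecular (myelin-associated) proton pool that conventional images
cannot see. Balanced SSFP is attractive for this because it is fast and
MT-sensitive, but at 3T its signal is confounded by off-resonance.
Sweeping the RF phase increment φ turns that confound into signal: the
complex data trace an ellipse in θ = ψ + φ,

    M(θ) = M_E (1 − a e^{−iθ}) / (1 − b cos θ) · e^{i(ψ/2 + φ_RF)},

and with magnetization transfer between the free water pool and a bound
pool included in the two-pool Bloch–McConnell steady state, the ellipse
parameters become

    M_E = M0f E2f (B(1−E1f)+C) sin α / (A − B E1f cos α − E2f² (B E1f − A cos α)),
    a   = exp(−TR/T2f),
    b   = E2f (A − B E1f)(1 + cos α) / (A − B E1f cos α − E2f² (B E1f − A cos α)),

where A, B, C collect the exchange (k_bf, k_fb), bound-pool relaxation
(E1b) and RF-saturation (exp(−W·TRF), W = π G0 (p2/p1²) α²/TRF²) terms.
Only M_E and b carry MT weighting; `a` is MT-blind. Acquiring several
ellipses at different flip angles α and pulse durations TRF therefore
lets a two-stage fit recover the full parameter set — free-pool proton
density M0f, bound-pool fraction f_b, exchange rate k_bf, T1f and T2f —
from SSFP data alone:

1. **Stage 1** (`fit_ellipse`): per-ellipse bounded nonlinear least
   squares for (M_E, a, b, ψ, φ_RF) on the complex samples, with an
   exact verticality constraint, multi-start initialization and a Huber
   loss.
2. **Stage 2** (`estimate_t2f`, `fit_qmt`): T2f in closed form from the
   `a` values, then a bounded fit of (M0f, f_b, k_bf, T1f) to the
   mean-scaled M_E and b series, with T1b = T1f.

The package also provides the forward model in three cross-checked
forms (per-TR matrix recursion, matrix-inverse steady state, closed
form), a Monte Carlo validation harness, a 3D digital phantom with
banding and B1+ variation, voxelwise NIfTI fitting, and a CLI.

## Worked example

One simulated voxel at the validation conditions (WM-like tissue, four
MT weightings, SNR ≈ 70):

```r
library(mtellipse)
tis   <- tissue_params()        # M0f = 100, T1f/T2f = 1100/80 ms, fb = 10%, kbf = 4.45 /s
proto <- default_protocol()     # α = 15,15,30,30°; TRF = 256,1024,256,1024 µs; TR = 7/7.768 ms

samples <- draw_realization(mc_config(seed = 7), psi = 0.8, phi_rf = -0.3)
fits <- lapply(seq_along(proto$settings), function(i) {
  s <- proto$settings[[i]]
  fit_ellipse(samples[i, ], s$phase_increments, s$tr, s$alpha)
})
fits[[1]]
#> <ellipse_fit> M_E = 8.451, a = 0.9128, b = 0.7068, psi = 0.804, phi_rf = -0.300 |
#>   rmse = 0.221 (2.61% of M_E), converged

a  <- sapply(fits, function(f) f$params$a)
me <- sapply(fits, function(f) f$params$me)
b  <- sapply(fits, function(f) f$params$b)
t2f <- estimate_t2f(a, sapply(proto$settings, `[[`, "tr"))
fit_qmt(me, b, proto$settings, t2f)
#> <qmt_fit> M0f = 98.85, fb = 6.32%, kbf = 12.9 /s, T1f = 1056 ms, T2f = 79.39 ms |
#>   cost = 9.37e-05
```

The stage-1 fit pins the ellipse to better than 1% despite the noise
and recovers the off-resonance (ψ = 0.804 vs 0.8 true) and transmit
phase exactly enough that neither needs an external map. The stage-2
output illustrates the one genuinely hard direction of this protocol: a
single noisy voxel slides along the f_b–k_bf trade-off ridge (here to
6.3% / 12.9 s⁻¹ from the true 10% / 4.45 s⁻¹) while M0f, T1f, T2f stay
tight; averaged over thousands of realizations the f_b and k_bf medians
are exact but their dispersion is large. That ridge is an information
limit of the long-TR protocol, not a solver artifact — see the methods
vignette (`vignettes/mt-ssfp-ellipse.Rmd`) for the Cramér–Rao analysis.

A full Monte Carlo summary:

```r
run_monte_carlo(mc_config(n_realizations = 4096, seed = 1))
```

Command-line use (installed under `exec/`):

```sh
mtellipse phantom --out /tmp/ph --shape 16,16,8 --sigma 0.2 --seed 1
mtellipse fit --dir /tmp/ph --out /tmp/maps
mtellipse montecarlo --n 4096 --seed 1 --out mc.json
```

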