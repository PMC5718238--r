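# iplheat

Coupled Monte Carlo light transport and ADI heat diffusion for intense
pulsed light (IPL) photoepilation.

## What it is for

Commercial IPL hair-removal systems deliver the same nominal fluence with
very different temporal pulse structures: a capacitor-style **free
discharge**, a constant-power **square pulse**, a burst of tightly spaced
sub-pulses (**close pulse stacking**) or widely spaced sub-pulses
(**spaced pulse stacking**). `iplheat` is a simulation tool for medical
physicists and device designers who want to compare these structures on a
common physical footing: how hot does the melanin-rich epidermis get
(safety), and how hot does a buried hair follicle get (efficacy), at
matched radiant exposure?

The model couples two stages on a 2-D Cartesian skin section (5 µm cells;
80 µm epidermis with 5 % melanosomes; a 200 µm-diameter, 2000 µm-long
follicle with 30 % melanosomes buried 200 µm deep):

1. **Photon transport.** Weighted photon packets with wavelengths drawn
   from a 600-bin (1 nm) broadband spectrum walk through the grid:
   exponential steps *s* = −ln *R*/µ<sub>t</sub>, per-interaction
   deposition ΔW = W µ<sub>a</sub>/(µ<sub>a</sub>+µ<sub>s</sub>),
   Henyey–Greenstein redirection
   cos θ = (1/2g)[1+g² − ((1−g²)/(1−g+2gR))²] with g = 0.789, uniform
   azimuth φ = 2πR, termination at 1/100 of the launch weight. The result
   is the absorbed-energy-density matrix per unit radiant exposure.
2. **Heat diffusion.** That matrix, modulated by the pulse train's
   normalised power profile, drives
   ρc ∂T/∂t = ∇·(k∇T) + H(y,z,t), advanced by a Peaceman–Rachford
   alternating-direction-implicit (ADI) scheme with harmonic-mean
   interface conductances and tridiagonal (Thomas) solves per grid line.
   Probe traces are recorded 20 µm deep in the epidermis and 10 µm inside
   the follicle edge at 2000 µm depth.

Full model details, parameter tables, the calibration rationale and known
limitations are in the methods vignette
(`vignettes/ipl-pulse-structure.Rmd`).

## Worked example

The test fixture (0.5 × 0.5 mm grid, shallow follicle, 2×10⁴ packets) runs
the whole pipeline in about a second:

```r
library(iplheat)
report <- run_comparison(make_fixture("tiny_grid"))
report
#> <comparison_report> 4 categories, 20000 photons, seed 20120906, 10 J/cm^2
#> <peak_metrics> threshold 70 C
#>             category peak_epidermal peak_follicle rise_epidermal rise_follicle exceeds_threshold
#> 1     FREE_DISCHARGE          60.23         91.10          25.23         56.10              TRUE
#> 2       SQUARE_PULSE          57.91         81.10          22.91         46.10              TRUE
#> 3  CLOSE_PULSE_STACK          56.53         75.27          21.53         40.27              TRUE
#> 4 SPACED_PULSE_STACK          54.96         70.11          19.96         35.11              TRUE
#> free-discharge epidermal peak-rise excess (%):
#>       SQUARE_PULSE  CLOSE_PULSE_STACK SPACED_PULSE_STACK
#>              10.13              17.19              26.42
```

Reading the output: peaks are absolute probe temperatures (°C) from a
35 °C baseline; rises are peaks minus baseline. The free discharge heats
the epidermis most — its energy arrives faster than the 80 µm layer can
conduct it away — while the spaced stack heats the follicle least, because
energy leaks away during its 15 ms inter-pulse gaps. (This fixture's
follicle is only 150–450 µm deep, hence the high follicular peaks; the
production geometry buries the probe at 2000 µm.)

The production-scale comparison is one call — `run_comparison(run_config())`
— or, from a shell, the bundled CLI:

```sh
Rscript inst/cli/iplcmp.R run --config inst/extdata/default_config.yaml --out ipl_out/
Rscript inst/cli/iplcmp.R fixture --kind tiny_grid --out fixture.yaml
```

Reports are written as versioned JSON plus delimited-text probe traces and
a self-describing text matrix of the absorption grid; identical
configuration + seed reproduces them byte for byte.

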