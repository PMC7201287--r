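---
title: "Reducing sparse 4D-STEM nanobeam diffraction tilt series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reducing sparse 4D-STEM nanobeam diffraction tilt series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The experiment this package reduces

In scanning nanobeam electron-diffraction tomography (nanoEDT), a focused
electron probe (~12 nm full width at half maximum) is raster-scanned across a
nanocrystal on a coarse grid (40 nm steps), and a full 2D diffraction pattern
is recorded at every scan position on a direct electron detector. After each
scan the stage is tilted by one degree and the scan repeats, giving one 4D
dataset (scan row x scan col x detector row x detector col) per tilt over a
range of roughly +/-45 degrees. Because each probe position illuminates only a
few unit cells at ~1 e-/A^2 per frame, the individual frames are extremely
sparse: most detector pixels see no electron at all.

The scientific payoff of this geometry is twofold. First, dose: the area
mapped by one scan step (step^2 = 1600 nm^2) is about 14 times larger than the
area actually illuminated by the probe (pi (FWHM/2)^2 ~ 113 nm^2), so the
average exposure across the crystal is an order of magnitude below the nominal
series dose. Second, the selected area becomes a *digital* choice: any subset
of scan positions can be summed after the fact into a diffraction pattern, so
crystal regions are selected by image segmentation rather than by a physical
aperture, and overlapping lattices from adjacent crystallites can be separated
cleanly.

`stem4d` implements the full reduction chain from raw frames to an indexable
diffraction tilt series, plus a seeded synthetic generator used to validate
every stage against ground truth.

## Hybrid electron counting

An integrating detector reports, per pixel, roughly
`gain * n_electrons + dark + read noise`. Sparse frames are converted to
electron counts in four steps:

1. **Alignment.** Each frame's primary beam is located (brightest pixel, then
   the intensity centre of mass inside a window around it) and the frame is
   shifted by *whole pixels* onto the central detector pixel. Integer shifts
   preserve counting statistics; sub-pixel interpolation would correlate
   neighbouring pixels.
2. **Dark subtraction.** The per-pixel temporal median across all scan
   positions estimates the dark level, because sparse signal leaves the median
   untouched. One caveat is built into the design: the central beam occupies
   the *same* detector pixels in every frame, so the temporal median absorbs
   it there. For counting and peak work this is harmless (the beam is excluded
   anyway); for quantitative beam intensities (thickness mapping) the dark
   reference should come from a beam-blanked acquisition, which the simulator
   produces by setting the electron budget to zero.
3. **Noise model.** A Gaussian is fitted robustly to the central mode of the
   dark-subtracted value histogram (median/MAD location and scale, refined
   once by the trimmed standard deviation within 4 robust sigma, ignoring the
   positive electron tail). The counting threshold is `k_sigma * sigma` with
   `k_sigma = 4` by default: at four sigma, false counts from read noise are
   negligible while single electrons (one gain above zero, ~6 sigma here)
   are retained. Unless the gain is known, it is estimated as the mode of the
   above-threshold values, where single hits dominate; the kernel density uses
   a fixed bandwidth of `sigma / 2` because the long coincident-beam tail
   would otherwise inflate an automatic bandwidth and smear the
   single-electron mode.
4. **Quantization.** A dark-subtracted value `v` becomes
   `0` if `v <= threshold`, else `max(1, round(v / gain))` — "hybrid" counts.
   Binary counting (`0/1`) is kept as a baseline: with coincident arrivals it
   saturates at one count per pixel, while the hybrid rule recovers the
   multiplicity. With exact gain and no noise the rule is exact, so total
   counts are conserved; the package's acceptance checks measure the binary
   baseline losing >90% of the electrons in an intense beam while hybrid
   counting stays within a fraction of a percent.

## Virtual imaging, segmentation and the digital aperture

Summing, at every scan position, the counts outside a central disc produces a
virtual annular dark-field (ADF) image: crystal positions scatter electrons to
Bragg angles and appear bright, support film appears dark. The default inner
radius is 1.5x the central-beam disc radius estimated from the aggregate
pattern (the radius where the azimuthally averaged intensity first falls below
2% of its central value). Bright-field disc and complementary annulus
partition every count exactly — an invariant the test suite asserts.

Crystal regions are segmented from the ADF image by Otsu thresholding
(an absolute threshold is available), morphological opening then closing with
disc structuring elements (radius 1 by default; the field is padded with
background first so regions touching the image border are not distorted by
edge handling), and 8-connected component labelling with a minimum area of 4
scan pixels. Manual polygon apertures are supported as an alternative. The
selected scan positions are summed per tilt into one diffraction pattern, the
patterns are ordered by tilt angle, and the series is exported as SMV images
(512-byte ASCII header, unsigned 16-bit payload) for external indexing
software. Indexing, integration, scaling and structure solution are explicitly
out of scope.

## Thickness from the log-ratio model

Crystal thickness per scan position follows the EELS-style log-ratio formula

    Z_xy = lambda * ln(I0 / I_xy)

with `lambda = 332 nm`, the inelastic mean free path appropriate for a
hydrated-density peptide crystal at 300 kV. `I_xy` is the *transmitted*
intensity: the central-beam disc integrated on raw dark-subtracted detector
values divided by the gain (the beam is too intense for counting — coincidence
saturates it), **plus** discs at the located Bragg peaks integrated on hybrid
counts. Omitting the elastically scattered electrons systematically inflates
the apparent thickness, so a missing peak list triggers a warning and the
beam-only variant is only provided for comparison. `I0` is the mean of `I_xy`
over a vacuum region (a hole in the support film) minus two standard
deviations, a conservative allowance for beam-current fluctuation; `Z(I0) = 0`
exactly, brighter-than-vacuum pixels are clamped to zero with a message, and
non-positive intensities are flagged invalid rather than computed.

The peak integration disc must cover the spot: the exported default radius is
3 px, but any analysis should set it to the actual spot radius plus a small
margin (the simulator-matched analyses here use 18 px for 15 px spots).
Similarly the beam disc radius should enclose the rendered beam (estimated
radius + 4 px here). For tomography, `prepare_tilt_images()` aligns
consecutive thickness maps by integer-pixel cross-correlation (ties favour the
smallest shift, so featureless maps stay put), crops to the common field of
view, subtracts a flat background measured on a vacuum strip (by default the
dimmest border strip of width 2), and clips negatives — the input a
tomographic reconstruction package would consume. Reconstruction itself is out
of scope.

## Peak localization

Summed patterns are binned 5x (non-overlapping block sums, counts conserved,
edges cropped with a warning if not divisible) and matched against a flat
circular template 6 binned pixels in diameter using normalized
cross-correlation, which is invariant to affine intensity rescaling. Local
maxima above `ncc_min = 0.5` survive greedy non-maximum suppression at one
template diameter, and coordinates map back to unbinned pixels with the
bin-centre convention: binned pixel `b` (1-based) maps to unbinned
`(b - 1) * factor + (factor + 1) / 2`. All coordinates in this package are
1-based `(row, col)`, the R convention. Peaks inside twice the estimated
beam-disc radius are excluded — reflections under or near the beam are not
observable. For multi-crystal fields of view, each full-field peak is labelled
with every region whose region-selected pattern has a peak within a matching
radius, separating coincident lattices without any multi-lattice indexing.

## The synthetic generator and what passing tests mean

`sim_config()` defaults restate the experimental conditions: 40 nm step,
12 nm probe FWHM, 1 e-/A^2 per frame, tilts -45..45 in 1 degree steps, a
30 x 70 scan grid, 0.0197 A wavelength (300 kV), and a needle-shaped crystal
on a support film with a vacuum hole. Two quantities are scaled to desk size,
deliberately and together: the detector is 128 x 128 (a full direct-detection
chip is ~2k x 2k) and the per-frame electron budget is 20000, chosen so that
per-pixel occupancy away from the beam stays sparse — the regime counting
requires — just as on the real detector.

The diffraction model is kinematic. A reflection's reciprocal vector
(detector-pixel units) is rotated about the detector-row (tilt) axis; it is
excited when the rotated out-of-plane component is below a tolerance of
0.9 px, a stand-in for the relaxed Bragg condition (relrod broadening) of a
nanometre probe, so low-order reflections persist over a few degrees of tilt.
The beam and the excited spots are rendered as smooth-edged discs (logistic
edge, width 1.5 px): a convergent probe produces disc-shaped (CBED)
reflections, which is also what a circular matching template expects. The spot
radius default of 15 px makes a 5x-binned spot exactly one 6-px template wide;
the beam radius default of 8 px keeps the central exclusion zone (2x beam
radius) clear of the first-order reflections of the default lattice (spacings
44/48 px). Transmission through thickness `t` attenuates the whole pattern by
`exp(-t / 332 nm)`; a fraction (0.15) of the transmitted electrons goes into
the excited spots in proportion to a deterministic structure-factor table.
Arrivals are Poisson; the detector reading is
`round(arrivals * gain + dark + N(0, sigma))` with gain 32 ADU/e-, dark 100
ADU and sigma 5 ADU. Multiple arrivals in a pixel simply sum — exactly the
coincidence hybrid counting must undo. The seed fully determines the output.

Not modelled: dynamical scattering, partial coherence, detector MTF and
pixel-to-pixel gain variation, stage drift within a scan, and support-film
scattering. Passing tests therefore demonstrate that the *reduction* chain is
correct and self-consistent under Poisson statistics and Gaussian read noise;
they do not validate the kinematic approximation against real crystals.

Tests and the acceptance script run the generator at reduced problem sizes —
typically a 10 x 16 scan over 5 tilts (128 x 128 detector), a 12 x 20
two-crystal field at one tilt, and a 5 x 8 beam-only field for the coincidence
study — with every noise, dose and SNR default unchanged. The dose-arithmetic
checks (areas 1600 vs 113 nm^2, ratio ~14, 81 patterns over +/-40 degrees,
series dose 81 e-/A^2, selected-area dose 3 e-/A^2) are closed-form and run in
milliseconds.

## Numerical choices and edge cases

- Order of counting stages: align, then dark, then fit, then quantize.
  Alignment shifts fill vacated pixels with the dark map so later subtraction
  zeroes them; frames whose maximum does not exceed dark by 5 sigma are
  flagged unalignable and left unshifted.
- `estimate_dark()` requires at least 16 frames; the Gaussian fit rejects
  degenerate (zero-spread) histograms; gain estimation refuses to run on
  fewer than 50 events.
- Magnitude comparison between reflection datasets matches literal `(h,k,l)`
  indices only (no symmetry expansion — merging belongs to crystallographic
  software), filters both sets at `I/sigma > 2`, scales each set's
  intensities to equal totals, and regresses `sqrt(I)`.
- The 81-pattern +/-40 degree series and the 90-scan +/-45 degree acquisition
  both assemble correctly; the assembler accepts any tilt set, errors on
  duplicates, and logs gaps where a region selects no frames.
- SMV export adds a documented pedestal (default 0), clips to 65535 with a
  counted warning, and writes `OSC_RANGE = 0` for stills.
- File formats are all plain or standard: the 4D container is an ASCII
  `key = value` header plus little-endian payload (row-major, documented in
  the README), raw binary carries a text sidecar, TIFF stacks are 16-bit
  pages, and float maps are 32-bit TIFF scaled to [0, 1] with a plain-text
  scale sidecar.

## Known limitations

Thickness accuracy inherits a small negative bias from the `mean - 2 sd`
definition of `I0` (about `2 sigma_rel * lambda`, ~2% here) and a small
positive bias from the finite peak integration disc; both are well inside the
5% validation band at the default electron budget. Segmentation assumes
crystals are brighter than everything else in the ADF image — thick amorphous
contamination would violate that. The peak finder reports binned-grid
positions (2.5 unbinned px quantization at factor 5); applications needing
sub-pixel centres should refine on the unbinned pattern. The CLI's `count`
stage estimates dark from the stack itself, which is only appropriate for
sparse data; pass a beam-blanked reference when beam quantities matter.
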