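# gaussCBCT

Time-resolved dynamic cone-beam CT (CBCT) reconstruction with 3D Gaussian
representations — one reconstructed volume per x-ray projection, from a
single conventional CBCT scan, with no prior anatomical model, no prior
motion model, and no respiratory phase sorting.

The package is aimed at researchers in image-guided radiotherapy and
tomographic reconstruction who want a self-contained, CPU-only, fully
testable implementation of motion-resolved CBCT: it ships its own 4D
thorax phantom and scan simulator, so every stage of the method can be
exercised end to end with known ground truth and no external data.

## Method

A dynamic scan is modelled as a motion-compensated, low-rank decomposition

```
I(x, p) = I_ref(x + d(x, p)),        d(x, p) = Σ_{i=1..9} w_i(p) · e_i(x)
```

* `I_ref(x)` — a reference-frame CBCT represented by a dense set of 3D
  Gaussian kernels `ρ · exp(-½ (x-p)ᵀ Σ⁻¹ (x-p))`, with
  `Σ = R(q) diag(s²) R(q)ᵀ`;
* `e_i(x)` — nine motion-basis components (three coarse-to-fine levels ×
  three Cartesian directions), each a field of *signed* Gaussian kernels
  voxelized by a negative-permitting voxelizer;
* `w_i(p)` — per-projection coefficients produced by a six-layer
  convolutional encoder applied to the projection image itself.

All three parts are solved jointly from one projection set by a
progressive three-stage optimization: stage 1 fits the reference kernels
through a splatting-based x-ray rasterizer (each 3D kernel marginalizes to
a 2D Gaussian on the detector with amplitude
`ρ · sqrt(2π det Σ̃ / det Σ̂)`); stages 2–3 fit everything through a
differentiable voxelize → warp → project chain (Joseph ray marching with
an exact adjoint), coarse to fine. Losses: projection-domain L1 + 0.25
D-SSIM, 0.05 × total variation of random reference subvolumes, and a
normality term that fixes the basis/coefficient gauge. Initialization
comes from an FDK reconstruction (Ram-Lak, Parker weights for short
scans, offset-detector weighting for half-fan scans).

## Worked example

A scaled-down quasi-periodic breathing experiment (50×50×26 voxels at
4 mm, 120 projections over 360°, 3,000 reference kernels) that runs in
about seven minutes on one CPU core:

```r
library(gaussCBCT)

grid <- volume_grid(c(50, 50, 26), 4)
spec <- phantom_spec(grid)                       # analytic 4D thorax
traj <- make_circular_trajectory(0, 360, 60, 2)  # 60 s scan, 2 fps
geom <- scan_geometry(1000, 1500, 96, 72, 3.2, 3.2, traj$angles, traj$times)
trace <- make_trace("S1", 60, 2, seed = 0)       # ~5 s cycles, 13 mm
sim <- simulate_scan(spec, trace, geom, keep = c("volume", "mask"))

cfg <- recon_config("desk", M = 3000,
                    schedule = stage_schedule(1000, 350, 250, 32, 8),
                    densify_from = 200, densify_until = 800, seed = 0)
rec <- reconstruct(sim$projections, grid, cfg)

gt <- lapply(sim$frames, `[[`, "volume")
frames <- lapply(seq_along(gt), function(k) materialize_frame(rec, k))
re <- relative_error(frames, gt, mask = phantom_body_mask(spec, grid))
cat(sprintf("mean relative error (body): %.3f\n", as.numeric(re)))

ctr <- contour_tumor(rec$reference, sim$frames[[1]]$tumor_mask)
come_k <- sapply(seq_along(gt), function(k) {
  come(propagate_contour(ctr, frame_dvf(rec, k)),
       sim$frames[[k]]$tumor_mask, grid)
})
cat(sprintf("mean tumor COM error: %.2f mm\n", mean(come_k)))
```

Printed output of this exact script (seed 0):

```
mean relative error (body): 0.152
mean tumor COM error: 2.03 mm
```

The relative error says the reconstructed dynamic frames differ from the
analytic ground truth by ~15% in L2 norm inside the body; the tumor
center-of-mass error says the 30 mm tumor, moving 13 mm over the scan, is
localized to within ~2 mm on average at this coarse problem size (half a
voxel). Larger problem sizes (finer grids/detectors, more kernels and
steps) tighten both numbers; see the vignette for how scores scale with
resolution.

## Command-line interface

A thin wrapper over the same functions is installed at
`inst/cli/gausscbct`:

```sh
gausscbct simulate --scenario S1 --duration 60 --fps 11 --out sim/
gausscbct fdk --proj sim/projections.tif --grid 100x100x50 --spacing 2 --out avg.mha
gausscbct reconstruct --proj sim/projections.tif --grid 100x100x50 --spacing 2 --out recon/
gausscbct evaluate --recon recon/ --gt sim/ --out metrics.json
```

Volumes are MetaImage (`.mha`) or NIfTI; projections are multi-page TIFF
with a JSON geometry sidecar.
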