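# glareDrop

Label-free detection of micrometer-scale particles — polymer beads and
multicellular spheroids (MCSs) — inside free-falling ~30 nl droplets, from
single camera frames. In drop-on-demand (DoD) bioprinting, a piezo-driven
dispenser ejects one droplet per trigger; printing defined numbers of
spheroids requires knowing whether each *ejected* droplet actually carries
one. Monitoring the nozzle region fails when a spheroid sticks to the
nozzle, so glareDrop works on the droplet after ejection: a triggered camera
captures each droplet in flight, and image analysis decides per frame
whether a particle is inside.

The package is aimed at bioprinting and liquid-handling groups who want to
evaluate or recalibrate such inline detection, and at anyone needing a
reproducible, fully synthetic benchmark for it: a seeded generator renders
droplet frames for both illumination concepts, so the entire pipeline runs
and is tested without captured camera data.

## The detectors

A droplet barely images its contents directly — it acts as a spherical
lens. Two illumination concepts work around that:

* **Glare-point projection**: directed LEDs (4 or 6, typically 405 nm at
  40° incidence) produce bright specular *glare points* on the droplet
  surface via refraction and a single internal reflection. An enclosed
  particle intercepts the internal light path, so glare points grow,
  shrink, appear or disappear.
* **Diffuse anterior illumination**: white light from a reflective
  hemisphere suppresses the lens behavior; the droplet appears as a bright
  disc and an *opaque* particle as a dark patch. Transparent particles and
  spheroids stay invisible under this concept.

Three per-frame detectors operate on 200 × 200 crops, each calibrated on
empty-droplet frames:

* **WPC (white pixel count)** — after Otsu binarization,
  `WPC = white pixels / total pixels`. The empty-droplet baseline is the
  mean WPC of ten empty frames; a ±15 % margin defines the detection
  cut-off. Strictly above (optionally also strictly below) the cut-off ⇒
  particle.
* **CC (contour count)** — glare points are extracted as 8-connected
  components after binarization and mask de-speckling, matched to an
  empty-droplet baseline by nearest centroid; a particle is called when a
  point appears/disappears or a matched point's enclosed area changes by
  more than 30 %.
* **DIS (droplet image similarity)** — frames are aligned by
  cross-correlation template matching to a reference mask (the binarized
  pixel-wise mean of 20 empty frames), then scored:

  ```
  UD  = missing pixels / reference pixels × 100 %   (white → black)
  OD  = surplus pixels / reference pixels × 100 %   (black → white)
  DIS = 100 % − (UD + OD) / 2
  ```

  A frame is a detection as soon as two of the three scores deviate beyond
  their calibrated cut-offs (mean + 3 sd of held-out empty frames).

Run-level performance is the detection accuracy
`A = detected / actual × 100 %` against the reference particle count, with
confusion counts reported whenever ground truth exists.

## Worked example

Calibrate on 30 synthetic empty droplets, then evaluate a 200-frame
glare-mode series in which 5 droplets carry a particle that suppresses one
glare point (sensor noise sd 5, 1 px trigger jitter):

```r
library(glareDrop)
optics <- opticalConfig(wavelengthNm = 405, nLeds = 6)
scene  <- sceneConfig("glare", noiseSd = 5, jitterSd = 1)

empties <- lapply(1:30, function(i)
  renderEmptyDroplet(scene, optics, seed = 100 + i, frameIndex = i - 1))
profile <- calibrateProfile(empties, sidedness = "two_sided")
profile
#> CalibrationProfile [glare]:
#>   WPC: baseline 0.00776 (two_sided)
#>   CC:  6 reference points
#>   DIS: reference 316 white px, UD <= 9.809, OD <= 7.581

series <- generateSeries(scene, optics, nFrames = 200,
                         particleFrames = c(12, 57, 101, 143, 188),
                         effect = particleEffect("remove_spot"), seed = 7)
report <- runBatch(series, profile)
report
#> RunReport: 200 frames [glare], actual particle count 5
#>  detector detectedCount accuracyPercent truePositives falsePositives
#>       wpc             5           100.0             5              0
#>        cc             5           100.0             5              0
#>       dis             5           100.0             5              0
#>  falseNegatives
#>               0
#>               0
#>               0
```

The calibration line reads: empty droplets average 0.78 % white pixels
(six ~52 px glare points in a 40 000 px crop), the CC baseline holds six
reference glare points, and the DIS reference mask has 316 white pixels
with empty-frame scores allowed up to UD 9.8 % / OD 7.6 %. All three
detectors then recover the five particle frames with no false positives —
accuracy 100 %.

The same workflow is scriptable from a shell via the thin CLI in
`inst/cli/glaredrop` (`simulate`, `calibrate`, `detect`, `evaluate`).

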