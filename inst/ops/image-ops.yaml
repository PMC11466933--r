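version: "1"
ops:
  - names: [filter.gauss]
    type: computer
    priority: 0.0
    source: "opsmatch::.op_gauss"
    description: "Separable Gaussian blur: normalized discrete kernel, half-width ceil(4*sigma), mirror border, float64 accumulation, cast to the container's element kind."
    parameters:
      - {name: input, type: dense-image, io: input, optional: false,
         description: "image to blur"}
      - {name: sigma, type: real, io: input, optional: false,
         description: "positive standard deviation, isotropic"}
      - {name: output, type: dense-image, io: container,
         description: "pre-allocated container, same shape as the input"}
    dependencies: []
  - names: [filter.dog]
    type: function
    priority: 0.0
    source: "opsmatch::.op_dog"
    description: "Difference of Gaussians: gauss(input, sigma1) minus gauss(input, sigma2), all three steps resolved as op dependencies by the engine."
    parameters:
      - {name: input, type: dense-image, io: input, optional: false,
         description: "image to filter"}
      - {name: sigma1, type: real, io: input, optional: false,
         description: "sigma of the first blur"}
      - {name: sigma2, type: real, io: input, optional: false,
         description: "sigma of the second blur"}
      - {name: output, type: dense-image, io: output,
         description: "band-pass filtered image"}
    dependencies:
      - {slot: gauss1, name: filter.gauss, type: function,
         in: [dense-image, real], out: dense-image}
      - {slot: gauss2, name: filter.gauss, type: function,
         in: [dense-image, real], out: dense-image}
      - {slot: sub, name: math.sub, type: function,
         in: [dense-image, dense-image], out: dense-image}
  - names: [image.histogram]
    type: function
    priority: 0.0
    source: "opsmatch::.op_histogram"
    description: "Intensity histogram; uint8 images bin over [0, 256), float images over [min, max] with a right-closed last bin."
    parameters:
      - {name: input, type: dense-image, io: input, optional: false,
         description: "image to count"}
      - {name: bins, type: integer, io: input, optional: true, default: 256,
         description: "number of bins, at least 2"}
      - {name: histogram, type: histogram, io: output,
         description: "bin edges (length bins + 1) and counts"}
    dependencies: []
  - names: [threshold.otsu]
    type: function
    priority: 0.0
    source: "opsmatch::.op_otsu"
    description: "Otsu threshold: maximizes between-class variance over a 256-bin histogram; ties broken by the lowest maximizing threshold; mask is input > threshold."
    parameters:
      - {name: input, type: dense-image, io: input, optional: false,
         description: "image with at least two distinct values"}
      - {name: result, type: threshold-result, io: output,
         description: "threshold value plus binary mask"}
    dependencies: []
  - names: [filter.fft]
    type: function
    priority: 0.0
    source: "opsmatch::.op_fft"
    description: "Discrete Fourier transform with mirror padding; optional per-axis border size and fast-size rounding to lengths factorable into {2,3,5,7}."
    parameters:
      - {name: input, type: dense-image, io: input, optional: false,
         description: "real-valued image"}
      - {name: fftType, type: text, io: input, optional: false,
         description: "transform kind; only real_to_complex"}
      - {name: borderSize, type: integer, io: input, optional: true, default: 0,
         description: "mirror padding per axis, on each side"}
      - {name: fast, type: boolean, io: input, optional: true, default: true,
         description: "round padded axis lengths up to the next 7-smooth size"}
      - {name: output, type: complex-grid, io: output,
         description: "complex-valued frequency grid"}
    dependencies: []
  - names: [stats.pnorm]
    type: function
    priority: 0.0
    source: "opsmatch::.op_pnorm_scalar"
    description: "Standard normal cumulative distribution function."
    parameters:
      - {name: x, type: real, io: input, optional: false,
         description: "z-score"}
      - {name: p, type: real, io: output,
         description: "probability in [0, 1]"}
    dependencies: []
  - names: [coloc.sigMask, coloc.saca.sigMask]
    type: function
    priority: 0.0
    source: "opsmatch::.op_sigmask"
    description: "Binary mask of significantly colocalized pixels: one-sided upper-tail test (1 - pnorm(z)) < alpha on a z-score image; pnorm is resolved as an op dependency."
    parameters:
      - {name: zscores, type: dense-image, io: input, optional: false,
         description: "z-score heatmap"}
      - {name: alpha, type: real, io: input, optional: true, default: 0.05,
         description: "significance level in (0, 1)"}
      - {name: mask, type: dense-image, io: output,
         description: "uint8 mask, 1 = significant"}
    dependencies:
      - {slot: pnorm, name: stats.pnorm, type: function,
         in: [dense-image], out: dense-image}
  - names: [fixtures.synthetic_image]
    type: function
    priority: 0.0
    source: "opsmatch::.op_synthetic_image"
    description: "Seeded synthetic fluorescence image: Gaussian spots at random positions plus Gaussian noise; identical seed gives a bit-identical image."
    parameters:
      - {name: shape, type: int-vector, io: input, optional: false,
         description: "image shape, slowest axis first"}
      - {name: n_spots, type: integer, io: input, optional: false,
         description: "number of Gaussian spots"}
      - {name: spot_sigma, type: real, io: input, optional: false,
         description: "spot width (standard deviation, pixels)"}
      - {name: noise_sd, type: real, io: input, optional: false,
         description: "additive Gaussian noise standard deviation"}
      - {name: seed, type: integer, io: input, optional: false,
         description: "random seed fixing the image"}
      - {name: output, type: dense-image, io: output,
         description: "float64 image"}
    dependencies: []
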