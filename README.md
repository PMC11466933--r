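# opsmatch

Scientific image analysis pipelines routinely mix algorithms from
different libraries, each with its own data structures and calling
conventions.  `opsmatch` is an R framework that makes algorithm execution
*declarative*: algorithms are registered as **ops** — named, typed plugins
described by YAML metadata — and users request them by name and parameter
types.  A deterministic matching engine then selects the best registered
implementation, and when nothing fits exactly it can

* **adapt** an op between functional shapes — *function* (allocates a new
  output), *computer* (writes into a pre-allocated container), *inplace*
  (overwrites one mutable argument) — including lifting scalar ops
  element-wise across whole images;
* **convert** individual arguments between data types via single-hop
  `engine.convert` ops, with exact copy-back for converted containers;
* inject **defaults** for trailing optional parameters via reduced
  signatures; and
* resolve **op dependencies** recursively, so composite ops like a
  Difference of Gaussians never hard-link their helpers.

The selection is a pure function of the request: for a fixed environment,
the same request always resolves to the same op, regardless of
registration order — candidates are ranked by priority, then wrapper
count, then a lexicographic source tie-break.  Every resolved match is an
**InfoTree** (root op + adapters + converters + dependency subtrees), and
an append-only **OpHistory** records a digest of the tree that produced
each written output.

A foundational image op collection ships with the package: separable
Gaussian filtering, Difference of Gaussians, histograms, Otsu
thresholding, FFT with optional border/fast-size parameters, the standard
normal CDF, significance masks for colocalization z-scores, and a seeded
synthetic spot-image generator.  All of it — including the engine's own
create/copy/convert/adapt helpers — is registered through the same YAML
descriptor mechanism, so the engine is extensible purely by dropping in
descriptors.

## Worked example

```r
library(opsmatch)
env <- default_ops_env()

op(env, "math.add") |> op_input(2, 3) |> op_apply()
#> [1] 5

img <- synthetic_image(c(24, 24), n_spots = 8, spot_sigma = 2,
                       noise_sd = 5, seed = 7)
d <- op(env, "filter.dog") |> op_input(img, 2, 5) |> op_apply()
range(img_values(d))
#> [1] -33.615  62.130
```

`filter.dog` resolved three dependencies through the engine: two
`filter.gauss` computers (each adapted to a function by allocating its
container through `engine.create`) and the scalar `math.sub` lifted
element-wise across the image:

```r
op_match(env, op_request("filter.dog", "function",
                         c("dense-image", "real", "real")))
#> InfoTree 06d3a683
#>  {op=opsmatch::.op_dog#function#4;adapt=-;...;deps=gauss1:{op=opsmatch::.op_gauss#computer#3;
#>   adapt=opsmatch::.op_adapt_marker;aux=create:{...}},gauss2:{...},sub:{op=opsmatch::.op_math_sub#...}}

op_help(env, "filter.gauss")
#> filter.gauss(input: image, sigma: number, output: image [container]) -> image
```

The negative/positive range is the expected band-pass signature: spots
near the small sigma survive, smooth background cancels.  The history
records what wrote each output:

```r
op_history(env)[, c("request", "digest", "output")]
#>                                                    request   digest output
#> 1 filter.dog|function|in=dense-image,integer,integer|out=* 06d3a683  obj-4
```

A command-line front end (`inst/cli/ops`) wraps the same functions:
`ops list`, `ops help <query>`, `ops run filter.gauss --in spots.tif
--param sigma=2 --out blur.tif`, `ops index <src> -o ops.yaml`, and
`ops benchmark`.

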