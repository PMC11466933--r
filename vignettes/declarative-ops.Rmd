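---
title: "Declarative op matching: model, engine, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Declarative op matching: model, engine, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opsmatch)
```

## The problem

Image analysts combine algorithms from many libraries, each with its own
data structures and calling conventions.  `opsmatch` reframes algorithm
execution as a declarative task: algorithms are *ops* — named, typed
plugins described by YAML metadata — and users state *what* they want
(`filter.gauss` on this image with this sigma) rather than *which*
implementation should run.  A deterministic engine picks the best
registered implementation, adapts it between functional shapes, converts
arguments between data types, and resolves helper-op dependencies
recursively.  Because the choice is re-made at every request, registering a
better implementation transparently improves every workflow that names the
same op.

## The op model

An op has a name (plus optional aliases), a functional shape, an ordered
parameter list, a priority, and a source locator resolvable to a callable.
The three shapes mirror how numerical routines are written in practice:

* **function** — pure; consumes inputs, allocates and returns a new output;
* **computer** — writes its result into a pre-allocated *container*
  argument, avoiding allocation in tight loops;
* **inplace** — overwrites one *mutable* argument, avoiding allocation and
  a copy.

Ops are declared in YAML descriptor files (`parse_descriptor()` /
`emit_descriptor()`), so a library's routines can be wrapped with zero code
changes; `index_annotations()` alternatively scans doc comments carrying an
`@implNote op` tag and writes the same YAML.  Both shipped collections
(`inst/ops/*.yaml`) go through this exact mechanism — the engine's own
create/copy/convert/adapt helpers are ordinary, removable ops, which is
what makes the engine extensible from the outside.

Because R values are copied on modification, the container-like objects
(`dense_image()`, `planar_image()`, `byte_seq()`, `real_seq()`) are
environment-backed with reference semantics; this is what lets a computer
op genuinely overwrite its container and the history attribute outputs to
identities.

## Matching

A request (`op_request()`) names an op, a shape, and optionally the
argument/output type names.  Four routines are tried in a fixed order:

1. **direct** — name, shape and types fit as declared;
2. **adaptation** — a single `engine.adapt` op changes the candidate's
   shape (e.g. computer→function via an `engine.create` container
   allocation) or lifts a scalar op element-wise across images;
3. **conversion** — single-hop `engine.convert` ops bridge individual
   mismatched parameters; a converted container additionally needs a
   backward converter and an `engine.copy` op for the user's type so
   results are copied back;
4. **adaptation + conversion** combined.

The first routine with a fully resolvable candidate wins.  Within a
routine, candidates are ordered by priority, then by total wrapper count,
then lexicographically by source locator — a total order, so matching is a
pure function of the request and registration order never matters.
Adaptation is tried before conversion as a design choice: adaptation
rearranges the call without touching user data, while conversion may copy
it.  The alternative order is defensible; the chosen one is logged
per-match (debug level) so any divergence from other engines is
observable.  Likewise the engine always prefers a direct match over a
higher-priority op reachable only through conversion: routine precedence
outranks priority by design.

Conversion is deliberately single-hop and at most one adaptation is
applied per match; converter chains would make the search space quadratic
in the converter count for no demonstrated benefit.  If the top-ranked
candidate's dependencies cannot be resolved, the engine falls to the next
candidate of the same routine (and then to later routines) rather than
failing outright; dependency resolution is depth-capped at 100 and rejects
revisiting the same (op, shape) pair, so cycles are reported, not looped.

Dependencies declared without types (`{slot, name, type}`) are wildcard
requests resolved by name/shape/priority.  A dependency may carry `in:` and
`out:` types; `filter.dog` uses this to request `math.sub` at image types,
which forces the element-wise lifting adaptation into its resolution tree
exactly as a user-level image subtraction would resolve.

The resolved match is an *InfoTree*: root op, adaptation, per-parameter
conversions (with copy-back ops) and recursively resolved dependency
subtrees.  `info_tree_format()` is its canonical serialization;
`info_tree_digest()` a short stable hash of it.  The execution history
stores only digests — bounded memory, and the full tree is recoverable by
replaying the match against the same environment.

## Reduced signatures

Trailing optional parameters are dropped one at a time, right to left, and
each reduction is materialized as its own registered signature at
registration time (eager materialization keeps matching a pure lookup over
a static op list; the lazy alternative would make the op list
request-dependent).  Executing a reduced signature injects the declared
defaults at the dropped positions.  An optional parameter followed by a
required one is legal to declare but never droppable; registration logs it.
`filter.fft(input, fftType, borderSize?, fast?)` therefore exposes exactly
three signatures.

## The image op collection

* `filter.gauss` — separable convolution with a normalized discrete
  Gaussian, kernel half-width `ceil(4σ)` (beyond 4σ the discarded tail mass
  is below 1e-4 of the kernel), mirror borders without edge doubling,
  float64 accumulation, cast to the container's element kind at the end
  (uint8 rounds half-up and clamps to [0, 255]).  The filter numerics are
  normative for this package; they match common reference implementations.
* `filter.dog` — `gauss(σ1) − gauss(σ2)`, all three steps engine-resolved
  dependencies.  The identity `dog ≡ sub(gauss, gauss)` holds bit-exactly
  because both sides traverse the same resolved executables.
* `image.histogram` — uint8 images bin over the fixed range [0, 256);
  float images over [min, max] with a right-closed last bin; assignment is
  `floor((v − lo)/width)`.
* `threshold.otsu` — maximizes between-class variance over the 256-bin
  histogram; ties resolve to the lowest maximizing threshold; the mask is
  `input > threshold`; constant images are rejected as degenerate.
* `filter.fft` — mirror padding per axis, optional rounding of each padded
  length up to the next size factorable into {2, 3, 5, 7} (the radix set
  virtually all FFT back ends handle at O(n log n)), then the standard DFT.
* `stats.pnorm` — the standard normal CDF, registered as a scalar op;
  image-wide application resolves through element-wise lifting, which is
  how `coloc.sigMask` consumes it as a dependency.
* `coloc.sigMask` — one-sided upper-tail test `(1 − pnorm(z)) < α` on a
  z-score image, default α = 0.05, no multiple-testing adjustment.
  Colocalization strength is a one-sided quantity, so the upper tail is the
  scientifically meaningful side; the producing z-score kernel itself is
  out of scope here, so any z-image is accepted.  Both the one-sidedness
  and the absence of a correction are deliberate, documented limitations.

Axis conventions everywhere: 0-based data-model indices, slowest axis
first, half-open intervals; R's 1-based array accessors sit on top of this
without changing the order.

## The synthetic generator

`synthetic_image()` emulates a fluorescence micrograph: `n_spots` isotropic
Gaussian spots of amplitude 100 at seeded-uniform positions, plus additive
Gaussian noise, in float64.  Defaults (64×64, 20 spots, σ = 2 px,
noise SD 5) are in the regime of a sparse spot image at moderate SNR — a
realistic small field of view for filtering and thresholding demonstrations.
It does **not** emulate Poisson photon statistics, camera offset/gain,
spot-shape anisotropy or background gradients; tests passing on these
fixtures demonstrate the *framework's* contracts (identity of composed vs
engine-resolved pipelines, oracle agreement of the numerics), not
robustness claims about real microscopy data.

## Benchmarks

`ops_benchmark()` times `benchmark.increment` (first byte +1 mod 256, i.e.
runtime ≈ overhead) through six pathways: direct call, engine matching
(cache off), engine cached, adaptation, conversion, and their composition.
Absolute times depend on the host; only orderings are asserted anywhere in
the package: cached < uncached, direct < any engine pathway, and the
combined pathway at least as costly as either feature alone.

## Problem sizes and tolerances

The test suite and the acceptance script use 24×24–64×64 images, 20-image
identity sweeps, 200 random matcher environments and 100 shuffle-invariance
requests — sizes at which every oracle (dense convolution, exhaustive Otsu
search, flat match enumeration) is itself trivially verifiable by
inspection.  Bit-exact identities are asserted as such; floating-point
comparisons use 1e-8 (gauss vs dense convolution, FFT round-trip), 1e-10
(reduced vs full FFT calls) and 1e-6 (pnorm vs numeric integration).

## Known limitations

* Dispatch discriminates on parameter *types*, never values — two
  same-name ops cannot split one type domain by, say, kernel size.
* No generic/parameterized type variance; the type registry is a plain
  named DAG.
* Converter chaining and multiple simultaneous adaptations are excluded by
  design (see above).
* Executables returned by `op_function()` and friends bypass the history
  when invoked later; only builder terminals log.
* Neighborhood-wise lifting is a plausible future adapter; only
  element-wise lifting is implemented.
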