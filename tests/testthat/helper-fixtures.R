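## Shared fixtures, built once per test run on first use.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

## The standard desk-scale instance: 32x32, 6 coils, 3 respiratory phases.
fixture32 <- function() cached("fx32", function() synthetic_fixture(seed = 1))

## A lighter instance for replica loops and quick end-to-end checks.
fixture_small <- function() cached("fxs", function()
  synthetic_fixture(grid_shape = c(24, 24), n_coils = 4, n_phases = 2,
                    n_interleaves = 720, samples_per_interleaf = 48,
                    noise_sd = 0.02, seed = 2))

## A 48x48 phantom used by registration tests (richer texture).
phantom48 <- function() cached("ph48", function()
  make_dynamic_phantom(phantom_spec(grid_shape = c(48, 48), n_phases = 6,
                                    diaphragm_amplitude = 4, seed = 7)))

## Archimedean spiral coordinates for operator tests.
test_spiral <- function(K, rmax, turns = 6, th0 = 0) {
  t <- seq(0, 1, length.out = K)
  cbind(rmax * t * cos(2 * pi * turns * t + th0),
        rmax * t * sin(2 * pi * turns * t + th0))
}

rand_complex <- function(n, seed = NULL) {
  gen <- function() complex(real = rnorm(n), imaginary = rnorm(n))
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

rand_stack <- function(dims, seed = NULL) array(rand_complex(prod(dims), seed), dims)
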