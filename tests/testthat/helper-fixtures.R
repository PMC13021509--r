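# Shared fixtures, generated in code. Small grids keep the suite fast;
# seeds are fixed so every run sees identical data.

# Desk phantom (48^3 at 3 mm), memoized across tests.
deskPhantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- makePhantom(phantomSpec(seed = 42L))
    cache
  }
})

# Small phantom for cheap geometric tests (32^3 at 4 mm).
smallPhantom <- function(seed = 7L) {
  makePhantom(phantomSpec(
    grid = gridSpec(c(32L, 32L, 32L), rep(4, 3)),
    wmRadii = c(34, 42, 32), gmThickness = 10, csfThickness = 7,
    ventRadii = c(5, 11, 7), ventOffset = c(8, 2, -3),
    seed = seed))
}

# Random smooth displacement field (normalized units), peak `ampVox` voxels.
randomSmoothField <- function(shape, ampVox, smoothVox = 2, seed = 1L) {
  makeDeformationTruth(shape, amplitudeVox = ampVox, smoothVox = smoothVox,
                       seed = seed)$vpair@vFwd
}

expect_max_abs <- function(x, bound) {
  expect_lt(max(abs(x)), bound)
}
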