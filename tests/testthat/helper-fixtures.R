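# Shared synthetic fixtures, generated once per test run and cached.
.fixture_env <- new.env()

get_fixtures <- function(duration_s = 60, height = 72, width = 96,
                         seed = 3) {
  key <- paste(duration_s, height, width, seed, sep = "_")
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- make_fixture_set(seed = seed,
                                            duration_s = duration_s,
                                            height = height, width = width)
  .fixture_env[[key]]
}

# tiny flat-spectrum cube for I/O and arithmetic tests
tiny_cube <- function(h = 8, w = 8, seed = 42, kind = "reflectance") {
  set.seed(seed)
  grid <- canonical_grid()
  data <- array(runif(h * w * length(grid), 0.05, 0.95),
                c(h, w, length(grid)))
  spectral_image(data, grid, kind = kind, degrees_per_pixel = 0.1)
}

# independent loop oracle for cone excitations
loop_cone_excitations <- function(values, s, dl = 10) {
  q <- c(0, 0, 0)
  for (i in seq_along(values))
    for (ch in 1:3) q[ch] <- q[ch] + values[i] * s[i, ch] * dl
  q
}
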