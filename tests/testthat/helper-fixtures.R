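# Shared fixture builders: profiles sampled from known response functions.

profile_from_fn <- function(f, n = 20, lo = 10, hi = 100, id = "fx",
                            species = NA_character_, temperature_C = NA_real_) {
  do <- seq(hi, lo, length.out = n)
  rate_profile(id, do, f(do), species = species,
               temperature_C = temperature_C)
}

# A random but reproducible wiggly non-negative profile.
random_profile <- function(seed, n = 8, lo = 5, hi = 100) {
  set.seed(seed)
  do <- sort(runif(n, lo, hi))
  rate_profile(paste0("rnd", seed), do, runif(n, 0.1, 2))
}

expect_no_skips <- function(ri) {
  expect_equal(nrow(attr(ri, "skipped")), 0)
}
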