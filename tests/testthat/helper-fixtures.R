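# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fixturePlan <- function() {
  if (is.null(.fx$plan))
    .fx$plan <- syntheticPlan(imageSize = 256L, seed = 11L)
  .fx$plan
}

# one optimal-dose well at 256 px
fixtureWell <- function() {
  if (is.null(.fx$well))
    .fx$well <- generateWell(fixturePlan(), dose = 6, seed = 101L)
  .fx$well
}

# small codebooks fitted on images disjoint from anything else we test on
fixtureCodebooks <- function() {
  if (is.null(.fx$cb)) {
    imgs <- lapply(1:5, function(i)
      pixels(generateWell(fixturePlan(), 6, seed = 9000L + i)$bright))
    .fx$cb <- list(
      sift = fitCodebook(imgs, "f128", 256L, seed = 1L, fitIds = paste0("fit", 1:5)),
      orb = fitCodebook(imgs, "f32", 64L, seed = 1L, fitIds = paste0("fit", 1:5)))
  }
  .fx$cb
}

# band-limited texture helper for planted-shift and translator tests
textureField <- function(side, sigma, seed) {
  withSeed(seed, pscdiff:::.smoothNoise(side, sigma))
}
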