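# Reduced-geometry phantom specs for fast unit tests. Acceptance tests use
# the full default geometry.

small_spec <- function(...) {
  args <- utils::modifyList(
    list(n_bscans = 2L, n_ascans = 48L, n_depth = 360L,
         speckle_k = Inf, surface_sag = 0),
    list(...)
  )
  do.call(phantom_spec, args)
}

# Random spec within the default operating regime: retina thickness
# 150-300 um, thin rat choroid, sclera strictly brightest.
random_regime_spec <- function(seed) {
  set.seed(seed)
  thick <- runif(1, 150, 300)
  orl <- runif(1, 950, 1050)
  gap <- runif(1, 120, 180)
  small_spec(
    irl_depth = orl - thick, orl_depth = orl,
    sclera_center = orl + gap,
    sclera_band_sd = runif(1, 20, 35),
    levels = c(vitreous = runif(1, 0.02, 0.08),
               retina = runif(1, 0.45, 0.65),
               choroid = runif(1, 0.15, 0.35), sclera = 1.0),
    transition_scale = runif(1, 3, 8),
    speckle_k = sample(c(Inf, 200, 50), 1),
    seed = seed
  )
}
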