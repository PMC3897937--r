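# Small fixture builders used across the suite. Everything is generated in
# code; no stored binaries.

# a quick-to-render section: 2 villi on a 300 um baseline
small_spec <- function(...) {
  args <- list(...)
  defaults <- list(n_villi = 2, villus_height_um = 250, villus_width_um = 80,
                   crypt_depth_um = 120, muscularis_length_um = 300, seed = 1L)
  do.call(mucosa_spec, utils::modifyList(defaults, args))
}

# a rectangular single-villus section with trivially known truth
rect_spec <- function(...) {
  args <- list(...)
  defaults <- list(n_villi = 1, villus_height_um = 300, villus_width_um = 60,
                   crypt_depth_um = 120, muscularis_length_um = 200,
                   profile = "rect", seed = 1L)
  do.call(mucosa_spec, utils::modifyList(defaults, args))
}

# fast effect spec for small simulated trials
small_effect_spec <- function(...) {
  args <- list(...)
  defaults <- list(n_per_letter = 6, seed = 1L)
  do.call(effect_spec, utils::modifyList(defaults, args))
}
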