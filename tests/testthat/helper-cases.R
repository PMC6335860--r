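# Shared fixtures, built in code. Heavier synthetic cases are cached per
# test run so several files can reuse them without regenerating.

fast_params <- function(site = "spine", ...) {
  defaults <- list(n_z = 4L,
                   bone_radius_range = if (site == "spine") c(15, 18) else c(24, 30))
  over <- utils::modifyList(defaults, list(...))
  do.call(generator_params, c(list(site = site), over))
}

.case_cache <- new.env(parent = emptyenv())

cached_case <- function(key, site, params, seed) {
  if (is.null(.case_cache[[key]]))
    .case_cache[[key]] <- generate_case(site, params, seed)
  .case_cache[[key]]
}

noiseless_spine <- function()
  cached_case("spine0", "spine", fast_params("spine", noise_sd = 0), seed = 101)

noisy_spine <- function()
  cached_case("spine5", "spine", fast_params("spine"), seed = 202)

# small constant-modulus bar mesh with materials and roller compression BCs
bar_model <- function(shape = c(10, 10, 30), e = 1000, force = 1000) {
  blk <- make_uniform_block(shape, 1000, 1)
  m <- build_mesh(blk$mask, blk$spacing)
  m <- set_materials(m, rep(e, nrow(m$elements)))
  apply_boundary_conditions(m, "spine", force, constraint = "roller",
                            load_distribution = "tributary")
}

disc_mask <- function(r, n = 2 * r + 21) {
  xs <- seq_len(n) - (n + 1) / 2
  outer(xs, xs, function(a, b) a^2 + b^2 <= r^2)
}
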