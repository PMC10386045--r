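# Shared fixtures, built in code. Heavy objects are memoized so each is
# simulated once per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

water_only <- function(t1 = 2, t2 = 0.06) {
  pool_system(pool(0, t1, t2), list())
}

# water + one solute, optionally mirrored to negative offsets
one_solute_system <- function(shift = 3.5, rate = 30) {
  pool_system(pool(0, 2, 0.06),
              list(pool(shift, 1, 0.01, 7e-4, base_rate = rate, ph_slope = 1)))
}

# compact two-class phantom used by processing tests: a tumor-like patch
# inside contralateral-like surroundings
two_class_spec <- function(nx = 16, ny = 16, noise_sigma = 0, seed = 11,
                           ph_tumor = 6.8, ph_contra = 7.1,
                           b0 = b0_polynomial(c(0, 0.04, -0.03, 0, 0.02, 0))) {
  phantom_spec(
    nx = nx, ny = ny, voxel_dims = c(0.4, 0.4, 2),
    classes = list(
      tissue_class("contralateral", ph_contra, "ellipse",
                   center = c(0.3, 0.5), radii = c(0.18, 0.3)),
      tissue_class("tumor", ph_tumor, "ellipse",
                   center = c(0.72, 0.5), radii = c(0.16, 0.22))),
    b0 = b0, noise_sigma = noise_sigma, seed = seed)
}

# noiseless flat-B0 two-class phantom, one repeat (shared across tests)
noiseless_phantom <- function() {
  memo("noiseless_phantom", {
    generate_phantom(two_class_spec(noise_sigma = 0, b0 = 0), n_repeats = 1)
  })
}

# noiseless single-voxel CEST/WASSR spectra of the default system at pH 7
default_spectra <- function() {
  memo("default_spectra", {
    sys <- default_pool_system()
    cs <- cest_schedule()
    ws <- wassr_schedule()
    list(
      sys = sys,
      cest_offsets = cs$offsets_ppm,
      wassr_offsets = ws$offsets_ppm,
      cest_z = z_spectrum(sys, cs$offsets_ppm, cs$b1_amplitude, cs$sat_duration, 7),
      wassr_z = z_spectrum(sys, ws$offsets_ppm, ws$b1_amplitude, ws$sat_duration, 7))
  })
}

# dense WASSR master of the default system: lets tests synthesize shifted
# WASSR voxels without re-running the Bloch-McConnell solver per voxel
wassr_master_fun <- function() {
  memo("wassr_master", {
    sys <- default_pool_system()
    ws <- wassr_schedule()
    grid <- seq(-0.95, 0.95, by = 0.005)
    z <- z_spectrum(sys, grid, ws$b1_amplitude, ws$sat_duration, 7)
    splinefun(grid, z, method = "natural")
  })
}

# long-format balanced repeated-measures table (2 sides x k times)
random_rm_table <- function(n_subj = 6, k_time = 4, effect = 0, sigma = 0.03,
                            subj_sd = 0.05) {
  subj_eff <- rnorm(n_subj, 0, subj_sd)
  df <- expand.grid(subject = seq_len(n_subj), side = c("contralateral", "tumor"),
                    time = seq_len(k_time))
  df$value <- 1.5 + subj_eff[df$subject] +
    ifelse(df$side == "tumor", -0.05, 0) +
    effect * (df$time == 2) + rnorm(nrow(df), 0, sigma)
  df
}
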