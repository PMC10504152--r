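# Shared fixtures: small phantoms are expensive enough to build once and
# reuse across test files (everything downstream treats them read-only).

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# 32^3 at 4 mm: same physical head as the default, coarser lattice
tiny_spec <- function(...) phantom_spec(n = 32L, vox = 4, ...)

tiny_phantom <- function() cached_fixture("tiny", generate_phantom(tiny_spec()))

tiny_phantom_clean <- function()
  cached_fixture("tiny_clean", generate_phantom(tiny_spec(noise_sd = 0)))

# 48^3 at 8/3 mm: the grid used for fit-quality checks
mid_spec <- function(...) phantom_spec(n = 48L, vox = 8 / 3, ...)

mid_phantom_clean <- function()
  cached_fixture("mid_clean", generate_phantom(mid_spec(noise_sd = 0)))

mid_phantom <- function() cached_fixture("mid", generate_phantom(mid_spec()))

# 7-point discrete Laplacian (interior)
discrete_laplacian <- function(a) {
  d <- dim(a)
  i <- 2:(d[1] - 1); j <- 2:(d[2] - 1); k <- 2:(d[3] - 1)
  a[i + 1, j, k] + a[i - 1, j, k] + a[i, j + 1, k] + a[i, j - 1, k] +
    a[i, j, k + 1] + a[i, j, k - 1] - 6 * a[i, j, k]
}

measured_fm_of <- function(truth) {
  compute_field_map(truth$echoes[[1]], truth$echoes[[2]], truth$TE,
                    truth$spec$vox)
}

reference_of <- function(truth, measured = measured_fm_of(truth)) {
  b0_reference(measured, truth$fields$B_SH, truth$fields$Bk,
               truth$fields$Bchi_p, truth$spec$b0_shift, truth$chi,
               truth$brain_mask, truth$body_mask, truth$spec$f0,
               truth$spec$pad_factor, Bchi_m = truth$fields$Bchi)
}
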