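# Shared small fixtures, built in code at test time.

# compact two-channel bead slab: full 2 mm depth physics on a narrow lateral
# field so measurement and correction stay fast
small_bead_spec <- function(seed, n = 20, jitter_sd = 0.5, noise_sd = 50,
                            shape = c(500L, 64L, 64L),
                            pitch = c(4, 2, 2), ...) {
  phantom_spec(shape = shape, pitch = pitch, n_objects = n,
               jitter_sd = jitter_sd, noise_sd = noise_sd, seed = seed, ...)
}

# a stack holding a single analytic Gaussian bead, for centroid tests
single_bead_stack <- function(center, sigma = c(6, 2, 2),
                              pitch = c(2, 2, 2), shape = c(60L, 24L, 24L),
                              peak = 10000, z0 = 0, channel_id = "473") {
  vox <- array(0, shape)
  vox <- chromaxial:::add_blob(vox, center, sigma, pitch, z0, peak,
                               extent = 20)
  channel_stack(round(vox), dx = pitch[3], dy = pitch[2], dz = pitch[1],
                z0 = z0, channel_id = channel_id)
}

# minimal ImageJ .roi rectangle file written byte-by-byte
write_imagej_rect <- function(path, top, left, bottom, right) {
  be_short <- function(v) as.raw(c(v %/% 256, v %% 256))
  raw <- c(charToRaw("Iout"),        # magic
           be_short(228),            # version
           as.raw(c(1, 0)),          # type: rectangle
           be_short(top), be_short(left), be_short(bottom), be_short(right),
           raw(64 - 16))
  writeBin(raw, path)
  invisible(path)
}
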