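# shared fixture builders; everything is generated in code at test time

default_schedule <- function(n = 20) stim_schedule(n_stims = n)

# white-noise trial matrix laid out as 30 s trials at the two-photon rate
null_trials <- function(n_trials, fs = 7.63, seed = 1) {
  with_seed <- nvpipe:::with_seed
  len <- round(30 * fs)
  with_seed(seed, matrix(rnorm(n_trials * len), n_trials, len))
}

# straight-tube phantom shared by anatomy tests
tube_phantom <- function(radius = 3, length_um = 150, voxel = c(1, 1, 1),
                         seed = 1, noise_sd = 5) {
  gen_anatomy_stack(list(list(p0 = c(5, 20, 15), p1 = c(5 + length_um, 20, 15),
                              radius = radius)),
                    voxel_size = voxel, noise_sd = noise_sd, seed = seed)
}
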