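# shared fixtures: small synthetic scenes and movies built in code

test_camera <- function() camera_slb()

# a single-emitter scene of oligomer order n, fully labeled, centred field
one_emitter_scene <- function(n = 1, field_um = 3.2, seed = 1) {
  cfg <- scene_config(field_size_um = field_um, n_emitters = 1,
                      oligomer_fractions = c(rep(0, n - 1), 1),
                      labeling_p = 1, min_separation_nm = 0,
                      border_margin_nm = field_um * 350)  # keep PSF well inside
  generate_scene(cfg, seed = seed)
}

# small dimer/trimer field for pipeline-level tests
small_mixture_movie <- function(n_emitters = 120, field_um = 12.8,
                                labeling_p = 0.7, n_frames = 60,
                                seed = 7) {
  cfg <- scene_config(field_size_um = field_um, n_emitters = n_emitters,
                      oligomer_fractions = c(0, 0.5, 0.5),
                      labeling_p = labeling_p, min_separation_nm = 800)
  sc <- generate_scene(cfg, seed = seed)
  list(scene = sc,
       movie = render_movie(sc, n_frames = n_frames, seed = seed + 1))
}

# synthetic calibration object without running mclust
fixed_calibration <- function(mu1 = 300, sigma1 = 75) {
  structure(list(mu1 = mu1, sigma1 = sigma1, n_particles = 1000L),
            class = "monomer_calibration")
}
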