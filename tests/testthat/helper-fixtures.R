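# Small layouts and configs shared across tests; everything is generated in
# code so the suite needs no stored data.

tiny_layout <- function() build_layout(1, 6, 2, 3, well_pitch = 120,
                                       well_diameter = 90)

small_layout <- function(wells = 500, rows = 20, cols = 25) {
  build_layout(1, wells, rows, cols)
}

quiet_config <- function(...) {
  # no optics: ideal rendering for exact-value checks
  sim_config(psf_sigma = 0, read_noise_sd = 0, negative_sd = 1e-9,
             positive_sd = 1e-9, ...)
}

# random invertible homography with a dominant affine part, as a scanner
# would produce (mild keystone)
random_homography <- function() {
  repeat {
    H <- matrix(c(runif(1, 0.5, 2), runif(1, -0.2, 0.2), runif(1, -50, 50),
                  runif(1, -0.2, 0.2), runif(1, 0.5, 2), runif(1, -50, 50),
                  runif(1, -1e-4, 1e-4), runif(1, -1e-4, 1e-4), 1),
                3, 3, byrow = TRUE)
    if (abs(det(H)) > 1e-3) return(H)
  }
}

apply_h <- function(H, xy) {
  p <- H %*% rbind(t(xy), 1)
  cbind(p[1, ] / p[3, ], p[2, ] / p[3, ])
}

uniform_image <- function(value, h, w, channels = "FAM") {
  planes <- lapply(channels, function(ch) matrix(as.integer(value), h, w))
  names(planes) <- channels
  structure(planes, class = "chip_image")
}
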