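# Shared builders for flat-spectrum closed-form scenarios.

flat_spec <- function(v = 1, unit = "relative", grid = canonical_grid()) {
  spectrum(grid, rep(v, length(grid)), unit)
}

# Flat light field already on the photon scale so closed-form algebra is
# unaffected by the energy->photon reweighting.
flat_lf <- function(L = 1, sigma = 0.2, shading = "average",
                    unit = "photon_radiance") {
  light_field_scenario(10, flat_spec(L, unit), flat_spec(L * sigma, unit),
                       shading, flat_spec(sigma, "fraction"))
}

flat_gamm <- function(Rcx = 0.3, Rnc = 0.05, Rbody = 0.05, Tbody = 0.6,
                      eye_radius = 0.0625) {
  gammarid_optics(eye_radius, flat_spec(Rcx), flat_spec(Rnc), Rcx / Rnc,
                  flat_spec(Rbody), flat_spec(Tbody, "fraction"))
}

# Visual system with fully transparent ocular media, for closed forms.
flat_vs <- function() viewer_visual_system(T_om = flat_spec(1, "fraction"))

make_qc <- function(qs, qd) {
  structure(list(q_single = qs, q_double = qd), class = "quantum_catches")
}

# NA means "never detectable": shorter than any realised distance.
dist0 <- function(x) ifelse(is.na(x), 0, x)
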