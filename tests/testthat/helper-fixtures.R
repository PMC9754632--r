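# Shared experimental constants used across the suite: the reference
# magnetization context (Mv = 250 A/m, grad(B) = 170 T/m, f = 4.25e4 N/m^3)
# and the 530 um reference spheroid.
ref_ctx <- function() magnetic_context(Mv = 250, gradB = 170)
ref_R_m <- 530e-6
ref_V_m3 <- 4 / 3 * pi * ref_R_m^3

# forward-generated noise-free landmarks at a given surface tension (mN/m)
forward_landmarks <- function(gamma, ctx = ref_ctx(), V = ref_V_m3) {
  cc <- force_density(ctx) / (gamma * 1e-3)
  sol <- solve_shape_for_volume(cc, V, keep_path = FALSE)
  landmark_set(h = sol$h * 1e6, w = sol$w * 1e6, V = sol$V * 1e18)
}
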