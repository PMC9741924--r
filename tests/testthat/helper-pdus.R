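# Shared fixtures: presets and small rendered frame pairs built in code.

preset5 <- pd_preset("5MHz")
preset20 <- pd_preset("20MHz")

# small clutter-only field + grid for fast rendering tests
small_setup <- function(frame_mm = c(3, 3), seed = 1, preset = preset5, M = 1) {
  grid <- preset_grid(preset, frame_mm, M = M)
  pulse <- preset$pulse
  vol <- c(frame_mm[1] + 2.5, 3, frame_mm[2] + 2.5)
  field <- scatterer_field(pulse, volume_dims = vol,
                           tau_beta = preset$tau_beta, roi = list(), seed = seed)
  list(field = field, grid = grid, pulse = pulse)
}

# render a frame pair where the second frame's scatterers are shifted by
# (dx, dy, dz) mm; returns list(f1, f2, grid, pulse)
shifted_pair <- function(d, seed = 1, frame_mm = c(3, 3), preset = preset5) {
  s <- small_setup(frame_mm, seed, preset)
  f1 <- pdus:::render_frames(s$field, motion_model(), s$pulse, s$grid)[, , 1]
  s2 <- s$field
  s2$positions <- sweep(s$field$positions, 2, d, "+")
  f2 <- pdus:::render_frames(s2, motion_model(), s$pulse, s$grid)[, , 1]
  list(f1 = f1, f2 = f2, grid = s$grid, pulse = s$pulse)
}
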