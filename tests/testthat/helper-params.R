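# Calibrated parameterisations used throughout: each law tuned so a
# post-division pair (separation 0.3) reaches 99% of the rest length at 1 h.
calib_cubic <- function() force_params("cubic", mu = 5.7)

calib_pwq <- function() force_params("pwq", mu_R = 9.1, m = 0.21)

# strategy 1: breadth fitted to the cubic law's adhesive magnitude (leaves an
# O(0.02) jump at the cutoff); strategy 2: breadth from the small-jump rule.
calib_gls <- function(strategy = 2) {
  alpha <- if (strategy == 1) 7.51 else alpha_small_jump(1.95, 1, 1.5, eps = 1e-3)
  force_params("gls", mu = 1.95, alpha = alpha)
}

calib_all <- function() {
  list(cubic = calib_cubic(), pwq = calib_pwq(), gls = calib_gls(2))
}
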