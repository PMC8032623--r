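# Shared fixtures built in code.

# Small, fast human-like parameter set used where absolute calibration
# does not matter: two tissues (brain + liver) plus lung, flows summing
# to the cardiac output.
toy_params <- function(ps_brain = 0.5, fu_brain = 0.1, cl = 5,
                       ps_liver = 20) {
  tis <- data.frame(
    name = c("brain", "liver"),
    volume_vascular = c(0.07, 0.30),
    volume_tissue = c(1.45, 1.80),
    blood_flow = c(40, 60),
    PS = c(ps_brain, ps_liver),
    fu_tissue = c(fu_brain, 0.05)
  )
  pbpk_params(
    body_weight = 73, cardiac_output = 100,
    blood_volumes = list(venous = 3.4, arterial = 1.8),
    lung = list(volume_vascular = 0.15, volume_tissue = 0.5,
                PS = 50, fu_tissue = 0.05),
    tissues = tis, hepatic_clearance = cl,
    compound = compound_properties()
  )
}

# Degenerate parameterization approximating a single well-mixed blood
# pool of volume V with clearance CL: all tissue PS = 0 except a huge
# liver PS with fu = 1 and negligible liver tissue volume, very large
# cardiac output so mixing is much faster than elimination.
onecomp_params <- function(V = 5, CL = 0.5, CO = 1e5) {
  v_small <- 0.01
  tis <- data.frame(
    name = c("brain", "liver"),
    volume_vascular = c(v_small, v_small),
    volume_tissue = c(v_small, 1e-4),
    blood_flow = c(CO / 2, CO / 2),
    PS = c(0, 1e6),
    fu_tissue = c(1, 1)
  )
  p <- pbpk_params(
    body_weight = 73, cardiac_output = CO,
    blood_volumes = list(venous = V - 4 * v_small - 1e-4,
                         arterial = v_small),
    lung = list(volume_vascular = v_small, volume_tissue = v_small,
                PS = 0, fu_tissue = 1),
    tissues = tis, hepatic_clearance = CL,
    compound = compound_properties(fu_plasma = 1, blood_plasma_ratio = 1)
  )
  p
}

# total accessible volume of the one-compartment construction (liver
# tissue equilibrates 1:1 through the huge PS)
onecomp_volume <- function(p) {
  p$blood_volumes$venous + p$blood_volumes$arterial +
    p$lung$volume_vascular + sum(p$tissues$volume_vascular) +
    p$tissues$volume_tissue[p$tissues$name == "liver"]
}

# fast reverse-dosimetry config: single 24-h window after one bolus
fast_cfg <- function(metric = "AUC", dose_min = 0.01, dose_max = 5000) {
  revdose_config(metric = metric, n_doses = 1L, window = c(0, 24),
                 duration = 24, grid_step = 0.2, dose_min = dose_min,
                 dose_max = dose_max)
}

# exp5 truth used across BMD recovery checks
recovery_truth <- function(sd = 5) {
  chat_truth_params(family = "exp5", a = 100, b = 0.06414, d = 1.5,
                    c = 0.55, sd = sd, n = 5L)
}
recovery_doses <- c(0, 0.5, 1, 2, 4, 8)
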