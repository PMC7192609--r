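# shared fixtures: printed fit parameters from a dGTP calibration run
# (blank and 3 pmol wells) reused across kinetics/binding tests
blank_params <- list(A1 = 28869, k1 = 2.0e-4, F0 = 35978)
dgtp3_params <- list(A1 = 6393, k1 = 2.5e-3, A2 = 23485, k2 = 1.1e-4,
                     F0 = 35540)
# dTTP fast-phase relative-amplitude quadratic-binding parameters
dttp_quad <- list(A_quad = 0.660, F0 = 0.054, E_T = 8.345, K_app = 0.741)

split_schedule <- function() acquisition_schedule(c(100, 200), c(13, 80))
fast_config <- function(...) fit_config(max_lag_s = 0, ...)
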