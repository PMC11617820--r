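# Shared fixtures: a small bare scenario builder used across test files.
make_scenario <- function(load = 1000, area = 100, kp = 0.1, ksc = 2e-6,
                          ko = 0, kww = 0, wear_h = 2, horizon_h = wear_h,
                          oral_events = list(), wash_at_min = numeric()) {
  exposure_scenario(
    product = textile_product(load, area),
    rates = rate_constants(kp_per_min = kp, ksc_per_h = ksc,
                           ko_per_min = ko, kww_per_min = kww),
    wear_intervals = wear_schedule(horizon_h, wear_h),
    horizon_min = horizon_h * 60,
    oral_events = oral_events,
    wash_at_min = wash_at_min)
}

# Random but valid parameter draws for property-style tests.
random_scenarios <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    make_scenario(load = runif(1, 10, 3000),
                  area = runif(1, 1, 2000),
                  kp = runif(1, 0.001, 0.3),
                  ksc = runif(1, 0, 50e-6),
                  ko = runif(1, 0, 0.001),
                  kww = runif(1, 0, 0.001),
                  wear_h = runif(1, 0.5, 4),
                  horizon_h = 4)
  })
}
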