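# Shared helpers for the test suite. All fixtures are built in code.

# maximum relative difference, with an absolute floor so compartments that
# are mathematically tiny do not inflate the metric
max_rel_diff <- function(x, ref, floor = 1e-9 * max(abs(ref), 1)) {
  max(abs(x - ref) / pmax(abs(ref), floor))
}

state_vec <- function(state) unname(unclass(state)[c("C1", "C2", "C3", "C4")])

# wide matrix (times x subsets) from a time_course tibble
tc_matrix <- function(tc) {
  times <- sort(unique(tc$time_days))
  m <- sapply(c("DN3", "DN4", "ISP", "DP"), function(s) {
    rows <- tc[tc$subset == s, ]
    rows$count[match(times, rows$time_days)]
  })
  rownames(m) <- NULL
  m
}

# random positive parameter set: rates log-uniform in [1e-3, 1] /day,
# influx log-uniform in [1e3, 1e6] cells/day (Kd2 = Kd3 = 0 unless asked)
random_params <- function(with_influx = TRUE, free_kd23 = FALSE) {
  r <- exp(runif(5, log(1e-3), log(1)))
  rate_parameters(
    K = if (with_influx) exp(runif(1, log(1e3), log(1e6))) else 0,
    K1 = r[1], Kd1 = r[2], K2 = r[3], K3 = r[4], Kd4 = r[5],
    Kd2 = if (free_kd23) exp(runif(1, log(1e-3), log(1))) else 0,
    Kd3 = if (free_kd23) exp(runif(1, log(1e-3), log(1))) else 0,
    label = "random")
}

acd3_C0 <- function() compartment_state(0, C1 = 3e8)

# the reference 3-hour grid over 3 days
acd3_grid <- function() seq(0, 3, by = 0.125)

# fixed parameters for a steady-state fit with the given free set, taking
# every other rate from the WT preset
wt_fixed_except <- function(free) {
  wt <- preset_parameters("WT")
  fixed <- wt[setdiff(c("K", "K1", "Kd1", "K2", "Kd2", "K3", "Kd3", "Kd4"),
                      free)]
  fixed
}
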