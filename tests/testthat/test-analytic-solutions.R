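test_that("exact steady state matches the balance formulas", {
  wt <- preset_parameters("WT")
  ss <- steady_state_exact(wt)
  expect_true(is.infinite(unclass(ss)[["t"]]))
  # flux balance by hand: C1 = K/(K1+Kd1), then each stage passes its
  # forward flux downstream
  expect_equal(unclass(ss)[["C1"]], 154000 / 0.2)
  expect_equal(unclass(ss)[["C2"]], 154000 * 0.1 / (0.2 * 0.162))
  expect_equal(unclass(ss)[["C3"]], 154000 * 0.1 / (0.2 * 0.07))
  expect_equal(unclass(ss)[["C4"]], 154000 * 0.1 / (0.2 * 0.00058))

  none <- rate_parameters(K = 0, K1 = 0.1, Kd1 = 0.1, K2 = 0.2, K3 = 0.1,
                          Kd4 = 0.01)
  expect_equal(state_vec(steady_state_exact(none)), rep(0, 4))

  expect_error(steady_state_exact(
    rate_parameters(K = 10, K1 = 0.1, Kd1 = 0, K2 = 0.1, K3 = 0.1,
                    Kd4 = 0)), "no finite steady state")
  expect_error(steady_state_exact(
    rate_parameters(K = 10, K1 = 0, Kd1 = 0, K2 = 0.1, K3 = 0.1,
                    Kd4 = 0.1)), "K1\\+Kd1")
})

test_that("knockout:wild-type steady-state ratios are the exact rationals", {
  wt <- state_vec(steady_state_exact(preset_parameters("WT")))
  ko <- state_vec(steady_state_exact(preset_parameters("Itpkb-KO")))
  # exact rational arithmetic on the balance formulas: doubling K1 and
  # tripling K2, K3 at fixed influx gives 2/3, 4/9, 4/9, 4/3
  expect_equal(ko / wt, c(2 / 3, 4 / 9, 4 / 9, 4 / 3), tolerance = 1e-12)
})

test_that("steady state is a fixed point of the rate equations", {
  for (g in preset_genotypes()) {
    p <- preset_parameters(g)
    C <- state_vec(steady_state_exact(p))
    dC <- c(p$K - (p$K1 + p$Kd1) * C[1],
            p$K1 * C[1] - (p$K2 + p$Kd2) * C[2],
            p$K2 * C[2] - (p$K3 + p$Kd3) * C[3],
            p$K3 * C[3] - p$Kd4 * C[4])
    expect_lt(max(abs(dC)), 1e-8 * max(p$K, 1))
  }
})

test_that("simplified steady state agrees with the exact one when DN4/ISP turnover vanishes", {
  p <- preset_parameters("WT")  # Kd2 = Kd3 = 0
  expect_equal(state_vec(steady_state_approx(p)),
               state_vec(steady_state_exact(p)), tolerance = 1e-12)
  expect_equal(unclass(steady_state_approx(p))[["C2"]],
               154000 * 0.1 / (0.162 * 0.2))
  # violating the smallness assumption with Kd2 = K2 doubles the DN4 error
  q <- rate_parameters(K = 1e5, K1 = 0.1, Kd1 = 0.1, K2 = 0.2, Kd2 = 0.2,
                       K3 = 0.1, Kd4 = 0.001)
  expect_equal(unclass(steady_state_approx(q))[["C2"]] /
                 unclass(steady_state_exact(q))[["C2"]], 2,
               tolerance = 1e-12)
  expect_error(steady_state_approx(
    rate_parameters(K = 1, K1 = 0.1, Kd1 = 0.1, K2 = 0, K3 = 0.1,
                    Kd4 = 0.1)), "K2, K3 and Kd4")
})

test_that("closed-form transient matches hand evaluation and the start state", {
  p <- preset_parameters("Rag2-WT")
  C0 <- acd3_C0()
  at0 <- transient_solution(p, C0, 0)
  expect_equal(unclass(at0), unclass(C0))
  at2 <- transient_solution(p, C0, 2)
  expect_equal(unclass(at2)[["C1"]], 3e8 * exp(-0.4), tolerance = 1e-12)
  expect_error(transient_solution(preset_parameters("WT"), C0, 1),
               "requires K = 0")
})

test_that("closed-form transient agrees with the ODE oracle on a dense grid", {
  for (g in c("Rag2-WT", "Rag2-ItpkbKO")) {
    p <- preset_parameters(g)
    grid <- acd3_grid()
    analytic <- transient_solution(p, acd3_C0(), grid[-1])
    ode <- tc_matrix(integrate_ode(p, acd3_C0(), grid))[-1, ]
    expect_lt(max_rel_diff(analytic, ode, floor = 1e-6 * max(ode)), 1e-6)
  }
})

test_that("matrix-exponential solver matches the closed form and its limits", {
  p <- preset_parameters("Rag2-ItpkbKO")
  grid <- acd3_grid()[-1]
  closed <- transient_solution(p, acd3_C0(), grid)
  spectral <- spectral_solution(p, acd3_C0(), grid)
  expect_lt(max_rel_diff(spectral, closed, floor = 1e-9 * max(closed)),
            1e-10)
  # exactly repeated decay rates: finite output matching the ODE oracle
  d <- rate_parameters(K = 0, K1 = 0.1, Kd1 = 0.1, K2 = 0.2, K3 = 0.07,
                       Kd4 = 0.00058, label = "degenerate")
  times <- c(1, 2, 3)
  sp <- spectral_solution(d, acd3_C0(), times)
  ode <- tc_matrix(integrate_ode(d, acd3_C0(), c(0, times)))[-1, ]
  expect_true(all(is.finite(sp)))
  expect_lt(max_rel_diff(sp, ode, floor = 1e-6 * max(ode)), 1e-6)
  # long-time limit: by 5e4 days even the slow DP mode (1/Kd4 ~ 1724 days)
  # has relaxed, so the trajectory sits on the fixed point
  wt <- preset_parameters("WT")
  far <- spectral_solution(wt, compartment_state(0), 5e4)
  expect_lt(max_rel_diff(state_vec(far),
                         state_vec(steady_state_exact(wt))), 1e-6)
})

test_that("inputs outside the closed form dispatch to the general solver", {
  p <- preset_parameters("Rag2-WT")
  C0 <- compartment_state(0, C1 = 1e6, C2 = 1e4)
  expect_message(out <- transient_solution(p, C0, 1), "spectral_solution")
  direct <- spectral_solution(p, C0, 1)
  expect_equal(unclass(out), unclass(direct))
  d <- rate_parameters(K = 0, K1 = 0.1, Kd1 = 0.1, K2 = 0.2, K3 = 0.07,
                       Kd4 = 0.00058)
  expect_message(transient_solution(d, acd3_C0(), 1), "spectral_solution")
})

test_that("random parameter sets: matrix-exponential solver matches the ODE oracle", {
  set.seed(42)
  C0 <- compartment_state(0, C1 = 1e5, C2 = 2e4, C3 = 3e4, C4 = 4e4)
  times <- c(0.5, 1, 2, 5, 10, 25, 50)
  for (i in 1:100) {
    p <- random_params(with_influx = TRUE, free_kd23 = (i %% 2 == 0))
    sp <- spectral_solution(p, C0, times)
    ode <- tc_matrix(integrate_ode(p, C0, c(0, times)))[-1, ]
    expect_lt(max_rel_diff(sp, ode, floor = 1e-6 * max(ode)), 1e-6)
  }
})

test_that("speeding up differentiation depletes DN4/ISP and spares DN3/DP", {
  set.seed(7)
  for (i in 1:25) {
    p <- random_params(with_influx = TRUE)
    lam <- exp(runif(1, log(1.2), log(5)))
    sped <- rate_parameters(K = p$K, K1 = lam * p$K1, Kd1 = p$Kd1,
                            K2 = lam * p$K2, K3 = lam * p$K3, Kd4 = p$Kd4)
    a <- state_vec(steady_state_exact(p))
    b <- state_vec(steady_state_exact(sped))
    expect_lt(b[2], a[2])  # DN4 strictly down
    expect_lt(b[3], a[3])  # ISP strictly down
    expect_gt(b[4], a[4])  # DP up
    # DN3 shrinks exactly by the effective exit-rate ratio
    expect_equal(a[1] / b[1], (lam * p$K1 + p$Kd1) / (p$K1 + p$Kd1),
                 tolerance = 1e-12)
  }
})

test_that("knockout DP counts dominate wild-type at every transient grid time", {
  grid <- acd3_grid()[-1]
  wt <- transient_solution(preset_parameters("Rag2-WT"), acd3_C0(), grid)
  ko <- transient_solution(preset_parameters("Rag2-ItpkbKO"), acd3_C0(),
                           grid)
  expect_true(all(ko[, "DP"] > wt[, "DP"]))
})

test_that("closed forms stay non-negative on random non-negative input", {
  set.seed(11)
  times <- seq(0, 30, by = 0.5)
  for (i in 1:50) {
    p <- random_params(with_influx = (i %% 2 == 0))
    m <- spectral_solution(p, acd3_C0(), times)
    expect_true(all(m >= 0))
    if (p$K == 0) {
      mt <- suppressMessages(transient_solution(p, acd3_C0(), times))
      expect_true(all(mt >= 0))
    }
  }
})

test_that("DN4 peak time follows the closed form and its degenerate limit", {
  expect_equal(dn4_peak_time(preset_parameters("Rag2-WT")),
               log(0.162 / 0.2) / (0.162 - 0.2), tolerance = 1e-12)
  expect_equal(dn4_peak_time(preset_parameters("Rag2-ItpkbKO")),
               log(0.486 / 0.3) / (0.486 - 0.3), tolerance = 1e-12)
  # faster differentiation moves the peak earlier
  expect_lt(dn4_peak_time(preset_parameters("Rag2-ItpkbKO")),
            dn4_peak_time(preset_parameters("Rag2-WT")))
  degen <- rate_parameters(K = 0, K1 = 0.1, Kd1 = 0.1, K2 = 0.2, K3 = 0.07,
                           Kd4 = 0.00058)
  expect_equal(dn4_peak_time(degen), 5)
  # the closed-form peak actually maximises the DN4 curve
  p <- preset_parameters("Rag2-WT")
  tpk <- dn4_peak_time(p)
  f <- function(t) unclass(transient_solution(p, acd3_C0(), t))[["C2"]]
  expect_gt(f(tpk), f(tpk * 0.99))
  expect_gt(f(tpk), f(tpk * 1.01))
  expect_error(dn4_peak_time(preset_parameters("WT")), "K = 0")
})
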