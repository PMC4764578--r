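#' Numerical integration of the compartment model
#'
#' Integrates
#' \deqn{dC_1/dt = K - (K_1+K_{d1}) C_1,\quad
#'       dC_2/dt = K_1 C_1 - (K_2+K_{d2}) C_2,}
#' \deqn{dC_3/dt = K_2 C_2 - (K_3+K_{d3}) C_3,\quad
#'       dC_4/dt = K_3 C_3 - K_{d4} C_4}
#' with a stiff-safe adaptive method (`deSolve::lsoda`). This is an
#' independent check on the closed-form solvers, not the production path;
#' the output grid is an output grid, not the internal step size.
#'
#' @param params a [rate_parameters()] object.
#' @param C0 a [compartment_state()]; integration starts at `C0`'s time.
#' @param times strictly increasing output times in days, starting at the
#'   time of `C0`. Default: the 3-hour/3-day reference grid.
#' @param rel_tol relative tolerance, in (0, 1e-3]. Default 1e-8; absolute
#'   tolerance is fixed at 1e-6 cells.
#' @return A [time_course()] tibble with `engine = "ode"`.
#' @examples
#' p <- preset_parameters("Rag2-ItpkbKO")
#' integrate_ode(p, compartment_state(0, C1 = 3e8))
#' @export
integrate_ode <- function(params, C0, times = seq(0, 3, by = 0.125),
                          rel_tol = 1e-8) {
  validate_parameters(params)
  if (!(rel_tol > 0 && rel_tol <= 1e-3))
    stop("rel_tol must lie in (0, 1e-3]", call. = FALSE)
  t0 <- unclass(C0)[["t"]]
  if (length(times) < 1 || times[1] != t0 ||
      (length(times) > 1 && any(diff(times) <= 0)))
    stop("times must be strictly increasing and start at C0's time",
         call. = FALSE)
  A <- system_matrix(params)
  b <- c(params$K, 0, 0, 0)
  rhs <- function(t, y, ...) list(as.vector(A %*% y + b))
  sol <- deSolve::lsoda(y = unname(state_counts(C0)), times = times,
                        func = rhs, rtol = rel_tol, atol = 1e-6)
  m <- unname(sol[, 2:5, drop = FALSE])
  m[m < 0 & m > -1e-6] <- 0  # integrator round-off only
  time_course(times, m, engine = "ode", label = params$label)
}

#' Exact stochastic simulation of the compartment model
#'
#' Simulates the continuous-time Markov jump process whose mean-field limit
#' is the ODE model, by the direct (next-reaction-time) method. Reactions:
#' influx into DN3 at rate `K`; for each stage, differentiation to the next
#' stage and loss, with per-cell (intensive) rates, so scaled-down initial
#' counts sample the same per-cell dynamics. Used to verify the
#' deterministic solvers at the population scale where demographic noise is
#' visible.
#'
#' @param params a [rate_parameters()] object.
#' @param C0 a [compartment_state()] with integer counts.
#' @param t_max end time in days.
#' @param seed integer seed; identical `(params, C0, t_max, seed)` give a
#'   bit-identical trajectory. The seed is echoed in the result's
#'   `seed` attribute.
#' @param record_times optional times at which the state is recorded
#'   (piecewise-constant interpolation of the jump trajectory). Default:
#'   the 3-hour grid up to `t_max`.
#' @return A [time_course()] tibble with `engine = "ssa"` and attribute
#'   `seed`.
#' @examples
#' p <- preset_parameters("Rag2-ItpkbKO")
#' sim <- simulate_ssa(p, compartment_state(0, C1 = 1e4), t_max = 2, seed = 1)
#' @export
simulate_ssa <- function(params, C0, t_max, seed,
                         record_times = NULL) {
  validate_parameters(params)
  counts <- unname(state_counts(C0))
  if (any(counts != round(counts)))
    stop("simulate_ssa requires integer initial counts", call. = FALSE)
  if (is.null(record_times))
    record_times <- seq(unclass(C0)[["t"]], t_max, by = 0.125)
  if (any(diff(record_times) <= 0) || t_max < max(record_times))
    stop("record_times must be strictly increasing and <= t_max",
         call. = FALSE)
  rates <- unlist(params[rate_names])
  m <- with_seed(as.integer(seed), {
    ssa_chain_cpp(rates, as.double(round(counts)),
                  as.double(unclass(C0)[["t"]]), as.double(record_times))
  })
  tc <- time_course(record_times, m, engine = "ssa", label = params$label)
  attr(tc, "seed") <- as.integer(seed)
  tc
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
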