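#' Exact steady state of the compartment model
#'
#' With constant influx the linear system has a unique globally attracting
#' fixed point obtained by balancing influx against outflux in each stage:
#' \deqn{C_1 = K/(K_1+K_{d1}),\quad
#'       C_2 = K K_1 / ((K_1+K_{d1})(K_2+K_{d2})),}
#' \deqn{C_3 = K K_1 K_2 / ((K_1+K_{d1})(K_2+K_{d2})(K_3+K_{d3})),\quad
#'       C_4 = K K_1 K_2 K_3 / (K_{d4}(K_1+K_{d1})(K_2+K_{d2})(K_3+K_{d3})).}
#'
#' @param params a [rate_parameters()] object with `K1+Kd1 > 0`,
#'   `K2+Kd2 > 0`, `K3+Kd3 > 0` and, if `K > 0`, `Kd4 > 0`.
#' @return A [compartment_state()] with `t = Inf`.
#' @examples
#' steady_state_exact(preset_parameters("WT"))
#' @export
steady_state_exact <- function(params) {
  validate_parameters(params)
  e1 <- params$K1 + params$Kd1
  e2 <- params$K2 + params$Kd2
  e3 <- params$K3 + params$Kd3
  if (e1 <= 0 || e2 <= 0 || e3 <= 0)
    stop("steady state needs K1+Kd1, K2+Kd2 and K3+Kd3 all > 0",
         call. = FALSE)
  if (params$Kd4 <= 0) {
    if (params$K > 0)
      stop("no finite steady state for DP: Kd4 = 0 with positive influx",
           call. = FALSE)
    return(compartment_state(Inf))
  }
  C1 <- params$K / e1
  C2 <- C1 * params$K1 / e2
  C3 <- C2 * params$K2 / e3
  C4 <- C3 * params$K3 / params$Kd4
  compartment_state(Inf, C1, C2, C3, C4)
}

#' Simplified steady state
#'
#' When the DN4 and ISP turnover rates are small compared with their
#' differentiation rates (`K2/(K2+Kd2) ~ 1`, `K3/(K3+Kd3) ~ 1`) the exact
#' fixed point reduces to
#' \deqn{C_1 \approx K/(K_1+K_{d1}),\quad C_2 \approx K K_1/(K_2 (K_1+K_{d1})),}
#' \deqn{C_3 \approx K K_1/(K_3 (K_1+K_{d1})),\quad
#'       C_4 \approx K K_1/(K_{d4} (K_1+K_{d1})).}
#' This form makes the model's central qualitative prediction legible:
#' raising `K1`, `K2`, `K3` together at fixed influx leaves DN3 and DP pools
#' comparatively stable while depleting DN4 and ISP.
#'
#' @inheritParams steady_state_exact
#' @return A [compartment_state()] with `t = Inf`.
#' @export
steady_state_approx <- function(params) {
  validate_parameters(params)
  e1 <- params$K1 + params$Kd1
  if (e1 <= 0)
    stop("steady state needs K1+Kd1 > 0", call. = FALSE)
  if (params$K2 <= 0 || params$K3 <= 0 || params$Kd4 <= 0)
    stop("simplified steady state needs K2, K3 and Kd4 all > 0",
         call. = FALSE)
  C1 <- params$K / e1
  compartment_state(Inf,
                    C1,
                    C1 * params$K1 / params$K2,
                    C1 * params$K1 / params$K3,
                    C1 * params$K1 / params$Kd4)
}
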