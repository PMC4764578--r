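#' Configuration for rate-constant fitting
#'
#' The estimator is least squares on `log(count + pseudo_count)`: log-scale
#' residuals match the multiplicative noise of cell-count data and the
#' pseudo-count keeps the loss finite when event sampling produces zeros.
#' Optimisation runs on log-parameters (positivity by construction) with
#' box bounds, from `n_starts` log-uniform starting points; a fit is
#' declared converged only when the restarts agree, which guards against
#' the shallow valley between `K1` and `Kd1`.
#'
#' @param free character vector of parameters to estimate, a subset of
#'   `c("K", "K1", "Kd1", "K2", "Kd2", "K3", "Kd3", "Kd4")`.
#' @param fixed named list giving values for the parameters not in `free`.
#'   Defaults to the no-influx scenario with published turnover:
#'   `K = 0, Kd2 = 0, Kd3 = 0, Kd4 = 0.00058` (DP turnover is weakly
#'   identifiable over a 3-day window and is fixed by default; freeing it is
#'   allowed but will typically inflate the restart dispersion).
#' @param lower,upper named bounds on the natural scale; defaults
#'   `[1e-6, 10]` /day for rates and `[1, 1e7]` cells/day for `K`.
#' @param pseudo_count added inside the logarithm; default 0.5.
#' @param n_starts number of multi-start restarts; default 8.
#' @param tol optimizer tolerance (relative reduction in loss); default 1e-8.
#' @param seed seed for the restart draws; default 1.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(free = c("K1", "Kd1", "K2", "K3"),
                       fixed = list(K = 0, Kd2 = 0, Kd3 = 0, Kd4 = 0.00058),
                       lower = NULL, upper = NULL,
                       pseudo_count = 0.5, n_starts = 8, tol = 1e-8,
                       seed = 1) {
  free <- unique(as.character(free))
  if (!all(free %in% rate_names))
    stop("unknown free parameter(s): ",
         paste(setdiff(free, rate_names), collapse = ", "), call. = FALSE)
  lo <- stats::setNames(rep(1e-6, length(free)), free)
  hi <- stats::setNames(rep(10, length(free)), free)
  lo[free == "K"] <- 1; hi[free == "K"] <- 1e7
  if (!is.null(lower)) lo[names(lower)] <- unlist(lower)
  if (!is.null(upper)) hi[names(upper)] <- unlist(upper)
  if (any(lo <= 0) || any(lo >= hi))
    stop("bounds must satisfy 0 < lower < upper", call. = FALSE)
  structure(list(free = free, fixed = fixed, lower = lo, upper = hi,
                 pseudo_count = pseudo_count, n_starts = as.integer(n_starts),
                 tol = tol, seed = as.integer(seed)),
            class = "fit_config")
}

# Build a rate_parameters object from free values (named) plus config$fixed.
assemble_params <- function(theta, config, label = "fit") {
  v <- as.list(config$fixed)
  v[names(theta)] <- as.list(theta)
  missing <- setdiff(rate_names, names(v))
  if (length(missing))
    stop("no value (free or fixed) for parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  rate_parameters(K = v$K, K1 = v$K1, Kd1 = v$Kd1, K2 = v$K2, K3 = v$K3,
                  Kd4 = v$Kd4, Kd2 = v$Kd2, Kd3 = v$Kd3, label = label)
}

# Shared multi-start optimiser: minimises sum of squared log-scale
# residuals returned by resid_fun(params) over log-parameters.
multistart_fit <- function(resid_fun, config) {
  free <- config$free
  llo <- log(config$lower); lhi <- log(config$upper)
  obj <- function(lp) {
    theta <- stats::setNames(exp(lp), free)
    r <- tryCatch(resid_fun(assemble_params(theta, config)),
                  error = function(e) NULL)
    if (is.null(r) || anyNA(r)) return(1e12)
    sum(r^2)
  }
  starts <- with_seed(config$seed, {
    s <- matrix(stats::runif(config$n_starts * length(free)),
                config$n_starts, length(free))
    sweep(sweep(s, 2, lhi - llo, "*"), 2, llo, "+")
  })
  # first start at the geometric mid-point of the box: a neutral default
  starts[1, ] <- (llo + lhi) / 2
  fits <- lapply(seq_len(config$n_starts), function(i) {
    ans <- stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                        lower = llo, upper = lhi,
                        control = list(maxit = 1000,
                                       factr = config$tol / 1e-15))
    # L-BFGS-B can report convergence on a bound face of the K1/Kd1
    # valley; a derivative-free polish followed by a re-projection
    # reliably walks off it
    if (length(free) > 1) {
      nm <- stats::optim(ans$par, obj, method = "Nelder-Mead",
                         control = list(maxit = 2000,
                                        reltol = config$tol))
      ans2 <- stats::optim(pmin(pmax(nm$par, llo), lhi), obj,
                           method = "L-BFGS-B", lower = llo, upper = lhi,
                           control = list(maxit = 1000,
                                          factr = config$tol / 1e-15))
      if (ans2$value < ans$value) ans <- ans2
    }
    list(par = stats::setNames(exp(ans$par), free), loss = ans$value,
         ok = ans$convergence == 0)
  })
  losses <- vapply(fits, `[[`, 0, "loss")
  best <- fits[[which.min(losses)]]
  ests <- do.call(rbind, lapply(fits, `[[`, "par"))
  dispersion <- max(vapply(seq_along(free), function(j) {
    x <- ests[, j]
    (max(x) - min(x)) / max(abs(x), 1e-300)
  }, 0))
  restarts <- tibble::tibble(
    start = seq_len(config$n_starts), loss = losses,
    ok = vapply(fits, `[[`, TRUE, "ok"))
  list(estimates = best$par, loss = best$loss,
       converged = best$ok && dispersion <= 1e-3,
       dispersion = dispersion, restarts = restarts)
}

new_fit_result <- function(fit, config, model, n_obs) {
  structure(c(fit, list(config = config, model = model, n_obs = n_obs)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> model:", x$model, "| n_obs:", x$n_obs, "\n")
  print(signif(x$estimates, 6))
  cat(sprintf("loss = %.6g | converged = %s | restart dispersion = %.3g\n",
              x$loss, x$converged, x$dispersion))
  if (!is.null(x$intervals)) {
    cat("bootstrap 95% percentile intervals:\n")
    print(x$intervals)
  }
  invisible(x)
}

check_single_genotype <- function(data) {
  g <- unique(as.character(data$genotype))
  if (length(g) != 1)
    stop("fit one genotype at a time; filter the dataset first (found: ",
         paste(g, collapse = ", "), ")", call. = FALSE)
  g
}

log_residuals <- function(obs, pred, pc) log(obs + pc) - log(pred + pc)

#' Fit rate constants to an anti-CD3 time course
#'
#' Estimates differentiation (and optionally turnover) rates from per-mouse
#' subset counts observed at fixed days after synchronised release from the
#' DN3 arrest. Predictions come from the exact no-influx solution (with the
#' matrix-exponential fallback near rate degeneracies); the loss is summed
#' squared residuals on `log(count + pseudo_count)` over every
#' (mouse, subset) observation.
#'
#' @param data an `observed_dataset` from an `"acd3_timecourse"` design,
#'   restricted to a single genotype.
#' @param config a [fit_config()]; default frees `K1, Kd1, K2, K3`.
#' @param C0 initial state; taken from the dataset's design metadata when
#'   omitted.
#' @return A `fit_result` with estimates on the natural scale, final loss,
#'   convergence flag and restart dispersion.
#' @examples
#' d <- experiment_design("acd3_timecourse", "Rag2-ItpkbKO",
#'                        mice_per_group = 5)
#' obs <- generate_dataset(d, noise_model(cv = 0.05), seed = 1)
#' fit_transient(obs, fit_config(n_starts = 4))
#' @export
fit_transient <- function(data, config = fit_config(), C0 = NULL) {
  check_single_genotype(data)
  if ("K" %in% config$free)
    stop("the time-course design has no progenitor influx; K cannot be a ",
         "free parameter here", call. = FALSE)
  observed <- unique(as.character(data$subset))
  if (all(c("K1", "Kd1") %in% config$free) &&
      all(observed %in% "DN3"))
    stop("identifiability: with only DN3 observed, K1 and Kd1 enter the ",
         "model only through their sum K1+Kd1 and cannot both be free",
         call. = FALSE)
  if (is.null(C0)) {
    design <- attr(data, "design")
    C0 <- if (!is.null(design)) design$C0 else
      stop("C0 not supplied and not recoverable from the dataset",
           call. = FALSE)
  }
  if (any(is.na(data$time_days)))
    stop("time-course fit requires time_days for every observation",
         call. = FALSE)
  times <- sort(unique(data$time_days))
  sub_idx <- as.integer(factor(as.character(data$subset),
                               levels = subset_names))
  time_idx <- match(data$time_days, times)
  pc <- config$pseudo_count
  resid_fun <- function(params) {
    if (params$K > 0) stop("K must be 0 in the transient model")
    pred <- solve_grid(params, C0, times)
    log_residuals(data$count, pred[cbind(time_idx, sub_idx)], pc)
  }
  fit <- multistart_fit(resid_fun, config)
  new_fit_result(fit, config, "transient", nrow(data))
}

# Closed form when applicable, otherwise matrix exponential; plain matrix out.
solve_grid <- function(params, C0, times) {
  rates <- c(params$K1 + params$Kd1, params$K2, params$K3, params$Kd4)
  if (params$K == 0 && params$Kd2 == 0 && params$Kd3 == 0 &&
      sum(state_counts(C0)[-1]) == 0 && !rates_degenerate(rates)) {
    m <- transient_matrix(params, unclass(C0)[["C1"]], times)
    m[m < 0] <- 0
    m
  } else {
    m <- spectral_solution(params, C0, times)
    if (length(times) == 1L) m <- matrix(unclass(m)[-1], 1L)
    m
  }
}

#' Fit influx and DP turnover to a steady-state cross-section
#'
#' The steady state exposes only four observable combinations of the eight
#' rates, so at most `K` (overall scale) and `Kd4` (DP pool relative to the
#' upstream flux) can be freed with the remaining rates fixed; any other
#' free set raises an identifiability error rather than returning a
#' silently unidentified fit.
#'
#' @param data an `observed_dataset` from a `"steady_state_crosssection"`
#'   design, restricted to a single genotype.
#' @param config a [fit_config()] whose `free` is a subset of
#'   `c("K", "Kd4")` and whose `fixed` carries the remaining rates.
#' @return A `fit_result`.
#' @export
fit_influx_steady <- function(data, config) {
  check_single_genotype(data)
  extra <- setdiff(config$free, c("K", "Kd4"))
  if (length(extra))
    stop("identifiability: the steady state determines only 4 observable ",
         "combinations; free parameters must be a subset of {K, Kd4} ",
         "(offending: ", paste(extra, collapse = ", "), ")", call. = FALSE)
  sub_idx <- as.integer(factor(as.character(data$subset),
                               levels = subset_names))
  pc <- config$pseudo_count
  resid_fun <- function(params) {
    ss <- unname(unclass(steady_state_exact(params))[-1])
    log_residuals(data$count, ss[sub_idx], pc)
  }
  fit <- multistart_fit(resid_fun, config)
  new_fit_result(fit, config, "steady_state", nrow(data))
}

#' Case-resampling bootstrap intervals for a fit
#'
#' Resamples mice with replacement within (genotype, time) strata, refits
#' each replicate starting from the point estimate, and reports percentile
#' 95% intervals. Replicates that fail to converge are dropped; a failure
#' rate above 5% is flagged.
#'
#' @param data the `observed_dataset` used for the original fit.
#' @param fit the `fit_result` to wrap intervals around.
#' @param B number of bootstrap replicates, >= 100.
#' @param seed integer seed for the resampling.
#' @return The `fit_result` with added fields `intervals` (tibble:
#'   parameter, lower, upper), `bootstrap_estimates` (replicate draws) and
#'   `bootstrap_failure_rate`.
#' @export
bootstrap_ci <- function(data, fit, B = 200, seed = 1) {
  stopifnot(inherits(fit, "fit_result"))
  if (B < 100) stop("B must be >= 100", call. = FALSE)
  config <- fit$config
  # replicate fits start from the point estimate, with a couple of
  # perturbed restarts to keep the convergence guard meaningful
  boot_config <- config
  boot_config$n_starts <- 3L
  mice <- data |>
    dplyr::distinct(.data$mouse_id, .data$genotype, .data$time_days)
  refit <- function(d) {
    if (fit$model == "transient")
      fit_transient(d, boot_config, C0 = attr(data, "design")$C0)
    else fit_influx_steady(d, boot_config)
  }
  draws <- with_seed(as.integer(seed), {
    lapply(seq_len(B), function(b) {
      resampled <- mice |>
        dplyr::group_by(.data$genotype, .data$time_days) |>
        dplyr::slice_sample(prop = 1, replace = TRUE) |>
        dplyr::ungroup() |>
        dplyr::mutate(new_id = sprintf("b%05d", dplyr::row_number()))
      d <- dplyr::inner_join(
        resampled, data,
        by = c("mouse_id", "genotype", "time_days"),
        relationship = "many-to-many")
      d$mouse_id <- d$new_id
      bf <- tryCatch(refit(d), error = function(e) NULL)
      if (is.null(bf) || !bf$converged) return(NULL)
      bf$estimates
    })
  })
  ok <- !vapply(draws, is.null, TRUE)
  est <- do.call(rbind, draws[ok])
  failure_rate <- 1 - mean(ok)
  intervals <- tibble::tibble(
    parameter = config$free,
    lower = apply(est, 2, stats::quantile, 0.025, names = FALSE),
    upper = apply(est, 2, stats::quantile, 0.975, names = FALSE))
  fit$intervals <- intervals
  fit$bootstrap_estimates <- tibble::as_tibble(est)
  fit$bootstrap_failure_rate <- failure_rate
  fit$bootstrap_flagged <- failure_rate > 0.05
  fit$bootstrap_seed <- as.integer(seed)
  fit
}

#' Fold changes between two genotype fits
#'
#' For every parameter free in both fits, reports the knockout-to-wild-type
#' ratio of the estimates; when both fits carry bootstrap replicates, a
#' percentile interval for each fold change is added (replicates paired by
#' index, valid because the two fits are independent).
#'
#' @param fit_wt,fit_ko converged `fit_result`s with overlapping free sets.
#' @return A tibble with columns `parameter, wt, ko, fold_change` and,
#'   when available, `fold_lower, fold_upper`.
#' @export
compare_genotype_fits <- function(fit_wt, fit_ko) {
  shared <- intersect(names(fit_wt$estimates), names(fit_ko$estimates))
  if (!length(shared))
    stop("the two fits share no free parameters", call. = FALSE)
  if (!fit_wt$converged || !fit_ko$converged)
    warning("comparing fits that did not both converge")
  out <- tibble::tibble(
    parameter = shared,
    wt = unname(fit_wt$estimates[shared]),
    ko = unname(fit_ko$estimates[shared]),
    fold_change = unname(fit_ko$estimates[shared] /
                           fit_wt$estimates[shared]))
  bw <- fit_wt$bootstrap_estimates; bk <- fit_ko$bootstrap_estimates
  if (!is.null(bw) && !is.null(bk)) {
    n <- min(nrow(bw), nrow(bk))
    out$fold_lower <- out$fold_upper <- NA_real_
    for (i in seq_along(shared)) {
      p <- shared[i]
      if (p %in% names(bw) && p %in% names(bk)) {
        ratio <- bk[[p]][seq_len(n)] / bw[[p]][seq_len(n)]
        out$fold_lower[i] <- stats::quantile(ratio, 0.025, names = FALSE)
        out$fold_upper[i] <- stats::quantile(ratio, 0.975, names = FALSE)
      }
    }
  }
  out
}

#' Serialize a fit result to JSON
#'
#' Writes estimates, loss, convergence status, restart dispersion, optional
#' intervals and a config echo (free set, fixed values, bounds, seeds).
#'
#' @param fit a `fit_result`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  x <- list(
    model = fit$model,
    estimates = as.list(fit$estimates),
    loss = fit$loss,
    converged = fit$converged,
    restart_dispersion = fit$dispersion,
    n_obs = fit$n_obs,
    intervals = if (!is.null(fit$intervals)) fit$intervals,
    bootstrap_failure_rate = fit$bootstrap_failure_rate,
    bootstrap_seed = fit$bootstrap_seed,
    config = list(free = fit$config$free, fixed = fit$config$fixed,
                  lower = as.list(fit$config$lower),
                  upper = as.list(fit$config$upper),
                  pseudo_count = fit$config$pseudo_count,
                  n_starts = fit$config$n_starts, tol = fit$config$tol,
                  seed = fit$config$seed))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  invisible(path)
}
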