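#' Noise model for synthetic subset counts
#'
#' Describes how true compartment sizes become per-mouse observations.
#' `"lognormal-cv"` multiplies each subset count by an independent lognormal
#' factor with unit median and the stated coefficient of variation, keeping
#' counts positive and log-scale residuals homoscedastic. `"multinomial-events"`
#' emulates finite flow-cytometry event sampling: `n_events` events are
#' drawn from the four-subset proportions and rescaled to the mouse's total
#' cellularity. `"both"` composes them (lognormal per-mouse variability,
#' then event sampling).
#'
#' @param kind one of `"lognormal-cv"`, `"multinomial-events"`, `"both"`.
#' @param cv coefficient of variation of the multiplicative per-mouse noise
#'   (default 0.05).
#' @param n_events flow events recorded per mouse when event sampling is on
#'   (default 1e5).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("lognormal-cv", "multinomial-events", "both"),
                        cv = 0.05, n_events = 1e5) {
  kind <- match.arg(kind)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (n_events < 1) stop("n_events must be >= 1", call. = FALSE)
  structure(list(kind = kind, cv = cv, n_events = n_events),
            class = "noise_model")
}

#' Observation design for synthetic experiments
#'
#' Two designs mirror the model's two observable settings:
#' `"steady_state_crosssection"` samples unperturbed mice whose expected
#' subset counts are the model's fixed point, and `"acd3_timecourse"`
#' samples groups of recombination-deficient mice at fixed days after
#' anti-CD3 injection, starting from 3e8 DN3 cells with influx 0.
#'
#' @param scenario `"steady_state_crosssection"` or `"acd3_timecourse"`.
#' @param genotypes named list of [rate_parameters()], names used as
#'   genotype labels; or a character vector of preset genotype names.
#' @param times sampling times in days (ignored for the steady-state
#'   design); default `c(0, 0.5, 1, 1.5, 2, 2.5, 3)`.
#' @param mice_per_group virtual mice per (genotype, time) cell; default 20.
#' @param C0 initial state for the time-course design; default
#'   `compartment_state(0, C1 = 3e8)`.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(scenario = c("steady_state_crosssection",
                                           "acd3_timecourse"),
                              genotypes = c("WT", "Itpkb-KO"),
                              times = c(0, 0.5, 1, 1.5, 2, 2.5, 3),
                              mice_per_group = 20,
                              C0 = compartment_state(0, C1 = 3e8)) {
  scenario <- match.arg(scenario)
  if (is.character(genotypes)) {
    genotypes <- stats::setNames(lapply(genotypes, preset_parameters),
                                 vapply(genotypes, function(g)
                                   normalize_genotype(g), ""))
  }
  stopifnot(is.list(genotypes), length(genotypes) >= 1,
            !is.null(names(genotypes)))
  lapply(genotypes, validate_parameters)
  if (mice_per_group < 1) stop("mice_per_group must be >= 1", call. = FALSE)
  times <- sort(unique(as.numeric(times)))
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  if (scenario == "acd3_timecourse") {
    bad <- names(genotypes)[vapply(genotypes, function(p) p$K > 0, TRUE)]
    if (length(bad))
      stop("acd3_timecourse requires K = 0 presets; offending genotype(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(scenario = scenario, genotypes = genotypes, times = times,
                 mice_per_group = as.integer(mice_per_group), C0 = C0),
            class = "experiment_design")
}

# Expected (noise-free) counts for one genotype at the design's conditions:
# a matrix with one row per design time (a single row for the steady state).
design_truth <- function(design, params) {
  if (design$scenario == "steady_state_crosssection") {
    ss <- steady_state_exact(params)
    matrix(unname(unclass(ss)[-1]), nrow = 1L,
           dimnames = list(NULL, subset_names))
  } else {
    m <- time_course_matrix(solve_analytic(params, design$C0, design$times))
    if (length(design$times) == 1L)
      dimnames(m) <- list(NULL, subset_names)
    m
  }
}

#' Generate a synthetic observed dataset
#'
#' For every virtual mouse the true compartment sizes are computed from the
#' model (fixed point for the cross-section design, exact transient solution
#' for the time-course design) and perturbed by the noise model. The result
#' is deterministic under `(design, noise, seed)`.
#'
#' @param design an [experiment_design()].
#' @param noise a [noise_model()]. `noise_model(cv = 0)` with lognormal kind
#'   reproduces the model values exactly.
#' @param seed integer seed for the noise draws.
#' @param round_counts round counts to integers (half-even)? Default
#'   `FALSE`: the model is continuous and counts are kept real.
#' @return A tibble with columns `mouse_id, genotype, time_days, subset,
#'   count` (class `observed_dataset`), carrying `design`, `noise`, `seed`
#'   and the generating parameters as attributes.
#' @examples
#' d <- experiment_design("steady_state_crosssection", mice_per_group = 3)
#' generate_dataset(d, noise_model(cv = 0.05), seed = 1)
#' @export
generate_dataset <- function(design, noise = noise_model(), seed,
                             round_counts = FALSE) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(noise, "noise_model"))
  times <- if (design$scenario == "steady_state_crosssection") NA_real_
           else design$times
  rows <- with_seed(as.integer(seed), {
    out <- list()
    mouse <- 0L
    for (g in names(design$genotypes)) {
      truth <- design_truth(design, design$genotypes[[g]])
      for (i in seq_along(times)) {
        mu <- truth[min(i, nrow(truth)), ]
        for (m in seq_len(design$mice_per_group)) {
          mouse <- mouse + 1L
          counts <- mu
          if (noise$kind %in% c("lognormal-cv", "both") && noise$cv > 0) {
            sdlog <- sqrt(log(1 + noise$cv^2))
            counts <- counts * exp(stats::rnorm(4, 0, sdlog))
          }
          if (noise$kind %in% c("multinomial-events", "both")) {
            total <- sum(counts)
            if (total > 0) {
              ev <- stats::rmultinom(1, size = noise$n_events,
                                     prob = counts / total)[, 1]
              counts <- ev / noise$n_events * total
            }
          }
          out[[mouse]] <- tibble::tibble(
            mouse_id = sprintf("m%04d", mouse), genotype = g,
            time_days = times[i], subset = subset_names,
            count = unname(counts))
        }
      }
    }
    dplyr::bind_rows(out)
  })
  if (round_counts) rows$count <- round(rows$count)
  rows$subset <- factor(rows$subset, levels = subset_names)
  structure(rows, class = c("observed_dataset", class(rows)),
            design = design, noise = noise, seed = as.integer(seed),
            true_parameters = design$genotypes)
}

#' Summarise an observed dataset
#'
#' Per (genotype, time, subset): number of mice, mean count and standard
#' error of the mean (reported as `NA` for single-mouse groups). Also
#' returns the per-mouse DN3:DN4 count ratio and its group mean, the
#' model's steady-state diagnostic for accelerated DN3 exit.
#'
#' @param data an `observed_dataset` (or any tibble with the same columns).
#' @return A list with tibbles `counts` (n, mean, sem per group/subset) and
#'   `dn3_dn4_ratio` (per-group mean ratio, n).
#' @export
summarize_dataset <- function(data) {
  if (nrow(data) == 0) stop("empty dataset", call. = FALSE)
  counts <- data |>
    dplyr::group_by(.data$genotype, .data$time_days, .data$subset) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$count),
      sem = if (dplyr::n() > 1)
        stats::sd(.data$count) / sqrt(dplyr::n()) else NA_real_,
      .groups = "drop")
  ratios <- per_mouse_ratio(data) |>
    dplyr::group_by(.data$genotype, .data$time_days) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_ratio = mean(.data$ratio),
                     .groups = "drop")
  list(counts = counts, dn3_dn4_ratio = ratios)
}

# per-mouse DN3/DN4 count ratio
per_mouse_ratio <- function(df) {
  df |>
    dplyr::group_by(.data$mouse_id, .data$genotype, .data$time_days) |>
    dplyr::summarise(
      ratio = .data$count[.data$subset == "DN3"] /
        .data$count[.data$subset == "DN4"],
      .groups = "drop")
}

#' Write / read an observed dataset
#'
#' Tidy CSV (`mouse_id, genotype, time_days, subset, count`) plus a JSON
#' sidecar (`<path>.json`) recording the design, noise model, seed and true
#' generating parameters.
#'
#' @param data an `observed_dataset`.
#' @param path CSV path; the sidecar goes to `paste0(path, ".json")`.
#' @return The path (write) / a tibble with sidecar metadata attached if
#'   present (read).
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   quote = FALSE)
  design <- attr(data, "design"); noise <- attr(data, "noise")
  side <- list(
    seed = attr(data, "seed"),
    noise = if (!is.null(noise)) unclass(noise),
    scenario = if (!is.null(design)) design$scenario,
    times = if (!is.null(design)) design$times,
    mice_per_group = if (!is.null(design)) design$mice_per_group,
    true_parameters = lapply(attr(data, "true_parameters"),
                             function(p) p[c(rate_names, "label")]))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  df$subset <- factor(df$subset, levels = subset_names)
  df <- structure(df, class = c("observed_dataset", class(df)))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    attr(df, "sidecar") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df
}
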