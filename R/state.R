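subset_names <- c("DN3", "DN4", "ISP", "DP")

#' Compartment state of the four-stage model
#'
#' One snapshot of the population sizes `C1`-`C4` of the DN3, DN4, ISP and
#' DP compartments at time `t` (days). Populations are continuous cell
#' numbers; a steady state carries `t = Inf` as an explicit marker.
#'
#' @param t time in days, >= 0 (or `Inf` for a steady state).
#' @param C1,C2,C3,C4 population sizes of DN3, DN4, ISP, DP; >= 0.
#' @return An object of class `compartment_state` (named numeric vector
#'   `t, C1, C2, C3, C4`).
#' @examples
#' compartment_state(0, C1 = 3e8)  # the anti-CD3 initial condition
#' @export
compartment_state <- function(t, C1 = 0, C2 = 0, C3 = 0, C4 = 0) {
  x <- c(t = as.numeric(t), C1 = as.numeric(C1), C2 = as.numeric(C2),
         C3 = as.numeric(C3), C4 = as.numeric(C4))
  if (anyNA(x) || any(x[-1] < 0) || x[["t"]] < 0 || any(!is.finite(x[-1])))
    stop("compartment state needs t >= 0 and finite populations >= 0",
         call. = FALSE)
  structure(x, class = "compartment_state")
}

#' @export
print.compartment_state <- function(x, ...) {
  tlab <- if (is.infinite(x[["t"]])) "steady state" else
    sprintf("t = %g days", x[["t"]])
  cat("<compartment_state> ", tlab, "\n", sep = "")
  print(stats::setNames(unclass(x)[-1], subset_names))
  invisible(x)
}

state_counts <- function(state) unclass(state)[c("C1", "C2", "C3", "C4")]

#' Assemble a time course of compartment states
#'
#' A tidy tibble with one row per (time, compartment) pair and a provenance
#' tag naming the engine that produced it (`"analytic"`, `"ode"` or
#' `"ssa"`). Times must be strictly increasing and populations non-negative.
#'
#' @param times numeric vector of times in days, strictly increasing.
#' @param counts numeric matrix, `length(times)` rows by 4 columns
#'   (DN3, DN4, ISP, DP).
#' @param engine provenance tag.
#' @param label genotype or run tag.
#' @return A tibble with columns `engine, label, time_days, subset, count`,
#'   class `time_course`.
#' @export
time_course <- function(times, counts, engine = c("analytic", "ode", "ssa"),
                        label = "custom") {
  engine <- match.arg(engine)
  counts <- matrix(as.numeric(counts), nrow = length(times), ncol = 4L)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("time course requires strictly increasing times", call. = FALSE)
  if (any(counts < -1e-9 * max(1, max(abs(counts)))))
    stop("time course contains negative populations", call. = FALSE)
  tc <- tibble::tibble(
    engine = engine, label = label,
    time_days = rep(times, times = 4L),
    subset = factor(rep(subset_names, each = length(times)),
                    levels = subset_names),
    count = as.vector(counts))
  class(tc) <- c("time_course", class(tc))
  tc
}

# Wide matrix view (rows = times, cols = DN3..DP) of a time_course tibble.
time_course_matrix <- function(tc) {
  times <- sort(unique(tc$time_days))
  m <- matrix(NA_real_, length(times), 4L,
              dimnames = list(NULL, subset_names))
  for (s in subset_names) {
    rows <- tc[tc$subset == s, ]
    m[match(rows$time_days, times), s] <- rows$count
  }
  attr(m, "time_days") <- times
  m
}

#' Write / read a time course as tidy CSV
#'
#' Columns `run_id, engine, label, time_days, subset, count`; comma
#' separator, header row, UTF-8, `.` decimal.
#'
#' @param tc a [time_course()] tibble.
#' @param path output CSV path.
#' @param run_id identifier recorded in the `run_id` column.
#' @return The path (write) or a `time_course` tibble (read), invisibly for
#'   the writer.
#' @export
write_time_course <- function(tc, path, run_id = "run1") {
  out <- cbind(run_id = run_id, as.data.frame(tc))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_time_course
#' @export
read_time_course <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tc <- tibble::as_tibble(df[setdiff(names(df), "run_id")])
  tc$subset <- factor(tc$subset, levels = subset_names)
  class(tc) <- c("time_course", class(tc))
  tc
}
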