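#' Rate parameters of the beta-selection compartment model
#'
#' Bundles the eight rate constants of the linear four-compartment model of
#' thymocyte development: a constant progenitor influx `K` feeding the DN3
#' pool, forward differentiation rates `K1` (DN3 to DN4), `K2` (DN4 to ISP)
#' and `K3` (ISP to DP), and per-stage net turnover rates `Kd1`-`Kd4`.
#' Turnover is the net per-capita loss of a compartment (death minus
#' proliferation); the model treats it as non-negative.
#'
#' `Kd2` and `Kd3` default to 0: DN4 and ISP cells are highly proliferative
#' with viability similar to their neighbours, so their net turnover is small
#' compared with their differentiation rates and the published parameter sets
#' omit them. Both fields are kept explicit so users can override them.
#'
#' @param K progenitor influx into DN3, cells/day. Must be finite and >= 0.
#' @param K1,K2,K3 differentiation rates DN3->DN4, DN4->ISP, ISP->DP, 1/day.
#' @param Kd1,Kd2,Kd3,Kd4 turnover rates of DN3, DN4, ISP, DP, 1/day.
#' @param label free-text genotype tag carried through downstream results.
#'
#' @return An object of class `rate_parameters`: a named list with the eight
#'   rates (numeric scalars) and the label.
#' @examples
#' p <- rate_parameters(K = 1.54e5, K1 = 0.1, Kd1 = 0.1, K2 = 0.162,
#'                      K3 = 0.07, Kd4 = 0.00058, label = "WT")
#' k1_tilde(p)
#' @seealso [preset_parameters()] for the published parameter sets.
#' @export
rate_parameters <- function(K, K1, Kd1, K2, K3, Kd4, Kd2 = 0, Kd3 = 0,
                            label = "custom") {
  p <- structure(
    list(K = as.numeric(K), K1 = as.numeric(K1), Kd1 = as.numeric(Kd1),
         K2 = as.numeric(K2), Kd2 = as.numeric(Kd2), K3 = as.numeric(K3),
         Kd3 = as.numeric(Kd3), Kd4 = as.numeric(Kd4),
         label = as.character(label)[1]),
    class = "rate_parameters")
  validate_parameters(p)
  p
}

#' @export
print.rate_parameters <- function(x, ...) {
  cat("<rate_parameters> ", x$label, "\n", sep = "")
  cat(sprintf("  K   = %g cells/day (progenitor influx)\n", x$K))
  cat(sprintf("  K1  = %g, K2 = %g, K3 = %g /day (differentiation)\n",
              x$K1, x$K2, x$K3))
  cat(sprintf("  Kd1 = %g, Kd2 = %g, Kd3 = %g, Kd4 = %g /day (turnover)\n",
              x$Kd1, x$Kd2, x$Kd3, x$Kd4))
  invisible(x)
}

rate_names <- c("K", "K1", "Kd1", "K2", "Kd2", "K3", "Kd3", "Kd4")

#' Validate a rate-parameter set
#'
#' Checks that all eight rates are finite, numeric scalars and non-negative.
#' Called by every constructor and solver entry point; exposed so that
#' hand-built lists can be checked too.
#'
#' @param p a `rate_parameters` object or a named list with the eight rates.
#' @return `p`, invisibly, if valid; otherwise an error.
#' @export
validate_parameters <- function(p) {
  for (nm in rate_names) {
    v <- p[[nm]]
    if (is.null(v) || length(v) != 1L || !is.numeric(v) || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    if (v < 0)
      stop("parameter '", nm, "' must be >= 0 (got ", v, ")", call. = FALSE)
  }
  invisible(p)
}

# Published parameter sets, one row per genotype. Units: K cells/day, rest /day.
.presets <- list(
  "WT"           = list(K = 15.4e4, K1 = 0.1, Kd1 = 0.1, K2 = 0.162,
                        K3 = 0.07, Kd4 = 0.00058),
  "Itpkb-KO"     = list(K = 15.4e4, K1 = 0.2, Kd1 = 0.1, K2 = 0.486,
                        K3 = 0.21, Kd4 = 0.00058),
  "Rag2-WT"      = list(K = 0, K1 = 0.1, Kd1 = 0.1, K2 = 0.162,
                        K3 = 0.07, Kd4 = 0.00058),
  "Rag2-ItpkbKO" = list(K = 0, K1 = 0.2, Kd1 = 0.1, K2 = 0.486,
                        K3 = 0.21, Kd4 = 0.00058)
)

# Normalise a genotype label: case-insensitive, punctuation-insensitive,
# with the aliases users actually write for knockout nomenclature.
normalize_genotype <- function(genotype) {
  stopifnot(is.character(genotype), length(genotype) == 1L)
  key <- tolower(gsub("[^a-z0-9+]", "", tolower(genotype)))
  aliases <- c(
    "wt" = "WT", "itpkb++" = "WT",
    "itpkbko" = "Itpkb-KO", "itpkb" = "Itpkb-KO", "ko" = "Itpkb-KO",
    "rag2wt" = "Rag2-WT", "rag2itpkbwt" = "Rag2-WT", "rag2itpkb++" = "Rag2-WT",
    "rag2itpkbko" = "Rag2-ItpkbKO", "rag2ko" = "Rag2-ItpkbKO",
    "rag2itpkb" = "Rag2-ItpkbKO")
  if (!key %in% names(aliases))
    stop("unknown genotype '", genotype, "'; expected one of ",
         paste(names(.presets), collapse = ", "), call. = FALSE)
  unname(aliases[[key]])
}

#' Published rate-constant presets by genotype
#'
#' Returns the rate constants used for the four modeled genotypes. `WT` and
#' `Itpkb-KO` describe unperturbed mice with constant progenitor influx; the
#' two `Rag2-*` presets describe recombination-deficient mice whose
#' thymocytes are arrested at DN3 until anti-CD3 injection, so their influx
#' `K` is 0 (progenitor arrival over the 3-day observation window is
#' negligible). The Itpkb-deficient sets carry two-fold or larger increases
#' in all three differentiation rates (`K1` 0.1 -> 0.2, `K2` 0.162 -> 0.486,
#' `K3` 0.07 -> 0.21 per day) with influx and turnover unchanged.
#'
#' @param genotype one of `"WT"`, `"Itpkb-KO"`, `"Rag2-WT"`,
#'   `"Rag2-ItpkbKO"` (case- and punctuation-insensitive; common knockout
#'   spellings such as `"Itpkb-/-"` or `"Rag2-/-Itpkb-/-"` are accepted).
#' @return A [rate_parameters()] object with `Kd2 = Kd3 = 0`.
#' @examples
#' preset_parameters("WT")
#' preset_parameters("Rag2-/-Itpkb-/-")
#' @export
preset_parameters <- function(genotype) {
  canon <- normalize_genotype(genotype)
  v <- .presets[[canon]]
  rate_parameters(K = v$K, K1 = v$K1, Kd1 = v$Kd1, K2 = v$K2, K3 = v$K3,
                  Kd4 = v$Kd4, label = canon)
}

#' Genotypes with a published preset
#' @return Character vector of canonical genotype labels.
#' @export
preset_genotypes <- function() names(.presets)

#' Effective DN3 exit rate
#'
#' The DN3 compartment empties by differentiation and turnover together, so
#' its exponential decay (and the steady-state DN3 pool) is governed by the
#' combined rate `K1 + Kd1`, conventionally written with a tilde.
#'
#' @param params a [rate_parameters()] object.
#' @return `K1 + Kd1`, 1/day.
#' @export
k1_tilde <- function(params) {
  validate_parameters(params)
  params$K1 + params$Kd1
}

#' Read / write rate parameters
#'
#' Flat JSON or YAML files with keys `K, K1, Kd1, K2, Kd2, K3, Kd3, Kd4,
#' label`. Units are cells/day for `K` and 1/day for the rest. The format is
#' chosen by file extension (`.json`, `.yaml`/`.yml`).
#'
#' @param params a [rate_parameters()] object.
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `write_parameters()` returns `path` invisibly; `read_parameters()`
#'   returns a validated [rate_parameters()] object.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  x <- params[c(rate_names, "label")]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path, precision = 15L)
  } else stop("unsupported parameter file extension: ", path, call. = FALSE)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else stop("unsupported parameter file extension: ", path, call. = FALSE)
  missing <- setdiff(rate_names, names(x))
  if (length(missing))
    stop("parameter file lacks keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  rate_parameters(K = x$K, K1 = x$K1, Kd1 = x$Kd1, K2 = x$K2, K3 = x$K3,
                  Kd4 = x$Kd4, Kd2 = x$Kd2, Kd3 = x$Kd3,
                  label = x$label %||% "custom")
}
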