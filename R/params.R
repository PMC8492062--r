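#' @useDynLib zebracpg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm filter median sd setNames
#' @importFrom utils modifyList write.csv
#' @importFrom graphics image matplot
#' @importFrom grDevices hcl.colors
NULL

MODEL_VARIANTS <- c("single_coiling", "double_coiling",
                    "beat_glide_base", "beat_glide_bursting_v2a",
                    "beat_glide_all_tonic")

.sheet_cache <- new.env(parent = emptyenv())

#' Load the parameter sheet of a model variant
#'
#' Each developmental model variant ships with a human-readable YAML sheet
#' holding its neuron membrane parameters, gap-junction and chemical synaptic
#' weights, reversal potentials and time constants, conduction speed, and
#' musculoskeletal constants. Any field can be overridden through the
#' \code{overrides} argument of the circuit factories.
#'
#' @param variant one of \code{"single_coiling"}, \code{"double_coiling"},
#'   \code{"beat_glide_base"}, \code{"beat_glide_bursting_v2a"},
#'   \code{"beat_glide_all_tonic"}.
#' @return a named list mirroring the YAML structure.
#' @export
model_param_sheet <- function(variant) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  if (!is.null(.sheet_cache[[variant]])) return(.sheet_cache[[variant]])
  path <- system.file("extdata", "params", paste0(variant, ".yaml"),
                      package = "zebracpg")
  if (!nzchar(path)) stop("parameter sheet not found for variant ", variant)
  sheet <- yaml::read_yaml(path)
  .sheet_cache[[variant]] <- sheet
  sheet
}

#' Apply dotted-path overrides to a parameter sheet
#'
#' Paths address nested fields, e.g. \code{"constants.cv"},
#' \code{"populations.V2a.I_drive"} or \code{"chem_weights.V0v-IC"}.
#'
#' @param sheet a list as returned by [model_param_sheet()].
#' @param overrides named list of replacement values.
#' @keywords internal
apply_overrides <- function(sheet, overrides) {
  if (is.null(overrides) || length(overrides) == 0L) return(sheet)
  if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
    stop("overrides must be a fully named list")
  for (path in names(overrides)) {
    keys <- strsplit(path, ".", fixed = TRUE)[[1]]
    node <- sheet
    for (i in seq_along(keys)[-length(keys)]) {
      if (is.null(node[[keys[i]]]))
        stop("unknown override path: ", path)
      node <- node[[keys[i]]]
    }
    if (is.null(node[[keys[length(keys)]]]))
      stop("unknown override path: ", path)
    sheet[[keys]] <- overrides[[path]]
  }
  sheet
}

#' Izhikevich membrane parameters for a population
#'
#' Returns the nine-parameter set (a, b, c, d, Vmax, Vr, Vt, k, C) of a named
#' population in a given model variant.
#'
#' @param kind population name (\code{"IC"}, \code{"MN"}, \code{"V0d"},
#'   \code{"dI6"}, \code{"V0v"}, \code{"V2a"}, \code{"V1"}).
#' @param variant model variant name, see [model_param_sheet()].
#' @return named numeric vector of length 9.
#' @export
#' @examples
#' izhikevich_params("MN", "single_coiling")
izhikevich_params <- function(kind, variant) {
  sheet <- model_param_sheet(variant)
  pop <- sheet$populations[[kind]]
  if (is.null(pop))
    stop("population ", kind, " is not part of model variant ", variant)
  p <- unlist(pop[c("a", "b", "c", "d", "Vmax", "Vr", "Vt", "k", "C")])
  validate_izh_params(p)
  p
}

validate_izh_params <- function(p) {
  stopifnot(is.numeric(p), length(p) == 9L, all(is.finite(p)))
  if (!(p[["Vr"]] < p[["Vt"]] && p[["Vt"]] < p[["Vmax"]]))
    stop("invalid membrane parameters: need Vr < Vt < Vmax")
  if (p[["C"]] <= 0) stop("invalid membrane parameters: C must be positive")
  invisible(p)
}
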