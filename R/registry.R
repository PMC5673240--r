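#' Registry of intrinsic electrophysiological properties
#'
#' The package works with a closed set of 11 intrinsic electrophysiological
#' (ephys) properties, each measured by intracellular recording. Every
#' operation that accepts a property code validates it against this registry.
#' Strictly positive, right-skewed properties (input resistance, membrane
#' time constant, spike half-width, capacitance, rheobase, maximum firing
#' rate) are modeled on the log10 scale; the registry records which.
#'
#' @return A tibble with one row per property and columns:
#'   \describe{
#'     \item{property}{short code (e.g. `"Vrest"`, `"Rin"`).}
#'     \item{label}{human-readable name.}
#'     \item{units}{measurement units expected on input (fixed; no unit
#'       conversion is performed).}
#'     \item{log10_transform}{`TRUE` if the property is log10-transformed
#'       before condition modeling and multivariate modeling.}
#'     \item{higher_is}{free-text polarity note.}
#'   }
#' @examples
#' ephys_properties()
#' @export
ephys_properties <- function() {
  tibble::tribble(
    ~property, ~label,                              ~units, ~log10_transform, ~higher_is,
    "Vrest",   "resting membrane potential",        "mV",   FALSE, "more depolarized at rest",
    "Rin",     "input resistance",                  "MOhm", TRUE,  "larger voltage response per injected current",
    "Tau",     "membrane time constant",            "ms",   TRUE,  "slower membrane charging",
    "Cm",      "membrane capacitance",              "pF",   TRUE,  "larger effective membrane area",
    "APamp",   "action potential amplitude",        "mV",   FALSE, "taller spikes",
    "APhw",    "action potential half-width",       "ms",   TRUE,  "broader spikes",
    "APthr",   "action potential threshold",        "mV",   FALSE, "spikes initiated at more depolarized voltages",
    "AHPamp",  "afterhyperpolarization amplitude",  "mV",   FALSE, "deeper post-spike hyperpolarization",
    "Rheo",    "rheobase",                          "pA",   TRUE,  "more current needed to elicit a spike",
    "FRmax",   "maximum firing rate",               "Hz",   TRUE,  "faster maximal spiking",
    "SFA",     "spike frequency adaptation ratio",  "",     FALSE, "values near 1 mean little adaptation; near 0, strong adaptation"
  )
}

#' Property codes registered in the package
#'
#' @param log10_only If `TRUE`, return only the codes modeled on the log10
#'   scale.
#' @return Character vector of property codes.
#' @export
ephys_property_codes <- function(log10_only = FALSE) {
  reg <- ephys_properties()
  if (log10_only) reg$property[reg$log10_transform] else reg$property
}

#' Validate ephys property codes against the registry
#'
#' @param property Character vector of codes.
#' @return The input, invisibly, if all codes are registered.
#' @keywords internal
assert_property <- function(property) {
  bad <- setdiff(unique(property), ephys_property_codes())
  if (length(bad) > 0) {
    stop("Unknown ephys property code(s): ", paste(bad, collapse = ", "),
         ". Registered codes: ", paste(ephys_property_codes(), collapse = ", "),
         call. = FALSE)
  }
  invisible(property)
}

#' Is a property modeled on the log10 scale?
#' @param property Character vector of registered codes.
#' @return Logical vector.
#' @keywords internal
is_log10_property <- function(property) {
  assert_property(property)
  property %in% ephys_property_codes(log10_only = TRUE)
}

# Move a native-units value onto the modeling scale (log10 for the
# positivity-constrained set, identity otherwise). Errors on non-positive
# values for log10 properties: those are physically impossible readings.
to_model_scale <- function(value, property) {
  if (is_log10_property(property)) {
    bad <- which(!is.na(value) & value <= 0)
    if (length(bad) > 0) {
      stop("Non-positive value for log10-scale property '", property,
           "' (record ", bad[1], "): ", value[bad[1]], call. = FALSE)
    }
    log10(value)
  } else {
    value
  }
}

from_model_scale <- function(value, property) {
  if (is_log10_property(property)) 10^value else value
}
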