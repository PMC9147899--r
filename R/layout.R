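#' Array layout metadata
#'
#' Describes the printed antigen density series, replication and the serum
#' dilution series of one microspot titration experiment.
#'
#' @param antigen_concs nominal printed antigen concentrations (M),
#'   strictly decreasing, all > 0. The lowest concentration is treated as
#'   the serum-specific background level downstream.
#' @param n_replicates spots printed per concentration (>= 1).
#' @param dilutions serum fold-dilutions (all >= 1).
#' @param channels character vector of detection channel labels.
#' @return An object of class \code{"array_layout"}.
#' @seealso [default_layout()]
#' @export
array_layout <- function(antigen_concs, n_replicates = 5,
                         dilutions = 100 * 3^(0:4),
                         channels = "IgG") {
  stopifnot(is.numeric(antigen_concs), is.numeric(dilutions))
  if (length(antigen_concs) < 2)
    stop("need at least 2 antigen concentrations (one is the background)")
  if (any(antigen_concs <= 0))
    stop("antigen concentrations must all be > 0")
  if (any(diff(antigen_concs) >= 0))
    stop("antigen concentrations must be strictly decreasing")
  if (n_replicates < 1) stop("'n_replicates' must be >= 1")
  if (any(dilutions < 1)) stop("fold-dilutions must all be >= 1")
  if (anyDuplicated(dilutions)) stop("duplicate fold-dilutions")
  if (length(channels) < 1 || anyDuplicated(channels))
    stop("'channels' must be non-empty and unique")
  structure(list(antigen_concs = as.numeric(antigen_concs),
                 n_replicates = as.integer(n_replicates),
                 dilutions = as.numeric(dilutions),
                 channels = as.character(channels)),
            class = "array_layout")
}

#' Default microspot array layout
#'
#' The standard layout: 7 antigen concentrations in half serial dilution
#' starting from 200 uM (2e-4 M), printed in quintuplicate, probed with a
#' serum dilution series in three-fold steps from 1:100. The
#' \code{monoclonal} variant replaces the serum series with a 10-step
#' half-dilution analyte series (a purified antibody titrated from a known
#' stock), starting at \code{z = 1}.
#'
#' @param monoclonal logical; use the monoclonal-antibody variant.
#' @param dilutions optional override of the dilution series.
#' @param channels channel labels, default \code{"IgG"}.
#' @return An [array_layout()] object.
#' @examples
#' default_layout()$antigen_concs * 1e6  # 200 100 50 25 12.5 6.25 3.125 uM
#' @export
default_layout <- function(monoclonal = FALSE, dilutions = NULL,
                           channels = "IgG") {
  concs <- 2e-4 * 0.5^(0:6)
  if (is.null(dilutions)) {
    dilutions <- if (monoclonal) 2^(0:9) else 100 * 3^(0:4)
  }
  array_layout(antigen_concs = concs, n_replicates = 5,
               dilutions = dilutions, channels = channels)
}

#' @export
print.array_layout <- function(x, ...) {
  cat("Microspot array layout\n")
  cat(sprintf("  antigen: %d concentrations, %s uM, x%d replicates\n",
              length(x$antigen_concs),
              paste(signif(x$antigen_concs * 1e6, 4), collapse = ", "),
              x$n_replicates))
  cat(sprintf("  dilutions: %s\n", paste(x$dilutions, collapse = ", ")))
  cat(sprintf("  channels: %s\n", paste(x$channels, collapse = ", ")))
  invisible(x)
}
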