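#' Smooth unit step
#'
#' Logistic step used to smooth every threshold in the model (activator
#' self-regulation switch, maturation stimulation, mesenchyme gates).
#' Converges to the Heaviside step as `eps -> 0`.
#'
#' @param z signed distance from the threshold.
#' @param eps smoothing width (same units as `z`); must be > 0.
#' @return values in (0, 1).
#' @keywords internal
smoothStep <- function(z, eps) {
  stopifnot(eps > 0)
  1 / (1 + exp(-pmin(pmax(z / eps, -50), 50)))
}

#' Log-spaced grid
#' @keywords internal
logSpace <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Deep-merge two nested lists (patch wins on leaves)
#' @keywords internal
mergeConfig <- function(base, patch) {
  if (is.null(patch)) return(base)
  for (nm in names(patch)) {
    if (is.list(patch[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- mergeConfig(base[[nm]], patch[[nm]])
    } else {
      base[[nm]] <- patch[[nm]]
    }
  }
  base
}

#' Flatten a nested list to dotted keys
#' @keywords internal
flattenConfig <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(x[[nm]])) {
      out <- c(out, flattenConfig(x[[nm]], key))
    } else {
      out[[key]] <- x[[nm]]
    }
  }
  out
}
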