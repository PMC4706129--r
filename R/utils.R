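#' Round half away from zero
#'
#' Deterministic edge-count rounding for density thresholding. Base R's
#' `round()` rounds halves to even; edge counts here use the convention that
#' exact halves round away from zero, so `round_half_away(2.5) == 3`.
#'
#' @param x numeric vector.
#' @return numeric vector of rounded values.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Every randomized stage (subject simulation, null-model replicates,
#' modularity restarts) draws its own sub-seed from a master seed and a
#' counter, so substreams are independent and removing one consumer does not
#' perturb the others.
#'
#' @param master integer master seed.
#' @param index non-negative integer counter identifying the substream.
#' @return a positive integer seed below 2^31 - 1.
#' @export
derive_seed <- function(master, index) {
  m <- as.numeric(master) %% 1000003
  s <- (m * 2011 + as.numeric(index) * 7919 + 1) %% 2147483647
  as.integer(s + (s == 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  invisible(x)
}
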