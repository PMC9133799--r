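#' @keywords internal
#' @useDynLib voxrecon, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

## Coordinate convention (used everywhere): pixel coordinates are 0-based,
## (row, col) order, origin at the top-left corner. Degrees of visual angle
## are measured from the image midpoint.

vr_stop <- function(...) stop(..., call. = FALSE)

vr_assert <- function(cond, ...) if (!isTRUE(cond)) vr_stop(...)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code never perturbs the
#' caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a named sub-seed from a root seed
#'
#' All randomness in the package flows from one root seed split into named
#' substreams, so that e.g. the image stream and the noise stream of the
#' simulator are independently reproducible.
#'
#' @param root Integer root seed.
#' @param name Character stream name.
#' @return Integer seed below 2^31.
#' @export
derive_seed <- function(root, name) {
  h <- 5381
  for (c in utf8ToInt(name)) h <- (h * 33 + c) %% 2147483647
  as.integer((abs(as.numeric(root)) * 48271 + h) %% 2147483647)
}

## Cheap stable checksum of a model's parameters (frozen-encoder assertions).
param_checksum <- function(params) {
  v <- unlist(params, use.names = FALSE)
  c(n = length(v), sum = sum(v), sumsq = sum(v * v), sum3 = sum(v^3))
}

## flatten/unflatten a nested list of numeric arrays (optimizer plumbing)
map_params <- function(params, f) {
  if (is.list(params)) return(lapply(params, map_params, f = f))
  f(params)
}

zeros_like <- function(params) map_params(params, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p)))
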