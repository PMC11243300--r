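#' @useDynLib sacflow, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor optimize rnorm runif setNames uniroot
#' @importFrom utils head read.csv tail write.csv
NULL

# Unit convention: SI internally (m, s, Pa, kg). Mesh files and user-facing
# geometric parameters are in mm; conversion happens at construction.
MM <- 1e-3

#' Default blood-like fluid properties
#'
#' Newtonian blood model: density 1000 kg/m^3, dynamic viscosity 0.004 Pa s.
#'
#' @param rho_f fluid density (kg/m^3)
#' @param mu dynamic viscosity (Pa s)
#' @return object of class `fluid_properties`
#' @export
fluid_properties <- function(rho_f = 1000, mu = 0.004) {
  stopifnot(rho_f > 0, mu > 0)
  structure(list(rho_f = rho_f, mu = mu, nu = mu / rho_f),
            class = "fluid_properties")
}

#' Derive per-case child seeds from one master seed
#'
#' Splitting rule: the master seed seeds R's RNG once and `n` child seeds are
#' drawn without replacement from 1..(2^31 - 2). Documented so that runs are
#' reproducible from the single master seed.
#'
#' @param master integer master seed
#' @param n number of child seeds
#' @return integer vector of length `n`
#' @export
split_seed <- function(master, n) {
  stopifnot(is.finite(master), n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master))
  sample.int(2147483646L, n)
}

# internal: run code with a local RNG seed, restoring global state
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# internal: stop with a classed condition so callers/tests can distinguish
# parameter errors from topology errors etc.
abort_sf <- function(msg, class) {
  stop(structure(class = c(class, "sacflow_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
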