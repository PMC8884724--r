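# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the RNG seeded at `seed` and restores the caller's RNG
#' state afterwards, so generators are deterministic without clobbering the
#' session's random stream.
#'
#' @param seed integer seed (kept below 2^31).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  .assert(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
          "seed must be a single finite number")
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  expr
}

#' Beta-binomial random draws
#'
#' Draws counts from a beta-binomial with mean fraction `prob` and intra-class
#' correlation `rho` (the usual overdispersion parameterisation:
#' shape1 = prob*(1-rho)/rho, shape2 = (1-prob)*(1-rho)/rho). `rho = 0`
#' recovers the plain binomial, which is what calibration tests rely on.
#'
#' @param n number of draws.
#' @param size vector of trial counts (recycled).
#' @param prob success fraction in \[0,1\].
#' @param rho overdispersion in \[0,1).
#' @return integer vector of counts.
#' @export
rbetabinom <- function(n, size, prob, rho = 0) {
  .assert(all(prob >= 0 & prob <= 1), "prob must lie in [0,1]")
  .assert(rho >= 0 && rho < 1, "rho must lie in [0,1)")
  if (rho == 0 || all(prob %in% c(0, 1))) return(stats::rbinom(n, size, prob))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  p <- stats::rbeta(n, a, b)
  # degenerate shapes (prob exactly 0 or 1) produce NaN; those sites are fixed
  p[prob == 0] <- 0
  p[prob == 1] <- 1
  stats::rbinom(n, size, p)
}

# md5 of a canonical serialization of a config list, for output provenance
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}
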