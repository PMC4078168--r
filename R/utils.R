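#' Derive a labelled stream seed from a master seed
#'
#' All stochastic functions in the package take an integer `seed`. When one
#' master seed must drive several independent random streams (one per
#' treatment-year cell, per replicate, per trait), sub-seeds are derived
#' deterministically from the master seed and a text label, so that runs are
#' reproducible and streams do not collide.
#'
#' The derivation is a 31-bit polynomial hash: starting from the master seed,
#' each byte `b` of the UTF-8 label updates `h <- (h * 31 + b) mod (2^31 - 1)`.
#'
#' @param master Integer master seed.
#' @param label Character scalar naming the stream.
#' @return An integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(1L, "nri/control/2006")
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.character(label), length(label) == 1L)
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(master) %% m
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% m
  as.integer(h)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. seed = NULL runs on the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  code
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
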