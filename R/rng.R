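# Seed plumbing.  Every stochastic stage derives its own stream from one
# root seed by hashing "<stage>:<seed>" (FNV-1a 64-bit, reduced mod
# 2^31 - 1), so stages are independent and adding a stage never perturbs
# the draws of another.

derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer(.fnv64(paste0(stage, ":", format(seed, scientific = FALSE))) %%
               2147483646) + 1L
}

# Evaluate `code` under `seed`, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Short content hash of an R object
#'
#' Hashes the deparsed form of an object with a 64-bit FNV-1a hash.
#' Used to stamp output artifacts with the configuration that produced
#' them.
#'
#' @param x any R object
#' @return a 14-character hexadecimal string
#' @export
config_hash <- function(x) {
  txt <- paste(deparse(x, control = "all"), collapse = "\n")
  h <- .fnv64(txt)  # 53-bit value held exactly in a double
  paste0(sprintf("%07x", as.integer(h %/% 2^28)),
         sprintf("%07x", as.integer(h %% 2^28)))
}
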