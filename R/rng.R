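#' Derive a named RNG substream seed
#'
#' All randomness in the package flows from one integer seed. Each random
#' stage (walk generation, skip-gram initialisation, negative sampling,
#' network initialisation, fold assignment, ...) draws its own substream
#' seed so that changing one stage's consumption of random numbers cannot
#' perturb another stage.
#'
#' @param seed master integer seed.
#' @param name character tag of the substream.
#' @return an integer seed in `[0, 2^31 - 19)`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 2147483629
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is restored on exit.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}
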