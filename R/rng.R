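#' Named, independently reproducible random substreams
#'
#' All stochastic draws in a simulated session flow from one session-level
#' integer seed via named substreams (`"sequencer"`, `"baseline"`, `"agent"`,
#' `"laser"`, ...), so that each component of the simulation is reproducible
#' on its own: editing how many draws one component makes never perturbs the
#' others.
#'
#' A stream is an environment holding a private `.Random.seed`; evaluating
#' code "inside" the stream swaps the private state in, runs the code, and
#' swaps it back out.
#'
#' @param seed integer session seed.
#' @param name character substream name.
#' @return an object of class `rng_stream`.
#' @export
rng_stream <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  e <- new.env(parent = emptyenv())
  e$name <- name
  old <- get_global_seed()
  set.seed(substream_seed(seed, name))
  e$state <- .Random.seed
  restore_global_seed(old)
  class(e) <- "rng_stream"
  e
}

#' Derive a deterministic 31-bit sub-seed from a seed and a stream name
#'
#' @param seed integer seed.
#' @param name character stream name.
#' @return an integer in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 48271 + h) %% 2147483647)
}

get_global_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_global_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Evaluate code using a stream's private RNG state
#'
#' @param stream an [rng_stream()].
#' @param code expression making random draws.
#' @return the value of `code`.
#' @export
with_stream <- function(stream, code) {
  stopifnot(inherits(stream, "rng_stream"))
  old <- get_global_seed()
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    restore_global_seed(old)
  })
  code
}

#' @export
print.rng_stream <- function(x, ...) {
  cat("<rng_stream:", x$name, ">\n")
  invisible(x)
}
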