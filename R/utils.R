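# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Run code with a temporary RNG seed
#'
#' Sets the RNG to `seed`, evaluates `code`, and restores the caller's RNG
#' state, so seeded operations never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_("`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible sub-seed for a named random substream
#'
#' Hashes a stream label into the master seed so each generator draws from
#' its own independent, reproducible stream; partial reruns of one
#' generator do not disturb the others.
#'
#' @param seed master integer seed.
#' @param stream character label of the substream.
#' @return an integer in `[0, 2^31)`.
#' @export
#' @examples
#' derive_seed(1, "gaze") != derive_seed(1, "eeg")
derive_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 1000003
  as.integer((as.numeric(seed) %% 65536) * 32749 + h) %% 2147483647L
}

# numeric formatting used by the writers so read->write round-trips exactly
fmt_num <- function(x) sprintf("%.17g", x)
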