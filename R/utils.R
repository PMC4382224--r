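#' @importFrom stats rnorm runif var sd cor t.test
#' @importFrom utils head tail
NULL

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers do not disturb
#' the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Derive a deterministic sub-stream seed
#'
#' Hashes a root seed together with a stream name and optional indices into
#' a new 31-bit seed, so that independent parts of a simulation (trial
#' order, background noise, each oscillatory source, each participant) draw
#' from reproducible, non-overlapping streams.
#'
#' @param seed integer root seed.
#' @param ... character or integer stream identifiers.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
sub_seed <- function(seed, ...) {
  m <- 2147483629 # largest prime below 2^31
  h <- as.numeric(seed) %% m
  for (part in list(...)) {
    if (is.character(part)) keys <- utf8ToInt(paste(part, collapse = "/"))
    else keys <- as.numeric(part)
    for (k in keys) h <- (h * 1315423911 + k + 1) %% m
  }
  as.integer(h)
}

# package-wide logger; silent unless options(mibci.verbose = TRUE)
bci_log <- function(...) {
  if (isTRUE(getOption("mibci.verbose", FALSE)))
    message("[mibci] ", sprintf(...))
  invisible(NULL)
}

stop_mibci <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "mibci_error", "error", "condition")))
}
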