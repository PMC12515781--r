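# Internal helpers shared across modules.

logit <- function(p) log(p / (1 - p))

#' @noRd
.hashString <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Derive a per-subject RNG seed from a global seed and an id, so adding or
# removing one subject never perturbs the traces of the others.
childSeed <- function(seed, id) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + .hashString(id)) %%
               2147483647)
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Clock hour-of-day (fractional) for POSIXct stored in UTC.
hourOfDay <- function(time) (as.numeric(time) %% 86400) / 3600

isDaytime <- function(time) hourOfDay(time) >= 6

stopWithClass <- function(class, message, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = message, call = sys.call(-1), ...)))
}
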