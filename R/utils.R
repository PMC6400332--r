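# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never disturb the
# session RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministically derive a stage seed from a master seed; keeps results
# reproducible from one user-facing seed while decorrelating stages.
# Always in [1, 2^31 - 2].
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(master) %% 1000003L) * 2011L + h * 7919L) %% 2147483646L + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_binary <- function(x) all(x %in% c(0, 1))

stop_suvseg <- function(..., class) {
  stop(structure(class = c(class, "suvseg_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
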