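# Geometric mean of strictly positive values.
geo_mean <- function(x) {
  stopifnot(all(is.finite(x)), all(x > 0))
  exp(mean(log(x)))
}

# Sample SD with the n-1 denominator, defined as 0 for n = 1.
sd1 <- function(x) {
  if (length(x) < 2L) return(0)
  stats::sd(x)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so simulators never leak global state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Significance code used in screening tables: ns / * / ** at 0.05 / 0.01.
sig_code <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.01) "**" else if (pi < 0.05) "*" else "ns"
  }, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_rgstab <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "rgstab_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}
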