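# internal helpers shared across modules

# deterministic child seed: offsets keep sub-streams apart while staying
# inside the 32-bit integer range expected by set.seed()
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name, lo = 0, hi = 1, closed_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x >= lo &&
    (if (closed_hi) x <= hi else x < hi)
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single number in [%g, %g%s", name, lo, hi,
      if (closed_hi) "]" else ")"
    ))
  }
  invisible(x)
}

# mean log2 difference between two groups on the analysis scale
log2_fc <- function(x_case, x_ctrl) mean(x_case) - mean(x_ctrl)
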