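#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor rnorm runif rbinom pt pnorm qnorm qgamma sd
#'   ks.test mvfft setNames complete.cases
#' @importFrom utils read.csv write.csv packageVersion
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}

assert_count <- function(x, name, min = 0L) {
  if (!is_count(x, min)) stopf("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

assert_seed <- function(seed) {
  if (!is_count(seed, min = 0L)) stopf("`seed` must be a single non-negative integer")
  as.integer(seed)
}

# Pre-draw one child seed per iteration from a master seed so that
# iterations are order-independent and individually reproducible.
derive_seeds <- function(seed, n) {
  if (n == 0L) return(integer(0))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(assert_seed(seed))
  sample.int(.Machine$integer.max, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# fixed 6-significant-digit formatting for byte-stable exports
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    formatC(v, digits = 6L, format = "g")
  }, character(1))
  out
}

write_lines_atomic <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n")
  invisible(path)
}
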