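#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed` and restores the
#' caller's RNG state afterwards, so that no function in the package
#' leaves hidden global state behind.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derived seeds for loop iterations; kept strictly below 2^31
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 8191) %% 2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-column (feature is a row here: operates on matrices laid out
# features x samples) z-standardization with NA tolerance
row_standardize <- function(m, warn_constant = TRUE) {
  mu <- rowMeans(m, na.rm = TRUE)
  s <- apply(m, 1L, sd, na.rm = TRUE)
  const <- !is.na(s) & s < .Machine$double.eps * 1e3
  if (any(const) && warn_constant)
    warning(sum(const), " constant feature(s); left unstandardized (z undefined)")
  s[const | is.na(s)] <- 1
  out <- (m - mu) / s
  out[const, ] <- 0
  out
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
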