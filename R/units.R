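#' Unit conversions
#'
#' The package works in SI units internally (m, s, Pa, m^3/s). Imaging and
#' clinical inputs arrive in mm and mmHg; these helpers convert explicitly at
#' the I/O boundary (1 mmHg = 133.322 Pa).
#'
#' @param x numeric vector.
#' @return converted numeric vector.
#' @export
#' @examples
#' mmhg_to_pa(100)   # 13332.2 Pa
mmhg_to_pa <- function(x) x * 133.322

#' @rdname mmhg_to_pa
#' @export
pa_to_mmhg <- function(x) x / 133.322

# row-wise euclidean norm of an n x 3 matrix
.row_norm <- function(m) sqrt(rowSums(m * m))

# normalize rows; zero rows left untouched
.row_unit <- function(m) {
  n <- .row_norm(m)
  n[n == 0] <- 1
  m / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Run code with a private RNG stream: the global .Random.seed is saved and
# restored, so generators never leak state (seeds are arguments, not globals).
.with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
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

.assert_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("`%s` must be positive and finite", name), call. = FALSE)
  invisible(x)
}
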