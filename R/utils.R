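# Shared helpers: condition classes, angle arithmetic, seeded evaluation.

stop_input <- function(fmt, ...) {
  stop(structure(
    class = c("ellipstack_input_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

stop_numeric <- function(fmt, ...) {
  stop(structure(
    class = c("ellipstack_numeric_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_numeric_matrix <- function(x, ncol, what) {
  if (!is.matrix(x) || !is.numeric(x) || ncol(x) != ncol || !all(is.finite(x)))
    stop_input("%s must be a finite numeric matrix with %d columns", what, ncol)
  invisible(x)
}

#' @keywords internal
rot2 <- function(phi) {
  matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2L, 2L)
}

# Wrap into (-pi, pi].
wrap_pi <- function(x) {
  w <- x - 2 * pi * floor((x + pi) / (2 * pi))
  w[w <= -pi] <- pi
  w
}

# Wrap into (-pi/2, pi/2] (orientation angles; period pi).
wrap_half_pi <- function(x) {
  w <- x - pi * floor((x + pi / 2) / pi)
  w[w <= -pi / 2] <- pi / 2
  w
}

# Cumulative unwrap: successive differences folded to the representative of
# minimal magnitude modulo `period`. Orientation angles use period pi (adding
# pi to phi leaves the ellipse point set unchanged).
unwrap_angles <- function(x, period = pi) {
  if (length(x) < 2L) return(x)
  d <- diff(x)
  d <- d - period * round(d / period)
  cumsum(c(x[1L], d))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream. `seed = NULL` leaves the stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Centered moving average with the window clipped at the sequence ends.
moving_average <- function(x, window) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    idx <- max(1L, i - h):min(n, i + h)
    mean(x[idx])
  }, numeric(1))
}
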