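#' Evaluate code with a local random seed
#'
#' Sets the RNG seed for the duration of \code{code} and restores the
#' caller's RNG state afterwards, so generators never leak global RNG
#' state.
#'
#' @param seed single integer seed
#' @param code expression to evaluate
#' @return The value of \code{code}.
#' @keywords internal
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# 1-D Gaussian smoothing of each row (along = "position") or column of a
# matrix, with replicate padding at the borders. sigma = 0 is the identity.
gaussianSmooth1D <- function(mat, sigma, along = c("position", "time")) {
  along <- match.arg(along)
  if (sigma <= 0) return(mat)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  if (along == "time") return(t(gaussianSmooth1D(t(mat), sigma, "position")))
  n <- ncol(mat)
  idx <- pmin(pmax(seq_len(n + 2L * half) - half, 1L), n)
  padded <- mat[, idx, drop = FALSE]
  out <- matrix(0, nrow(mat), n)
  for (j in seq_along(k))
    out <- out + k[j] * padded[, j:(j + n - 1L), drop = FALSE]
  out
}

# Shift a matrix by (dr, dc), padding with `fill`.
shiftMatrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr); cs <- seq_len(nc)
  rdst <- rs + dr; cdst <- cs + dc
  keepR <- rdst >= 1 & rdst <= nr
  keepC <- cdst >= 1 & cdst <= nc
  out[rdst[keepR], cdst[keepC]] <- m[rs[keepR], cs[keepC]]
  out
}

# Exact integral of the empirical complementary cumulative distribution of
# a non-negative sample over [0, max(x)]; equals the sample mean.
ccdIntegral <- function(x) {
  stopifnot(all(x >= 0))
  xs <- sort(x)
  n <- length(xs)
  grid <- c(0, xs)
  surv <- c(1, (n - seq_len(n)) / n)  # P(X >= r) just above each grid point
  sum(diff(grid) * surv[-length(surv)])
}

#' Thermal energy conversion helpers
#'
#' Convert between pN um and kBT. At 25 degrees C, 1 kBT = 4.114 pN nm =
#' 4.114e-3 pN um.
#'
#' @param x value to convert
#' @param kBT thermal energy in pN nm
#' @return Converted value.
#' @examples
#' kbtFromPnUm(pnUmFromKbt(3)) == 3
#' @export
kbtFromPnUm <- function(x, kBT = 4.114) x / (kBT * 1e-3)

#' @rdname kbtFromPnUm
#' @export
pnUmFromKbt <- function(x, kBT = 4.114) x * (kBT * 1e-3)
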