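#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef fft kruskal.test lm median nls.control quantile
#'   residuals rmultinom rnorm runif sd setNames
#' @importFrom utils read.csv write.csv
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

# Periodic (wrap-around) 1-D Gaussian kernel of length n, unit sum.
# sigma <= 0 returns a unit impulse (identity under convolution).
gauss_kernel_periodic <- function(n, sigma) {
  if (sigma <= 0) return(c(1, rep(0, n - 1)))
  x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur of a 3-D array via FFT (periodic boundaries).
fft_blur3 <- function(a, sigma) {
  dm <- dim(a)
  K <- outer(
    outer(gauss_kernel_periodic(dm[1], sigma[1]), gauss_kernel_periodic(dm[2], sigma[2])),
    gauss_kernel_periodic(dm[3], sigma[3])
  )
  Re(fft(fft(a) * fft(K), inverse = TRUE)) / prod(dm)
}

# Gaussian smoothing followed by sinc (Fourier zero-padding) upsampling by
# integer factors `f` along each axis, fused into one FFT round trip.
# Requires even array dimensions so the spectrum can be split cleanly.
fft_smooth_upsample3 <- function(a, sigma, f) {
  dm <- dim(a)
  stopifnot(all(f >= 1), all(f == round(f)))
  K <- outer(
    outer(gauss_kernel_periodic(dm[1], sigma[1]), gauss_kernel_periodic(dm[2], sigma[2])),
    gauss_kernel_periodic(dm[3], sigma[3])
  )
  A <- fft(a) * fft(K)
  if (all(f == 1)) return(Re(fft(A, inverse = TRUE)) / prod(dm))
  dmo <- dm * f
  B <- array(0 + 0i, dmo)
  idx <- function(n, no) {
    h <- n %/% 2
    c(1:(h + 1), if (h + 2 <= n) (no - (n - h - 2)):no)
  }
  B[idx(dm[1], dmo[1]), idx(dm[2], dmo[2]), idx(dm[3], dmo[3])] <- A
  Re(fft(B, inverse = TRUE)) / prod(dm)
}

# Least-squares (Kasa) circle fit to boundary points.
fit_circle <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- qr.solve(A, b)
  cx <- sol[1]; cy <- sol[2]
  r <- sqrt(sol[3] + cx^2 + cy^2)
  list(cx = unname(cx), cy = unname(cy), r = unname(r))
}
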