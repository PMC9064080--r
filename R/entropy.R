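#' Sample entropy parameters
#'
#' @param m Template length (number of consecutive points compared);
#'   default 3.
#' @param r Tolerance as a fraction of the series standard deviation;
#'   default 0.2. The actual tolerance radius is `r*sd(x)` where `sd`
#'   is the population standard deviation (divisor N) of the analyzed
#'   series.
#' @return An object of class `sampen_params`.
#' @export
sampen_params <- function(m = 3L, r = 0.2) {
  m <- as.integer(m)
  if (m < 1L) stop("m must be a positive integer", call. = FALSE)
  if (!is.numeric(r) || r <= 0) stop("r must be > 0", call. = FALSE)
  structure(list(m = m, r = as.numeric(r)), class = "sampen_params")
}

.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

.sampen_from_counts <- function(a, b, n, params) {
  if (b == 0) {
    stop("sample entropy undefined: no template matches at length m",
         call. = FALSE)
  }
  if (a == 0) {
    warning("no template matches at length m+1; returning +Inf sentinel",
            call. = FALSE)
    value <- Inf
  } else {
    value <- log(b / a)  # == -log(A/B); yields +0, not -0, when A == B
  }
  structure(
    list(value = value, a_count = a, b_count = b, n = n, params = params),
    class = "sampen_result"
  )
}

#' @export
print.sampen_result <- function(x, ...) {
  cat(sprintf("SampEn(m=%d, r=%g, N=%d) = %.6g  [A=%d, B=%d]\n",
              x$params$m, x$params$r, x$n, x$value,
              as.integer(x$a_count), as.integer(x$b_count)))
  invisible(x)
}

#' Sample entropy of a time series
#'
#' SampEn is the negative natural logarithm of the conditional
#' probability that two sequences similar for `m` points remain similar
#' at `m + 1` points, excluding self-matches:
#' `SampEn = -log(A / B)`, where `B` counts template pairs within the
#' tolerance radius at length `m` and `A` those still within it at
#' length `m + 1`. Similarity is measured in the Chebyshev (max-norm)
#' distance with an inclusive comparison (`<= radius`), and both counts
#' run over the same `N - m` templates so that every length-`m` template
#' has a length-`m + 1` extension. A perfectly repeatable series (e.g. a
#' constant or strictly periodic signal) gives A = B and SampEn = 0.
#'
#' The tolerance radius is `r*sd(x)` with the population standard
#' deviation of `x` itself. If no pair matches at length `m + 1` the
#' value is the `+Inf` sentinel with a warning; downstream statistics
#' treat it as missing. If no pair matches even at length `m` the
#' entropy is undefined and an error is raised.
#'
#' @param x Numeric series, length > m + 1.
#' @param params A [sampen_params()].
#' @return A `sampen_result` with `value` (nats), the integer match
#'   counts `a_count` and `b_count`, `n` and `params`.
#' @export
sample_entropy <- function(x, params = sampen_params()) {
  stopifnot(inherits(params, "sampen_params"))
  x <- as.numeric(x)
  n <- length(x)
  if (n <= params$m + 1L) {
    stop(sprintf("series length %d must exceed m + 1 = %d",
                 n, params$m + 1L), call. = FALSE)
  }
  radius <- params$r * .pop_sd(x)
  cnt <- sampen_counts_cpp(x, params$m, radius)
  .sampen_from_counts(cnt$a, cnt$b, n, params)
}

#' Brute-force sample entropy oracle
#'
#' Verification twin of [sample_entropy()]: a literal double loop over
#' all template pairs, written independently of the optimized counting
#' path, producing exact integer A and B counts. Quadratic in N; refused
#' for N > 5000.
#'
#' @inheritParams sample_entropy
#' @return A `sampen_result`.
#' @export
sample_entropy_oracle <- function(x, params = sampen_params()) {
  stopifnot(inherits(params, "sampen_params"))
  x <- as.numeric(x)
  n <- length(x)
  if (n > 5000L) stop("oracle is quadratic; N must be <= 5000", call. = FALSE)
  if (n <= params$m + 1L) {
    stop(sprintf("series length %d must exceed m + 1 = %d",
                 n, params$m + 1L), call. = FALSE)
  }
  m <- params$m
  radius <- params$r * .pop_sd(x)
  nt <- n - m
  a <- 0L
  b <- 0L
  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      dm <- max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)]))
      if (dm <= radius) {
        b <- b + 1L
        if (max(dm, abs(x[i + m] - x[j + m])) <= radius) a <- a + 1L
      }
    }
  }
  .sampen_from_counts(a, b, n, params)
}

#' Sample entropy over a grid of m and r values
#'
#' Sensitivity analysis of the SampEn parameter choice: evaluates every
#' combination of the supplied template lengths and tolerance fractions
#' on one series. For fixed m, SampEn is non-increasing in r (a larger
#' radius admits every match a smaller one does).
#'
#' @param x Numeric series.
#' @param m_values Integer vector of template lengths.
#' @param r_values Numeric vector of tolerance fractions.
#' @return A data frame with columns `m`, `r`, `sampen`, `a_count`,
#'   `b_count`, `n`.
#' @export
sampen_sensitivity <- function(x, m_values = c(2L, 3L),
                               r_values = c(0.15, 0.2, 0.25)) {
  grid <- expand.grid(m = as.integer(m_values), r = as.numeric(r_values))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    s <- sample_entropy(x, sampen_params(grid$m[i], grid$r[i]))
    data.frame(m = grid$m[i], r = grid$r[i], sampen = s$value,
               a_count = s$a_count, b_count = s$b_count, n = s$n)
  })
  do.call(rbind, res)
}
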