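# Circular statistics for displacement bearings. Bearings use the geographic
# convention: degrees clockwise from north, in [0, 360).

#' Circular summary of bearings
#'
#' Computes the circular mean bearing, resultant length, and circular standard
#' deviation (Mardia convention, `sqrt(-2 log R)` expressed in degrees). When
#' the resultant length falls below `eps` (e.g., antipodal bearings cancel),
#' the mean bearing is undefined and returned as `NA`.
#'
#' @param bearings_deg Numeric vector of bearings in degrees, each in
#'   `[0, 360)`.
#' @param weights Optional nonnegative weights (e.g., displacement distances);
#'   unweighted by default.
#' @param eps Resultant-length threshold below which the mean is undefined.
#' @return A list of class `circular_summary` with elements
#'   `mean_bearing_deg`, `circ_sd_deg`, `resultant_length`, `n`.
#' @examples
#' circular_summary(c(350, 10))   # mean 0, R = cos(10 deg)
#' circular_summary(c(0, 180))    # resultant ~ 0, mean undefined
#' @export
circular_summary <- function(bearings_deg, weights = NULL, eps = 1e-8) {
  n <- length(bearings_deg)
  if (n == 0L) {
    return(structure(list(mean_bearing_deg = NA_real_, circ_sd_deg = NA_real_,
                          resultant_length = NA_real_, n = 0L),
                     class = "circular_summary"))
  }
  if (any(bearings_deg < 0 | bearings_deg >= 360))
    stop("circular_summary: bearings must be in [0, 360)", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0))
    stop("circular_summary: weights must be nonnegative and match bearings", call. = FALSE)
  th <- bearings_deg * pi / 180
  w <- weights / sum(weights)
  C <- sum(w * cos(th)); S <- sum(w * sin(th))
  R <- sqrt(C^2 + S^2)
  mean_deg <- if (R < eps) NA_real_ else (atan2(S, C) * 180 / pi + 360) %% 360
  sd_deg <- if (R < eps) Inf else sqrt(-2 * log(min(R, 1))) * 180 / pi
  structure(list(mean_bearing_deg = mean_deg, circ_sd_deg = sd_deg,
                 resultant_length = min(R, 1), n = n),
            class = "circular_summary")
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf("<circular_summary: n=%d, mean=%.1f deg, circ_sd=%.1f deg, R=%.3f>\n",
              x$n, x$mean_bearing_deg, x$circ_sd_deg, x$resultant_length))
  invisible(x)
}

#' Draw von Mises distributed bearings
#'
#' Best–Fisher (1979) rejection sampler, used by the synthetic scenario
#' generator to plant concentrated displacement directions.
#'
#' @param n Number of draws.
#' @param mu_deg Mean direction in degrees.
#' @param kappa Concentration parameter (`kappa = 0` gives the uniform
#'   circular distribution).
#' @return Bearings in degrees in `[0, 360)`.
#' @export
rvonmises_deg <- function(n, mu_deg, kappa) {
  if (kappa < 0) stop("rvonmises_deg: kappa must be >= 0", call. = FALSE)
  if (kappa == 0) return(stats::runif(n, 0, 360))
  mu <- mu_deg * pi / 180
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      th <- mu + sign(u3 - 0.5) * acos(f)
      out[i] <- (th * 180 / pi) %% 360
      i <- i + 1L
    }
  }
  out
}
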