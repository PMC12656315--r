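#' Mean diameter of each sieve fraction
#'
#' For a descending aperture stack the i-th fraction is bounded by the
#' aperture above and below; its representative diameter is the
#' arithmetic mean of those bounds. The coarsest fraction is bounded
#' above by `assumed_max_diameter`, the pan below by zero.
#'
#' @param s `sieve_fractions` object.
#' @return numeric vector (mm), one value per fraction including the pan.
#' @export
fraction_mean_diameters <- function(s) {
  stopifnot(inherits(s, "sieve_fractions"))
  upper <- c(s$assumed_max_diameter, s$apertures)
  lower <- c(s$apertures, 0)
  (upper + lower) / 2
}

#' Mass fraction of water-stable aggregates larger than 0.25 mm
#'
#' R0.25 = 1 - M(x < 0.25 mm) / M_T. Requires 0.25 mm to be one of the
#' sieve apertures so "finer than 0.25 mm" is a clean cut.
#'
#' @param s `sieve_fractions`.
#' @return mass fraction in \[0, 1\].
#' @export
r025 <- function(s) {
  stopifnot(inherits(s, "sieve_fractions"))
  i <- which(abs(s$apertures - 0.25) < 1e-12)
  if (length(i) != 1) {
    stop("0.25 mm is not an aperture of this stack; re-bin the fractions")
  }
  # fractions finer than 0.25 mm are those below aperture index i
  fine <- sum(s$masses[(i + 1):length(s$masses)])
  1 - fine / sum(s$masses)
}

#' Mean weight diameter (mm)
#'
#' Sum over fractions of mean diameter times mass fraction. Weights are
#' mass fractions (masses normalised to sum one) so MWD carries mm.
#'
#' @param s `sieve_fractions`.
#' @return MWD in mm.
#' @export
mwd <- function(s) {
  stopifnot(inherits(s, "sieve_fractions"))
  w <- s$masses / sum(s$masses)
  sum(fraction_mean_diameters(s) * w)
}

#' Geometric mean diameter (mm)
#'
#' exp of the mass-weighted mean log fraction diameter; zero-mass
#' fractions contribute nothing.
#'
#' @param s `sieve_fractions`.
#' @return GMD in mm.
#' @export
gmd <- function(s) {
  stopifnot(inherits(s, "sieve_fractions"))
  d <- fraction_mean_diameters(s)
  m <- s$masses
  keep <- m > 0
  exp(sum(m[keep] * log(d[keep])) / sum(m))
}

#' Fractal dimension of the aggregate size distribution
#'
#' Fits the cumulative mass-size power law
#' M(r < R_i) / M_T = (R_i / Rmax)^(3 - D) by ordinary least squares on
#' natural-log axes, where R_i is the mean diameter of fraction i and
#' Rmax the mean diameter of the coarsest fraction. The cumulative mass
#' at fraction i includes fraction i itself, so the coarsest point is 1
#' by construction and is excluded from the fit; zero cumulative masses
#' are dropped with a warning. D = 3 - slope.
#'
#' @param s `sieve_fractions`.
#' @param force_origin fit without intercept on the log-log axes.
#' @return list with `D`, `slope`, `intercept`, `r_squared`,
#'   `points_used`.
#' @export
fractal_dimension <- function(s, force_origin = FALSE) {
  stopifnot(inherits(s, "sieve_fractions"))
  d <- fraction_mean_diameters(s)
  m <- s$masses / sum(s$masses)
  rmax <- d[1]
  # cumulative mass fraction of aggregates with mean diameter <= d[i]
  cum <- rev(cumsum(rev(m)))
  x <- log(d / rmax)[-1]
  y <- log(cum)[-1]
  drop <- !is.finite(y)
  if (any(drop)) {
    warning(sum(drop), " zero cumulative mass point(s) dropped from fit")
    x <- x[!drop]; y <- y[!drop]
  }
  if (length(x) < 2) stop("fewer than 2 usable points for the power-law fit")
  if (force_origin) {
    slope <- sum(x * y) / sum(x * x)
    intercept <- 0
    fitted <- slope * x
  } else {
    fit <- lm(y ~ x)
    slope <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
    fitted <- fitted(fit)
  }
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(D = 3 - slope, slope = slope, intercept = intercept,
       r_squared = r2, points_used = length(x))
}

#' All aggregate stability indices for one sample
#'
#' Computes R0.25, MWD, GMD, fractal dimension D and the three size-grade
#' mass fractions: large aggregates (> 2 mm), small aggregates
#' (0.25-2 mm) and microaggregates (< 0.25 mm).
#'
#' @param s `sieve_fractions`.
#' @param force_origin passed to [fractal_dimension()].
#' @return one-row data.frame with columns sample_id, R0.25, MWD, GMD, D,
#'   lma, sma, mia, fit_r2.
#' @export
aggregate_indices <- function(s, force_origin = FALSE) {
  stopifnot(inherits(s, "sieve_fractions"))
  total <- sum(s$masses)
  i2 <- which(abs(s$apertures - 2) < 1e-12)
  i025 <- which(abs(s$apertures - 0.25) < 1e-12)
  if (length(i2) != 1 || length(i025) != 1) {
    stop("size grades need both 2 mm and 0.25 mm apertures in the stack")
  }
  lma <- sum(s$masses[seq_len(i2)]) / total
  mia <- sum(s$masses[(i025 + 1):length(s$masses)]) / total
  sma <- 1 - lma - mia
  fd <- fractal_dimension(s, force_origin = force_origin)
  data.frame(sample_id = s$sample_id, R0.25 = r025(s), MWD = mwd(s),
             GMD = gmd(s), D = fd$D, lma = lma, sma = sma, mia = mia,
             fit_r2 = fd$r_squared, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Aggregate indices for a list of samples
#' @param sets named list of `sieve_fractions` (e.g. from
#'   [read_sieve_csv()]).
#' @param force_origin passed to [fractal_dimension()].
#' @return data.frame, one row per sample.
#' @export
aggregate_indices_table <- function(sets, force_origin = FALSE) {
  out <- do.call(rbind, lapply(sets, aggregate_indices,
                               force_origin = force_origin))
  rownames(out) <- NULL
  out
}
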