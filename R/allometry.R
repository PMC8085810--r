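#' Log-log regression slope through the origin
#'
#' Slope of the no-intercept least-squares regression of \code{log(y)} on
#' \code{log(x)} (natural logarithms): \code{sum(ln x * ln y) / sum((ln
#' x)^2)}. Used for the orthogonal growth-gradient estimates that feed the
#' isotropy factor.
#'
#' @param x,y positive vectors of equal length (>= 2).
#' @return the slope.
#' @examples
#' loglog_origin_slope(c(exp(1), exp(2)), c(exp(2), exp(3)))  # 1.6
#' @export
loglog_origin_slope <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must have equal length >= 2")
  if (any(is.na(x) | is.na(y) | x <= 0 | y <= 0))
    stop("all values must be positive")
  lx <- log(x); ly <- log(y)
  sum(lx * ly) / sum(lx^2)
}

#' Isotropy inflation factor for vertical measures
#'
#' Ratio of the mean horizontal to the mean vertical log-log growth gradient
#' against body size. The study value, from slopes 0.7366 (horizontal) and
#' 0.5896 (vertical), is 1.249; it pre-multiplies log height values before
#' correlation analysis so a unit change means the same in every direction
#' of the log-morphometric space.
#'
#' @param horizontal,vertical slopes of log-log through-origin regressions
#'   of horizontal/vertical measures on body size.
#' @return mean(horizontal)/mean(vertical), reported to 3 decimals.
#' @examples
#' isotropy_factor(0.7366, 0.5896)  # 1.249
#' @export
isotropy_factor <- function(horizontal, vertical) {
  if (length(horizontal) < 1L || length(vertical) < 1L)
    stop("need at least one slope on each axis")
  mv <- mean(vertical)
  if (is.na(mv) || mv <= 0) stop("mean vertical slope must be positive")
  round(mean(horizontal) / mv, 3)
}

#' Power-law fit by ordinary least squares on the log-log scale
#'
#' Fits \code{y = a * x^b} as the spreadsheet "power trendline" does:
#' ordinary least squares of \code{ln(y)} on \code{ln(x)} with an intercept,
#' then \code{a = exp(intercept)}, \code{b = slope}. R-squared is that of
#' the log-log fit.
#'
#' @param x,y positive vectors, n >= 3.
#' @return object of class \code{"power_fit"}: list with \code{a}, \code{b},
#'   \code{r_squared}, \code{se_b}, \code{n} and the underlying \code{lm}.
#' @examples
#' f <- power_fit(1:10, 2 * (1:10))
#' c(f$a, f$b)  # 2, 1
#' @export
power_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3")
  if (any(is.na(x) | is.na(y) | x <= 0 | y <= 0))
    stop("all values must be positive")
  fit <- stats::lm(log(y) ~ log(x))
  cf <- stats::coef(fit)
  # summary.lm warns on exact fits; an exact power law is a legitimate input
  sm <- suppressWarnings(summary(fit))
  structure(list(a = unname(exp(cf[1])), b = unname(cf[2]),
                 r_squared = sm$r.squared,
                 se_b = sm$coefficients[2, 2],
                 n = length(x), lm = fit),
            class = "power_fit")
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: y = %.4g * x^%.4g  (log-log OLS, n = %d, R2 = %.3f)\n",
              x$a, x$b, x$n, x$r_squared))
  invisible(x)
}

#' Principal component analysis of the correlation matrix of log measures
#'
#' Multiplies the designated vertical log-columns by the isotropy inflation
#' factor, forms the Pearson correlation matrix and eigendecomposes it
#' (equivalently, \code{prcomp} on the standardised columns). Components are
#' ordered by decreasing eigenvalue; each loading column is flipped so that
#' its largest-magnitude entry is negative (an arbitrary but fixed sign
#' convention). Because correlations are invariant to positive linear
#' rescaling of any column, the inflation factor cannot change the result —
#' it is applied (and recorded) for fidelity to the published procedure.
#'
#' @param logX matrix or data.frame of log-scale measures (rows =
#'   species/specimens, columns = variables); \code{nrow >= ncol}.
#' @param vertical character vector of column names to pre-multiply.
#' @param inflation the isotropy factor (default 1.249).
#' @return object of class \code{"pca_correlation"}: \code{loadings}
#'   (variables x components), \code{sdev} (component standard deviations,
#'   i.e. square roots of eigenvalues), \code{variables}, \code{inflation}.
#' @examples
#' X <- log(data.frame(DSL = c(100, 240, 340, 190), MDL = c(37, 147, 130, 23),
#'                     HDS = c(26, 110, 50, 14)))
#' correlation_pca(X, vertical = "HDS")
#' @export
correlation_pca <- function(logX, vertical = character(), inflation = 1.249) {
  X <- as.matrix(logX)
  if (!is.numeric(X)) stop("logX must be numeric")
  if (anyNA(X) || any(!is.finite(X))) stop("all values must be finite")
  if (nrow(X) < ncol(X)) stop("need at least as many rows as variables")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("constant column(s): correlation undefined")
  if (length(vertical)) {
    if (!all(vertical %in% colnames(X)))
      stop("vertical names not in logX: ",
           paste(setdiff(vertical, colnames(X)), collapse = ", "))
    X[, vertical] <- inflation * X[, vertical]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  L <- pc$rotation
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] > 0) L[, j] <- -L[, j]
  }
  structure(list(loadings = L, sdev = pc$sdev,
                 variables = colnames(X), inflation = inflation),
            class = "pca_correlation")
}

#' @export
print.pca_correlation <- function(x, ...) {
  cat("Correlation-matrix PCA of log measures",
      sprintf("(vertical inflation %.3f)\n", x$inflation))
  print(round(x$loadings, 4))
  cat("Component standard deviations:",
      paste(signif(x$sdev, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Cephalisation classification from gnathosomal-width residuals
#'
#' Twice the width of the distal cheliceral segment estimates the breadth of
#' the "feeding head". Regressing \code{2*WDS} on the idiosomal index (raw
#' scale, ordinary least squares with intercept) and splitting the residual
#' range into equal thirds classifies each species as micro-cephalic (bottom
#' third, closed lower interval), mega-cephalic (top third) or meso-cephalic
#' (middle; also every species when all residuals are equal).
#'
#' @param records data.frame with columns \code{IL} and \code{WDS} (and
#'   optionally \code{species_id}).
#' @return data.frame with \code{species_id}, \code{residual} and
#'   \code{cephalic_status} in \code{c("micro", "meso", "mega")}.
#' @export
cephalisation <- function(records) {
  stopifnot(is.data.frame(records), all(c("IL", "WDS") %in% names(records)))
  if (anyNA(records$IL) || anyNA(records$WDS))
    stop("WDS and IL must be present for all records")
  if (nrow(records) < 3L) stop("need at least 3 records")
  y <- 2 * records$WDS
  fit <- stats::lm(y ~ IL, data = records)
  res <- stats::resid(fit)
  rng <- range(res)
  if (diff(rng) <= 1e-10 * max(1, max(abs(y)))) {
    status <- rep("meso", length(res))
  } else {
    cut1 <- rng[1] + diff(rng) / 3
    cut2 <- rng[1] + 2 * diff(rng) / 3
    status <- ifelse(res <= cut1, "micro", ifelse(res > cut2, "mega", "meso"))
  }
  data.frame(species_id = if ("species_id" %in% names(records))
    records$species_id else seq_along(res),
    residual = unname(res), cephalic_status = status,
    stringsAsFactors = FALSE)
}
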