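#' Transform a chelal velocity ratio for the feeding-habit model
#'
#' The velocity ratio is first symmetrised with the arcsine-square-root
#' transform (\code{asin(sqrt(VR))}, radians) and then logged, allowing
#' different tail behaviour at the extremes of the (0,1) domain:
#' \code{t = ln(asin(sqrt(VR)))}.
#'
#' @param VR velocity ratio(s), strictly inside (0, 1).
#' @return the transformed value(s); the supremum as VR approaches 1 is
#'   \code{log(pi/2)}.
#' @examples
#' transform_vr(0.25)  # log(pi/6)
#' @export
transform_vr <- function(VR) {
  if (any(is.na(VR) | VR <= 0 | VR >= 1))
    stop("VR must lie strictly inside (0, 1)")
  log(asin(sqrt(VR)))
}

#' Construct a feeding-habit logit model
#'
#' The model is a binomial regression with logit link of the binary outcome
#' "worm-like prey feeder" on the transformed velocity ratio:
#' \deqn{logit(p) = intercept + slope \cdot ln(asin(\sqrt{VR}))}
#' A species is called a micro-arthropod ("cutter") feeder when its
#' estimated probability falls below \code{threshold_p}, equivalently when
#' VR falls below \code{threshold_vr}; the two cuts are linked through
#' [threshold_from_p()].
#'
#' @param intercept,slope logit-scale coefficients.
#' @param threshold_p probability cut (default 0.475).
#' @param threshold_vr velocity-ratio cut (default 0.276).
#' @param provenance \code{"published"} or \code{"refit"}.
#' @param fit_report optional list of fit diagnostics (deviance etc.).
#' @return object of class \code{"feeding_model"}.
#' @seealso [published_feeding_model()], [fit_feeding_model()]
#' @export
feeding_model <- function(intercept, slope, threshold_p = 0.475,
                          threshold_vr = 0.276,
                          provenance = c("published", "refit"),
                          fit_report = NULL) {
  provenance <- match.arg(provenance)
  stopifnot(is.numeric(intercept), is.numeric(slope),
            threshold_p > 0, threshold_p < 1,
            threshold_vr > 0, threshold_vr < 1)
  structure(list(intercept = unname(intercept), slope = unname(slope),
                 threshold_p = threshold_p, threshold_vr = threshold_vr,
                 provenance = provenance, fit_report = fit_report),
            class = "feeding_model")
}

#' The published feeding-habit classifier
#'
#' Coefficients of the study's final velocity-ratio-only model (intercept
#' 1.426, slope 2.570 on the transformed VR) with its probability cut 0.475
#' and the equivalent velocity-ratio cut 0.276. This is the default model
#' for prediction because the exact training labels behind the refit are not
#' fully recoverable; refitting is available through [fit_feeding_model()].
#'
#' @return a \code{"feeding_model"} object.
#' @examples
#' predict(published_feeding_model(), VR = 0.199)  # p_worm 0.365
#' @export
published_feeding_model <- function() {
  feeding_model(intercept = 1.426, slope = 2.570, provenance = "published")
}

#' @export
print.feeding_model <- function(x, ...) {
  cat(sprintf(
    "Feeding-habit logit model (%s):\n  logit(p(worm-like)) = %.4g + %.4g * ln(asin(sqrt(VR)))\n",
    x$provenance, x$intercept, x$slope))
  cat(sprintf("  micro-arthropod call: p < %.3f  (VR < %.3f)\n",
              x$threshold_p, x$threshold_vr))
  if (!is.null(x$fit_report))
    cat(sprintf("  deviance %.4g on %d df (null %.4g); VR chisq(1) = %.4g, p = %.3g\n",
                x$fit_report$deviance, x$fit_report$df_residual,
                x$fit_report$null_deviance, x$fit_report$chisq,
                x$fit_report$p_value))
  invisible(x)
}

#' Predict feeding habit from velocity ratio
#'
#' @param object a \code{"feeding_model"}.
#' @param VR velocity ratio(s) in (0, 1).
#' @param ... unused.
#' @return data.frame with \code{VR}, the transformed value \code{t},
#'   \code{p_worm} and \code{habit_call} (\code{"microarthropod"} iff
#'   \code{VR < threshold_vr}, else \code{"worm_like"}).
#' @examples
#' predict(published_feeding_model(), VR = c(0.199, 0.458, 0.478))
#' @export
predict.feeding_model <- function(object, VR, ...) {
  t <- transform_vr(VR)
  p <- stats::plogis(object$intercept + object$slope * t)
  data.frame(VR = VR, t = t, p_worm = p,
             habit_call = ifelse(VR < object$threshold_vr,
                                 "microarthropod", "worm_like"),
             stringsAsFactors = FALSE)
}

#' Fit the feeding-habit logit model by maximum likelihood
#'
#' Binomial regression (logit link) of the worm-like-feeder indicator on the
#' transformed velocity ratio. Polyphagous and omnivorous species are scored
#' as potentially feeding on both prey classes: under the default
#' \code{"duplicate"} policy each such species contributes one worm-like and
#' one micro-arthropod observation; under \code{"fractional"} it contributes
#' both observations at weight 0.5 each.
#'
#' @param VR velocity ratios in (0, 1).
#' @param label per-species labels: \code{"worm_like"} (or 1),
#'   \code{"microarthropod"} (or 0), \code{"polyphagous"}, \code{"omnivore"}.
#' @param inclusion_policy \code{"duplicate"} (default) or
#'   \code{"fractional"}.
#' @param threshold_p probability cut for the returned model (default 0.475);
#'   the equivalent VR cut is derived with [threshold_from_p()].
#' @return a \code{"feeding_model"} with \code{provenance = "refit"} and a
#'   \code{fit_report} (deviance, null deviance, change-in-deviance
#'   chi-squared test on 1 df, coefficient standard errors, a
#'   perfect-separation flag, and the underlying \code{glm}).
#' @examples
#' set.seed(1)
#' vr <- runif(300, 0.1, 0.7)
#' y <- rbinom(300, 1, plogis(1.4 + 2.6 * transform_vr(vr)))
#' fit_feeding_model(vr, y)
#' @export
fit_feeding_model <- function(VR, label,
                              inclusion_policy = c("duplicate", "fractional"),
                              threshold_p = 0.475) {
  inclusion_policy <- match.arg(inclusion_policy)
  if (length(VR) != length(label)) stop("VR and label lengths differ")
  if (is.numeric(label)) {
    if (!all(label %in% c(0, 1))) stop("numeric labels must be 0/1")
    label <- ifelse(label == 1, "worm_like", "microarthropod")
  }
  ok_lab <- c("worm_like", "microarthropod", "polyphagous", "omnivore")
  if (!all(label %in% ok_lab))
    stop("labels must be one of: ", paste(ok_lab, collapse = ", "))

  both <- label %in% c("polyphagous", "omnivore")
  y <- c(ifelse(label[!both] == "worm_like", 1, 0), rep(1, sum(both)),
         rep(0, sum(both)))
  x <- c(VR[!both], VR[both], VR[both])
  w <- c(rep(1, sum(!both)),
         rep(if (inclusion_policy == "duplicate") 1 else 0.5, 2 * sum(both)))
  if (length(unique(y)) < 2L)
    stop("training data contain a single class after policy expansion")
  if (sum(y == 1) < 2L || sum(y == 0) < 2L)
    stop("need at least 2 observations per class after policy expansion")

  t <- transform_vr(x)
  dat <- data.frame(y = y, t = t, w = w)
  fit <- withCallingHandlers(
    stats::glm(y ~ t, family = stats::binomial("logit"), data = dat,
               weights = w,
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(wn) {
      # separation is re-reported below; fractional weights legitimately
      # produce non-integer successes
      if (grepl("fitted probabilities numerically 0 or 1|non-integer #successes",
                conditionMessage(wn)))
        invokeRestart("muffleWarning")
    })
  sep <- any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
  if (sep)
    warning("possible perfect separation: coefficients unreliable")
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  chisq <- fit$null.deviance - fit$deviance
  report <- list(deviance = fit$deviance,
                 null_deviance = fit$null.deviance,
                 df_residual = fit$df.residual,
                 chisq = chisq,
                 p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
                 se = unname(se),
                 separation = sep,
                 n_obs = nrow(dat),
                 glm = fit)
  m <- feeding_model(cf[1], cf[2], threshold_p = threshold_p,
                     threshold_vr = 0.5, provenance = "refit",
                     fit_report = report)
  m$threshold_vr <- tryCatch(threshold_from_p(m, threshold_p),
                             error = function(e) {
                               warning("probability cut not invertible for ",
                                       "these coefficients; threshold_vr NA")
                               NA_real_
                             })
  m
}

#' Velocity-ratio cut equivalent to a probability cut
#'
#' Inverts the model through the transform chain:
#' \code{VR* = sin(exp((logit(p*) - intercept)/slope))^2}.
#'
#' @param model a \code{"feeding_model"} with non-zero slope.
#' @param p probability cut(s) in (0, 1).
#' @return the equivalent velocity-ratio cut(s).
#' @examples
#' threshold_from_p(published_feeding_model(), 0.475)  # ~0.276
#' @export
threshold_from_p <- function(model, p) {
  if (any(is.na(p) | p <= 0 | p >= 1)) stop("p must lie in (0, 1)")
  if (model$slope == 0) stop("slope must be non-zero")
  arg <- exp((stats::qlogis(p) - model$intercept) / model$slope)
  if (any(arg >= pi / 2))
    stop("probability cut maps outside the arcsine domain (VR would be >= 1)")
  sin(arg)^2
}

#' Empirical ROC curve, AUC and Gini coefficient
#'
#' Sweeps every observed score as a threshold to build the empirical
#' receiver operating characteristic; the area under the curve is computed
#' by the trapezoid rule, which for tied scores is equivalent to the
#' rank-statistic (Mann-Whitney) form with ties averaged. The Gini
#' coefficient is \code{2*AUC - 1}. Deterministic; no smoothing.
#'
#' @param scores classifier scores (higher = more worm-like).
#' @param labels binary labels (1/0, logical, or "worm_like"/other).
#' @return object of class \code{"roc_curve"}: \code{curve} (data.frame of
#'   threshold, fpr, tpr), \code{auc}, \code{gini}.
#' @examples
#' r <- roc_curve(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
#' r$auc  # 1
#' @export
roc_curve <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.integer(as.character(labels) == "worm_like")
  labels <- as.integer(labels)
  ok <- stats::complete.cases(scores, labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(s) mean(scores[labels == 1] >= s), numeric(1))
  fpr <- vapply(thr, function(s) mean(scores[labels == 0] >= s), numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  # rank (Mann-Whitney) AUC: ties averaged, equals trapezoid on the curve
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(curve = curve, auc = auc, gini = 2 * auc - 1),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("Empirical ROC: AUC = %.4f, Gini = %.4f (%d thresholds)\n",
              x$auc, x$gini, nrow(x$curve) - 1L))
  invisible(x)
}

#' Conditional class proportions over equal-count bins
#'
#' A discrete analogue of a conditional density display: observations are
#' split into equal-count bins of \code{x} (quantile cuts) and the empirical
#' proportion of worm-like labels is reported per bin, with a Wilson score
#' interval rather than the kernel smoothing of a graphical conditional
#' density plot.
#'
#' @param x numeric covariate (e.g. velocity ratio).
#' @param labels binary labels as in [roc_curve()].
#' @param bins number of equal-count bins (default 5); \code{length(x)} must
#'   be at least \code{bins}.
#' @param conf confidence level for the Wilson interval (default 0.95).
#' @return data.frame with bin midpoints, counts, \code{prop} and Wilson
#'   \code{lower}/\code{upper}.
#' @export
conditional_density <- function(x, labels, bins = 5, conf = 0.95) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.integer(as.character(labels) == "worm_like")
  if (length(x) < bins) stop("need at least `bins` observations")
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        names = FALSE)
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  qs <- unique(qs)
  grp <- cut(x, breaks = qs, labels = FALSE, include.lowest = TRUE)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  out <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    xi <- x[grp == g]; yi <- labels[grp == g]
    n <- length(yi); p <- mean(yi)
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    data.frame(bin = g, x_mid = stats::median(xi), n = n, prop = p,
               lower = max(0, centre - half), upper = min(1, centre + half))
  }))
  out
}
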