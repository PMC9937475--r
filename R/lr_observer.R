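# The likelihood-ratio ideal observer. For a scalar decision variable x
# (a regional or total MTL volume) with class-conditional densities
# f_n (normal controls) and f_d (diseased), the observer scores
#
#     y(x) = log f_d(x) - log f_n(x)
#
# and calls "diseased" when y > 0. With Gaussian densities this is the
# one-dimensional quadratic discriminant; all evaluation is done in the
# log domain.

#' Fit a likelihood-ratio ideal-observer classifier
#'
#' Fits the pair of class-conditional densities (f_n from the NC group,
#' f_d from the AD group) of a volumetric measure, yielding the ideal
#' observer that scores a subject by the natural-log likelihood ratio
#' y = log f_d(x) - log f_n(x) and classifies y > 0 as diseased. The
#' score is threshold-free in the sense that the y = 0 criterion is the
#' equal-likelihood point; sweeping the threshold instead traces the
#' ROC curve (see [empirical_roc()]).
#'
#' @param cohort A [cohort_table()] containing both AD and NC subjects
#'   (the density-construction cohort).
#' @param measure A [measure_spec()]; defaults to the bilateral
#'   medial-temporal-lobe total, the best-performing measure.
#' @param backend `"gaussian"` (parametric, the primary analysis) or
#'   `"kde"` (Gaussian-kernel density cross-check).
#' @param ... Passed to [fit_kde()] for the KDE backend.
#' @return An object of class `lr_observer`: a list with elements
#'   `normal` and `diseased` (fitted densities), `measure`, `backend`,
#'   and `n` (named training counts).
#' @seealso [predict.lr_observer()], [decision_boundaries()],
#'   [binormal_az()], [evaluate_at_zero_threshold()]
#' @examples
#' set.seed(1)
#' train <- generate_cohort(default_recipe("adni_like", seed = 1))
#' fit <- lr_observer(train, mtl_measure())
#' fit
#' @export
lr_observer <- function(cohort, measure = mtl_measure(),
                        backend = c("gaussian", "kde"), ...) {
  backend <- match.arg(backend)
  stopifnot(inherits(cohort, "cohort_table"))
  vals <- measure_values(cohort, measure)
  if (any(vals$group == "UNKNOWN"))
    stop("density construction requires every subject labeled AD or NC",
         call. = FALSE)
  x_nc <- vals$value[vals$group == "NC"]
  x_ad <- vals$value[vals$group == "AD"]
  if (length(x_nc) == 0L || length(x_ad) == 0L)
    stop("construction cohort must contain both AD and NC subjects",
         call. = FALSE)
  fitter <- switch(backend,
                   gaussian = fit_gaussian,
                   kde = function(v) fit_kde(v, ...))
  structure(list(normal = fitter(x_nc), diseased = fitter(x_ad),
                 measure = measure, backend = backend,
                 n = c(NC = length(x_nc), AD = length(x_ad))),
            class = "lr_observer")
}

#' Assemble an LR observer from known density parameters
#'
#' Builds the observer directly from (mu, sigma) pairs — for instance
#' published cohort summary statistics — without subject-level data.
#'
#' @param normal,diseased `gaussian_density` objects (or the mu/sigma
#'   pairs via [gaussian_density()]) for NC and AD.
#' @param measure A [measure_spec()] describing the decision variable.
#' @return An `lr_observer`.
#' @export
lr_observer_from_params <- function(normal, diseased,
                                    measure = mtl_measure()) {
  stopifnot(inherits(normal, "volume_density"),
            inherits(diseased, "volume_density"))
  if (!identical(class(normal), class(diseased)))
    stop("both densities must use the same backend family", call. = FALSE)
  backend <- if (inherits(normal, "gaussian_density")) "gaussian" else "kde"
  structure(list(normal = normal, diseased = diseased, measure = measure,
                 backend = backend,
                 n = c(NC = normal$n %||% NA, AD = diseased$n %||% NA)),
            class = "lr_observer")
}

#' Log-likelihood-ratio score of a measurement
#'
#' Evaluates y = log f_d(x) - log f_n(x) (natural log) in the log
#' domain. The sign of y is invariant to the logarithm base, so the
#' diseased/normal decision does not depend on this choice.
#'
#' @param model An `lr_observer`.
#' @param x Numeric vector of measure values in mm^3.
#' @return Numeric vector of scores; positive means the diseased
#'   density is the more likely explanation.
#' @export
log_likelihood_ratio <- function(model, x) {
  stopifnot(inherits(model, "lr_observer"))
  ld <- density_logpdf(model$diseased, x)
  ln <- density_logpdf(model$normal, x)
  if (model$backend != "gaussian" && any(exp(ld) == 0 | exp(ln) == 0))
    stop("likelihood ratio undefined: a kernel density vanishes at x ",
         "(measurement far outside the fitted sample range)", call. = FALSE)
  y <- ld - ln
  if (any(!is.finite(y)))
    stop("likelihood ratio undefined: a density vanished at x",
         call. = FALSE)
  y
}

#' Classify subjects with a fitted LR observer
#'
#' Computes each subject's measure value, its log-likelihood-ratio
#' score, and the y > 0 decision. A score of exactly zero — equal
#' likelihood under both densities — is classified normal: ties go to
#' the null (non-diseased) class, the conservative clinical convention.
#'
#' @param object An `lr_observer`.
#' @param newdata A [cohort_table()] of subjects to classify; every
#'   subject must carry the volumes the model's measure requires.
#' @param ... Unused.
#' @return A data frame with columns `subject_id`, `group` (truth label
#'   if present), `value` (mm^3), `log_lr`, and `decision`
#'   (`"diseased"`/`"normal"`).
#' @export
predict.lr_observer <- function(object, newdata, ...) {
  vals <- measure_values(newdata, object$measure)
  vals$log_lr <- log_likelihood_ratio(object, vals$value)
  vals$decision <- ifelse(vals$log_lr > 0, "diseased", "normal")
  vals
}

#' @rdname predict.lr_observer
#' @param model An `lr_observer`.
#' @param newdata A [cohort_table()].
#' @export
classify <- function(model, newdata) predict(model, newdata)

#' Decision boundaries of a Gaussian-backend LR observer
#'
#' Solves y(x) = 0. In terms of the Gaussian parameters this is the
#' quadratic (1/sigma_n^2 - 1/sigma_d^2) x^2 / 2 + ... = 0: exactly one
#' root when sigma_n = sigma_d (the midpoint-like equal-likelihood
#' point), and zero, one or two real roots otherwise. Identical
#' densities make y identically zero, reported as a degenerate boundary.
#'
#' @param model An `lr_observer` with the Gaussian backend.
#' @return Numeric vector of boundary volumes (mm^3), increasing;
#'   length 0 with attribute `degenerate = TRUE` when the densities are
#'   identical, length 0 when the quadratic has no real root.
#' @export
decision_boundaries <- function(model) {
  stopifnot(inherits(model, "lr_observer"))
  if (model$backend != "gaussian")
    stop("decision boundaries are only available for the Gaussian backend",
         call. = FALSE)
  mn <- model$normal$mu;  sn <- model$normal$sigma
  md <- model$diseased$mu; sd_ <- model$diseased$sigma
  # y(x) = a x^2 + b x + c with:
  a <- 0.5 * (1 / sn^2 - 1 / sd_^2)
  b <- md / sd_^2 - mn / sn^2
  c0 <- 0.5 * (mn^2 / sn^2 - md^2 / sd_^2) + log(sn / sd_)
  if (a == 0 && b == 0) {
    out <- numeric(0L)
    attr(out, "degenerate") <- abs(c0) < 1e-12
    return(out)
  }
  if (a == 0) return(-c0 / b)
  disc <- b^2 - 4 * a * c0
  if (disc < 0) return(numeric(0L))
  sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
}

#' @export
print.lr_observer <- function(x, ...) {
  cat("Likelihood-ratio ideal observer (", x$backend, " backend)\n",
      sep = "")
  cat("  measure: ", x$measure$name, "\n", sep = "")
  cat("  f_n (NC): "); print(x$normal)
  cat("  f_d (AD): "); print(x$diseased)
  invisible(x)
}

#' @export
summary.lr_observer <- function(object, ...) {
  out <- list(model = object)
  if (object$backend == "gaussian") {
    out$az <- binormal_az(object$normal, object$diseased)
    out$boundaries <- decision_boundaries(object)
  }
  class(out) <- "summary.lr_observer"
  out
}

#' @export
print.summary.lr_observer <- function(x, ...) {
  print(x$model)
  if (!is.null(x$az)) {
    cat(sprintf("  binormal detectability index Az = %.3f\n", x$az))
    if (length(x$boundaries))
      cat("  y = 0 decision boundary(ies) at:",
          paste(sprintf("%.1f", x$boundaries), collapse = ", "),
          "mm^3\n")
  }
  invisible(x)
}

#' @export
coef.lr_observer <- function(object, ...) {
  if (object$backend != "gaussian")
    stop("coef() is defined for the Gaussian backend", call. = FALSE)
  matrix(c(object$normal$mu, object$normal$sigma,
           object$diseased$mu, object$diseased$sigma),
         nrow = 2L, byrow = TRUE,
         dimnames = list(c("NC", "AD"), c("mu", "sigma")))
}

#' Draw synthetic measure values from a fitted observer
#'
#' Simulates `nsim` pairs of cohorts of measure values from the fitted
#' class-conditional densities (Gaussian backend), e.g. for parametric
#' bootstrap checks of downstream statistics.
#'
#' @param object An `lr_observer` (Gaussian backend).
#' @param nsim Number of replicate data sets.
#' @param seed Optional integer seed.
#' @param n_nc,n_ad Cohort sizes; default to the training counts.
#' @param ... Unused.
#' @return A list of `nsim` data frames with columns `group`, `value`.
#' @export
simulate.lr_observer <- function(object, nsim = 1, seed = NULL,
                                 n_nc = NULL, n_ad = NULL, ...) {
  if (object$backend != "gaussian")
    stop("simulate() is defined for the Gaussian backend", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_nc <- n_nc %||% object$n[["NC"]]
  n_ad <- n_ad %||% object$n[["AD"]]
  lapply(seq_len(nsim), function(i) {
    data.frame(
      group = rep(c("NC", "AD"), c(n_nc, n_ad)),
      value = c(stats::rnorm(n_nc, object$normal$mu, object$normal$sigma),
                stats::rnorm(n_ad, object$diseased$mu,
                             object$diseased$sigma)),
      stringsAsFactors = FALSE)
  })
}

#' Plot the fitted class-conditional densities
#'
#' Overlays f_n and f_d over a range covering both fitted means plus
#' four standard deviations, marking the y = 0 decision boundary(ies).
#'
#' @param x An `lr_observer` (Gaussian backend).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.lr_observer <- function(x, ...) {
  stopifnot(x$backend == "gaussian")
  lo <- min(x$normal$mu - 4 * x$normal$sigma,
            x$diseased$mu - 4 * x$diseased$sigma)
  hi <- max(x$normal$mu + 4 * x$normal$sigma,
            x$diseased$mu + 4 * x$diseased$sigma)
  xs <- seq(lo, hi, length.out = 512L)
  fn <- density_pdf(x$normal, xs)
  fd <- density_pdf(x$diseased, xs)
  graphics::plot(xs, fn, type = "l", col = "blue",
                 xlab = paste(x$measure$name, "volume (mm^3)"),
                 ylab = "probability density (per mm^3)",
                 ylim = c(0, max(fn, fd)), ...)
  graphics::lines(xs, fd, col = "red")
  b <- decision_boundaries(x)
  if (length(b)) graphics::abline(v = b, lty = 2)
  graphics::legend("topright", legend = c("NC (f_n)", "AD (f_d)"),
                   col = c("blue", "red"), lty = 1, bty = "n")
  invisible(x)
}
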