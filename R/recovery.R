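#' Recovery coefficients and the volume-response curve
#'
#' The recovery coefficient (RC) of a structure is the ratio of measured to
#' true activity under noiseless emulation of the acquisition: it quantifies
#' partial-volume spill-out at the protocol resolution. The trend of RC
#' against volume is summarised by the two-parameter curve
#' `RC(V) = 1 / (1 + a/V)^b`.
#'
#' @name recovery
NULL

#' Simulate the recovery coefficient of a mask
#'
#' Places unit activity concentration in the mask (zero elsewhere), emulates
#' a noiseless acquisition with the model (including its post-filter), and
#' returns measured-over-true activity in the same mask. RC is defined on
#' noiseless simulation; a noisy model is an error.
#'
#' For a partial-weight mask the RC also absorbs the boundary-voxel sampling
#' loss of the weighted-VOI measurement (`sum(w^2)/sum(w)` at perfect
#' resolution): the coefficient is determined with exactly the measurement
#' procedure applied to the emulated patient images, so the correction
#' cancels it in the dose chain. A binary mask gives RC = 1 at sigma = 0.
#'
#' @param mask a non-empty [mask_voi()].
#' @param model a noiseless [acquisition_model()].
#' @param kidney_id,protocol labels carried into the record.
#' @return One-row tibble: `kidney_id`, `volume_mL`, `rc`, `protocol`,
#'   `postfilter_sigma_mm`.
#' @export
simulate_rc <- function(mask, model, kidney_id = mask$label,
                        protocol = NA_character_) {
  stopifnot(inherits(mask, "mask_voi"), inherits(model, "acquisition_model"))
  if (model$noise) {
    stop("RC must be simulated without noise; set `noise = FALSE`",
         call. = FALSE)
  }
  if (sum(mask$weights) == 0) stop("mask is empty", call. = FALSE)
  act <- voxel_image(mask$weights * 1, mask$spacing, mask$origin,
                     units = "MBq/mL")
  img <- acquire(act, model)
  true_activity <- sum(mask$weights) * voxel_volume(mask) # MBq at 1 MBq/mL
  rc <- voi_counts(img, mask) / (model$Q_cps_per_MBq * true_activity)
  tibble::tibble(
    kidney_id = kidney_id, volume_mL = voi_volume(mask), rc = rc,
    protocol = protocol, postfilter_sigma_mm = model$postfilter_sigma_mm
  )
}

#' Simulate recovery coefficients for a cohort
#'
#' @param cohort a `kidney_cohort` (or list of `kidney_phantom`s).
#' @param model a noiseless [acquisition_model()].
#' @param protocol label stored with each record.
#' @return Tibble with one RC record per kidney.
#' @export
simulate_rc_cohort <- function(cohort, model, protocol = NA_character_) {
  purrr::map_dfr(cohort, function(ph) {
    simulate_rc(ph$wkp_mask, model, kidney_id = ph$kidney_id,
                protocol = protocol)
  })
}

rc_curve_value <- function(V, a, b) 1 / (1 + a / V)^b

#' Fit the RC volume-response curve
#'
#' Nonlinear least squares of `rc ~ 1 / (1 + a/V)^b`, initialised from a
#' log-log linearization (for fixed `a`, `log RC` is linear in
#' `log(1 + a/V)`; a coarse grid over `a` picks the best starting pair).
#' Unweighted least squares on the RC scale.
#'
#' @param records tibble with columns `volume_mL` and `rc` (>= 3 records
#'   spanning at least a twofold volume range).
#' @return An `rc_fit` with elements `a` (mL), `b`, `residual_sd`, `n` and
#'   the fitted records; see [rc_predict()], [generics::tidy()] and
#'   [generics::glance()].
#' @export
fit_rc_curve <- function(records) {
  stopifnot(is.data.frame(records), all(c("volume_mL", "rc") %in% names(records)))
  V <- records$volume_mL
  rc <- records$rc
  if (length(V) < 3) stop("need at least 3 RC records", call. = FALSE)
  if (max(V) / min(V) < 2) {
    stop("RC records must span at least a twofold volume range", call. = FALSE)
  }
  if (any(rc <= 0)) stop("rc values must be positive", call. = FALSE)

  # flat data: b -> 0 limit, a unidentifiable
  if (max(rc) - min(rc) < 1e-12) {
    return(structure(
      list(a = mean(V), b = 0, residual_sd = 0, n = length(V),
           data = tibble::as_tibble(records)),
      class = "rc_fit"
    ))
  }

  lr <- log(rc)
  grid_a <- 10^seq(-1, 4, length.out = 40)
  init <- purrr::map_dfr(grid_a, function(a0) {
    x <- log1p(a0 / V)
    b0 <- -sum(lr * x) / sum(x^2)
    sse <- sum((rc - rc_curve_value(V, a0, max(b0, 1e-8)))^2)
    tibble::tibble(a = a0, b = max(b0, 1e-8), sse = sse)
  })
  best <- init[which.min(init$sse), ]

  df <- data.frame(V = V, rc = rc)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rc ~ 1 / (1 + a / V)^b, data = df,
      start = list(a = best$a, b = best$b),
      lower = c(a = 1e-8, b = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)
    ),
    error = function(e) {
      stop(sprintf(
        "RC curve fit did not converge (start a=%.3g, b=%.3g): %s",
        best$a, best$b, conditionMessage(e)
      ), call. = FALSE)
    }
  )
  est <- stats::coef(fit)
  res <- rc - rc_curve_value(V, est[["a"]], est[["b"]])
  structure(
    list(a = est[["a"]], b = est[["b"]],
         residual_sd = stats::sd(res), n = length(V),
         data = tibble::as_tibble(records)),
    class = "rc_fit"
  )
}

#' @export
print.rc_fit <- function(x, ...) {
  cat(sprintf(
    "<rc_fit> RC(V) = 1/(1 + a/V)^b with a = %.4g mL, b = %.4g  (n = %d, residual sd %.2g)\n",
    x$a, x$b, x$n, x$residual_sd
  ))
  invisible(x)
}

#' Predict RC at a volume
#'
#' Evaluates the fitted curve `1 / (1 + a/V)^b`; strictly increasing in `V`
#' and approaching 1 as `V` grows.
#'
#' @param fit an `rc_fit` (or list with elements `a` and `b`).
#' @param V volume(s) in mL, all > 0.
#' @return RC value(s).
#' @export
rc_predict <- function(fit, V) {
  if (any(V <= 0)) stop("`V` must be > 0", call. = FALSE)
  rc_curve_value(V, fit$a, fit$b)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.rc_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @exportS3Method generics::glance
glance.rc_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, residual_sd = x$residual_sd, n = x$n)
}

#' @exportS3Method ggplot2::autoplot
autoplot.rc_fit <- function(object, ...) {
  vgrid <- tibble::tibble(
    volume_mL = seq(min(object$data$volume_mL), max(object$data$volume_mL),
                    length.out = 200)
  )
  vgrid$rc <- rc_predict(object, vgrid$volume_mL)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$volume_mL, .data$rc)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = vgrid, colour = "steelblue") +
    ggplot2::labs(
      x = "volume (mL)", y = "recovery coefficient",
      title = sprintf("RC(V) = 1/(1 + %.3g/V)^%.3g", object$a, object$b)
    )
}

#' Coefficient of variation in percent
#'
#' `100 * sd / mean` with the sample standard deviation (n - 1 denominator).
#'
#' @param values numeric vector, length >= 2, nonzero mean.
#' @return COV in percent.
#' @export
cov_percent <- function(values) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("mean is zero; COV undefined", call. = FALSE)
  100 * stats::sd(values) / m
}
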