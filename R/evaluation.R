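#' Method agreement: normalization factors, bias, accuracy, Bland-Altman
#'
#' The WKP method is the reference. SV doses are normalised by the mean
#' single-SV dose ratio (the "apparent recovery coefficient" of the SV
#' method), and agreement is summarised by the mean (bias) and sample
#' standard deviation (accuracy) of the percentage difference, the Pearson
#' correlation, and Bland-Altman 95% limits of agreement.
#'
#' @name evaluation
NULL

#' Normalization factor for an SV method
#'
#' Arithmetic mean of single-SV over WKP dose ratios across all kidney x SV
#' pairs of one (SV volume, post-filter) stratum; with 36 kidneys and 5
#' single SVs each this is a mean of 180 ratio terms.
#'
#' @param d_sv single-SV doses, Gy.
#' @param d_wkp matching WKP reference doses, Gy (> 0).
#' @return The normalization factor (unitless mean ratio).
#' @export
normalization_factor <- function(d_sv, d_wkp) {
  if (length(d_sv) == 0) stop("no dose pairs supplied", call. = FALSE)
  if (length(d_sv) != length(d_wkp)) {
    stop("`d_sv` and `d_wkp` must have equal length", call. = FALSE)
  }
  if (any(d_wkp <= 0)) stop("all `d_wkp` must be > 0", call. = FALSE)
  mean(d_sv / d_wkp)
}

#' Apply a normalization factor
#'
#' @param d_sv SV dose(s), Gy.
#' @param nf normalization factor (> 0).
#' @return Normalized dose(s) `d_sv / nf`, Gy.
#' @export
apply_nf <- function(d_sv, nf) {
  if (nf <= 0) stop("`nf` must be > 0", call. = FALSE)
  d_sv / nf
}

#' Percentage difference against the reference method
#'
#' `100 * (d_svn - d_wkp) / d_wkp`.
#'
#' @param d_svn normalized SV dose(s), Gy.
#' @param d_wkp reference WKP dose(s), Gy (> 0).
#' @return Percentage difference(s).
#' @export
percent_difference <- function(d_svn, d_wkp) {
  if (any(d_wkp <= 0)) stop("all `d_wkp` must be > 0", call. = FALSE)
  100 * (d_svn - d_wkp) / d_wkp
}

#' Bias and accuracy of percentage differences
#'
#' Mean (bias) and sample standard deviation with n - 1 denominator
#' (accuracy) of the percentage differences.
#'
#' @param pds percentage differences, length >= 2.
#' @return Tibble with `bias_pct` and `accuracy_pct`.
#' @export
bias_accuracy <- function(pds) {
  if (length(pds) < 2) stop("need at least 2 percentage differences",
                            call. = FALSE)
  tibble::tibble(bias_pct = mean(pds), accuracy_pct = stats::sd(pds))
}

#' Bland-Altman agreement on the percentage-difference scale
#'
#' Differences are normalised to the reference method (percentage
#' differences); the limits of agreement are `bias +/- 1.96 x SD` exactly.
#'
#' @param d_sv test-method doses, Gy.
#' @param d_wkp reference doses, Gy (> 0); at least 3 pairs.
#' @return A `bland_altman` list: `bias_pct`, `sd_pct`, `loa_low`,
#'   `loa_high`, `n`, and the per-pair data.
#' @export
bland_altman <- function(d_sv, d_wkp) {
  if (length(d_sv) != length(d_wkp)) {
    stop("`d_sv` and `d_wkp` must have equal length", call. = FALSE)
  }
  if (length(d_sv) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (any(d_wkp <= 0)) stop("all `d_wkp` must be > 0", call. = FALSE)
  pd <- percent_difference(d_sv, d_wkp)
  bias <- mean(pd)
  s <- stats::sd(pd)
  structure(
    list(
      bias_pct = bias, sd_pct = s,
      loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
      n = length(pd),
      data = tibble::tibble(mean_dose_Gy = (d_sv + d_wkp) / 2, pd_pct = pd)
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> bias %.2f%%, accuracy (SD) %.2f%%, LoA [%.2f, %.2f]%% (n = %d)\n",
    x$bias_pct, x$sd_pct, x$loa_low, x$loa_high, x$n
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(bias_pct = x$bias_pct, sd_pct = x$sd_pct,
                 loa_low = x$loa_low, loa_high = x$loa_high, n = x$n)
}

#' @exportS3Method ggplot2::autoplot
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$mean_dose_Gy, .data$pd_pct)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias_pct, colour = "red") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        colour = "red", linetype = "dashed") +
    ggplot2::labs(x = "mean dose (Gy)",
                  y = "difference vs reference (%)",
                  title = "Bland-Altman agreement")
}

#' Pearson correlation coefficient
#'
#' Product-moment correlation with validity checks (n >= 3, nonzero
#' variance in both vectors).
#'
#' @param x,y numeric vectors of equal length.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length",
                                   call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance; correlation undefined", call. = FALSE)
  }
  stats::cor(x, y, method = "pearson")
}

#' Sweep the SV method over sphere volume, SV count and post-filter
#'
#' The experiment driver: for every kidney of the cohort it emulates the
#' SPECT series once at the protocol resolution, then for each post-filter
#' sigma derives the filtered images, the per-kidney simulated recovery
#' coefficient and the WKP reference dose, places `max(n_svs)` spheres of
#' each SV volume on the first-time-point image, and computes single-SV and
#' k-SV-mean doses. Per (SV volume, sigma) stratum the normalization factor
#' is the mean of the single-SV dose ratios; per (SV volume, k, sigma) cell
#' the summary holds the NF, bias, accuracy, Pearson r and Bland-Altman
#' limits of the NF-corrected doses. The k-SV means use the first k of the
#' placed spheres (greedy prefix), so the k sweep is nested.
#'
#' @param cohort a `kidney_cohort`.
#' @param model base [acquisition_model()]; its own post-filter should be 0,
#'   the sweep applies `sigmas` itself.
#' @param sv_volumes SV volumes, mL.
#' @param n_svs SV counts to evaluate (averaging the first k spheres).
#' @param place_k number of spheres placed per kidney (the normalization factor
#'   is defined over 5 single SVs per kidney, independently of which SV
#'   counts are evaluated).
#' @param sigmas post-filter sigmas, mm.
#' @param times acquisition schedule, h.
#' @param seed seed for the per-kidney, per-time noise draws.
#' @param nf_mode `"in_sample"` (the study design: NF from all kidneys) or
#'   `"split"` (NF from a training half of the patients, agreement reported
#'   on the held-out half; quantifies the optimism of in-sample correction).
#' @param split_fraction fraction of patients in the training half.
#' @return An `sv_sweep` tibble: one row per (sv_volume_mL, n_svs, sigma_mm)
#'   with `nf`, `bias_pct`, `accuracy_pct`, `pearson_r`, `loa_low`,
#'   `loa_high`, `n_kidneys`, `n_ratio_terms`, `seed`. Attributes `singles`
#'   and `doses` hold the per-kidney dose tables; `wkp` the reference doses.
#' @export
run_sweep <- function(cohort, model = protocol_preset("ASCC", noise = TRUE),
                      sv_volumes = c(4, 2, 0.6), n_svs = 1:5, place_k = 5L,
                      sigmas = c(0, 4), times = c(24, 48, 168),
                      seed = 1L, nf_mode = c("in_sample", "split"),
                      split_fraction = 0.5) {
  nf_mode <- match.arg(nf_mode)
  stopifnot(inherits(cohort, "kidney_cohort"), max(n_svs) <= place_k)
  if (model$postfilter_sigma_mm != 0) {
    stop("the sweep applies `sigmas` itself; use a model with postfilter 0",
         call. = FALSE)
  }
  manifest <- cohort_manifest(cohort)
  noise_seeds <- withr::with_seed(as.integer(seed), {
    matrix(sample.int(.Machine$integer.max, length(cohort) * length(times)),
           nrow = length(cohort))
  })

  singles <- list()
  kdoses <- list()
  wkps <- list()
  for (i in seq_along(cohort)) {
    ph <- cohort[[i]]
    raw <- purrr::map(seq_along(times), function(j) {
      acquire(activity_at(ph, times[j]), model, seed = noise_seeds[i, j])
    })
    for (sg in sigmas) {
      imgs <- purrr::map(raw, postfilter, sigma_mm = sg)
      rc_model <- acquisition_model(
        model$system_sigma_mm, model$Q_cps_per_MBq, model$acq_time_s,
        noise = FALSE, postfilter_sigma_mm = sg
      )
      rc_k <- simulate_rc(ph$wkp_mask, rc_model)$rc
      d_wkp <- estimate_dose(ph, imgs, times, method = "WKP",
                             Q = model$Q_cps_per_MBq, rc = rc_k)$dose_Gy
      wkps[[length(wkps) + 1]] <- tibble::tibble(
        kidney_id = ph$kidney_id, sigma_mm = sg, rc = rc_k, d_wkp = d_wkp
      )
      for (sv_v in sv_volumes) {
        svs <- suppressWarnings(
          place_svs(imgs[[1]], ph$wkp_mask, sv_v, k = place_k)
        )
        n_av <- length(svs$masks)
        # per-SV, per-time concentration matrix (n_av x n_times)
        conc <- vapply(imgs, function(img) {
          vapply(svs$masks, function(m) {
            sv_concentration(voi_counts(img, m), model$Q_cps_per_MBq, sv_v)
          }, numeric(1))
        }, numeric(n_av))
        conc <- matrix(conc, nrow = n_av)
        dose_of <- function(cvec) {
          fit <- fit_monoexp(data.frame(t = times, concentration = cvec))
          absorbed_dose(tiac(fit))
        }
        d_single <- apply(conc, 1, dose_of)
        singles[[length(singles) + 1]] <- tibble::tibble(
          kidney_id = ph$kidney_id, patient = manifest$patient[i],
          sv_volume_mL = sv_v, sigma_mm = sg,
          sv_index = seq_len(n_av), d_sv = d_single, d_wkp = d_wkp
        )
        d_k <- vapply(n_svs, function(k) {
          dose_of(colMeans(conc[seq_len(min(k, n_av)), , drop = FALSE]))
        }, numeric(1))
        kdoses[[length(kdoses) + 1]] <- tibble::tibble(
          kidney_id = ph$kidney_id, patient = manifest$patient[i],
          sv_volume_mL = sv_v, sigma_mm = sg, n_svs = n_svs,
          n_svs_used = pmin(n_svs, n_av), d_sv = d_k, d_wkp = d_wkp
        )
      }
    }
  }
  singles <- dplyr::bind_rows(singles)
  kdoses <- dplyr::bind_rows(kdoses)
  wkps <- dplyr::bind_rows(wkps)

  train_patients <- unique(manifest$patient)
  if (nf_mode == "split") {
    n_train <- max(1, round(length(train_patients) * split_fraction))
    train_patients <- withr::with_seed(
      as.integer(seed) + 1L,
      sample(unique(manifest$patient), n_train)
    )
  }
  nf_tab <- singles |>
    dplyr::filter(.data$patient %in% train_patients) |>
    dplyr::group_by(.data$sv_volume_mL, .data$sigma_mm) |>
    dplyr::summarise(
      nf = normalization_factor(.data$d_sv, .data$d_wkp),
      n_ratio_terms = dplyr::n(), .groups = "drop"
    )

  eval_doses <- if (nf_mode == "split") {
    dplyr::filter(kdoses, !(.data$patient %in% train_patients))
  } else {
    kdoses
  }
  summary <- eval_doses |>
    dplyr::left_join(nf_tab, by = c("sv_volume_mL", "sigma_mm")) |>
    dplyr::group_by(.data$sv_volume_mL, .data$n_svs, .data$sigma_mm) |>
    dplyr::summarise(
      nf = .data$nf[1], n_ratio_terms = .data$n_ratio_terms[1],
      bias_pct = mean(percent_difference(apply_nf(.data$d_sv, .data$nf[1]),
                                         .data$d_wkp)),
      accuracy_pct = stats::sd(
        percent_difference(apply_nf(.data$d_sv, .data$nf[1]), .data$d_wkp)
      ),
      raw_bias_pct = mean(percent_difference(.data$d_sv, .data$d_wkp)),
      pearson_r = pearson_r(.data$d_sv, .data$d_wkp),
      loa_low = .data$bias_pct - 1.96 * .data$accuracy_pct,
      loa_high = .data$bias_pct + 1.96 * .data$accuracy_pct,
      n_kidneys = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(seed = as.integer(seed), nf_mode = nf_mode)

  structure(
    summary,
    class = c("sv_sweep", class(summary)),
    singles = singles, doses = kdoses, wkp = wkps
  )
}

#' Per-SV and per-k dose tables of a sweep
#'
#' @param sweep an `sv_sweep` from [run_sweep()].
#' @return `sweep_singles()`: one row per kidney x single SV;
#'   `sweep_doses()`: one row per kidney x SV count; `sweep_wkp()`: the WKP
#'   reference doses and per-kidney recovery coefficients.
#' @export
sweep_singles <- function(sweep) attr(sweep, "singles")

#' @rdname sweep_singles
#' @export
sweep_doses <- function(sweep) attr(sweep, "doses")

#' @rdname sweep_singles
#' @export
sweep_wkp <- function(sweep) attr(sweep, "wkp")

#' @exportS3Method ggplot2::autoplot
autoplot.sv_sweep <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(.data$n_svs, .data$accuracy_pct,
                 colour = factor(.data$sigma_mm))
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~sv_volume_mL, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "number of SVs", y = "accuracy: SD of PD (%)",
                  colour = "post-filter\nsigma (mm)")
}

#' Render a sweep as a Markdown accuracy grid
#'
#' Accuracy of the NF-corrected SV doses by segmentation method and SV
#' count, at one post-filter sigma.
#'
#' @param sweep an `sv_sweep`.
#' @param sigma_mm which post-filter stratum to tabulate.
#' @return Character vector of Markdown lines (invisibly printed).
#' @export
sweep_markdown <- function(sweep, sigma_mm = 4) {
  tab <- sweep |>
    dplyr::filter(.data$sigma_mm == !!sigma_mm) |>
    dplyr::select("sv_volume_mL", "n_svs", "accuracy_pct") |>
    tidyr::pivot_wider(names_from = "n_svs", values_from = "accuracy_pct",
                       names_prefix = "k=")
  hdr <- paste0("| SV volume (mL) | ",
                paste(sprintf("%s SV", sub("k=", "", names(tab)[-1])),
                      collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|")
  rows <- apply(tab, 1, function(r) {
    paste0("| ", r[1], " | ",
           paste(sprintf("%.1f", as.numeric(r[-1])), collapse = " | "), " |")
  })
  lines <- c(sprintf("Accuracy (SD of PD, %%) at %g mm post-filter", sigma_mm),
             "", hdr, sep, rows)
  cat(lines, sep = "\n")
  invisible(lines)
}
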