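# Cohort report: per-parameter percentage-difference summaries with paired
# t-tests at the Bonferroni-corrected level, contour similarity summaries,
# the cross-patient difference histogram and the TLG prognosis table.

#' Build the cohort study report
#'
#' Mirrors the structure of the clinical analysis: per-lesion percentage
#' differences (CTACstd - CTACcba, relative to CTACcba) of GTV volume,
#' SUVmax, SUVmean and TLG for both contour methods (eight paired t-tests at
#' the corrected alpha), Dice/MDA summaries, the whole-image per-voxel SUV
#' difference, and TLG-based prognosis classification under both literature
#' rules.
#'
#' @param records list of `study_record`s from [simulate_patient()].
#' @param config the [study_config()] used.
#' @return object of class `study_report` with tibble fields `parameters`,
#'   `similarity`, `contours`, `metabolic`, `histogram`, `whole_image`,
#'   `prognosis`.
#' @export
build_study_report <- function(records, config = study_config()) {
  stopifnot(length(records) >= 1)
  contours <- dplyr::bind_rows(lapply(records, `[[`, "contours"))
  metabolic <- dplyr::bind_rows(lapply(records, `[[`, "metabolic"))
  alpha_c <- bonferroni_alpha(config$alpha, config$n_tests)

  metab_wide <- metabolic |>
    tidyr::pivot_longer(c("suv_max", "suv_mean", "volume_cm3", "tlg_g"),
                        names_to = "parameter", values_to = "value") |>
    tidyr::pivot_wider(names_from = "source_image", values_from = "value")

  param_rows <- list()
  for (method in unique(metab_wide$method)) {
    for (parameter in c("volume_cm3", "suv_max", "suv_mean", "tlg_g")) {
      sub <- dplyr::filter(metab_wide, .data$method == !!method,
                           .data$parameter == !!parameter)
      if (nrow(sub) < 2) next
      param_rows[[length(param_rows) + 1L]] <-
        cohort_summary(parameter, method, sub$CTACstd, sub$CTACcba, alpha_c)
    }
  }
  parameters <- dplyr::bind_rows(param_rows)

  similarity <- contours |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      n = dplyr::n(),
      dice_mean = mean(.data$dice),
      dice_se = sd(.data$dice) / sqrt(dplyr::n()),
      mda_mean_mm = mean(.data$mda_mm),
      mda_se_mm = sd(.data$mda_mm) / sqrt(dplyr::n()),
      pct_volume_diff_mean = mean(.data$pct_volume_diff),
      pct_volume_diff_se = sd(.data$pct_volume_diff) / sqrt(dplyr::n()),
      .groups = "drop"
    )

  histogram <- histogram_summary(lapply(records, `[[`, "histogram"))
  whole_image <- tibble::tibble(
    patient_id = vapply(records, `[[`, "", "patient_id"),
    mean_pct_diff = vapply(records, `[[`, 0, "whole_image_pct")
  )

  prognosis <- dplyr::bind_rows(lapply(c("choi", "ogawa"), function(nm) {
    rule <- prognosis_rule(nm)
    rep_tbl <- prognosis_tlg_table(records, rule, config)
    if (nrow(rep_tbl) == 0) return(NULL)
    cls <- classify_prognosis(rep_tbl, rule)
    cutoff <- rule$cutoff_g
    dplyr::mutate(cls, rule = nm, cutoff_g = cutoff, .before = 1)
  }))

  structure(list(parameters = parameters, similarity = similarity,
                 contours = contours, metabolic = metabolic,
                 histogram = histogram, whole_image = whole_image,
                 prognosis = prognosis, config = config,
                 n_patients = length(records)),
            class = "study_report")
}

# Per-lesion TLG at a prognosis rule's own SUVmax fraction (or reusing the
# study threshold GTVs when configured), on both image variants.
prognosis_tlg_table <- function(records, rule, config) {
  rows <- list()
  for (rec in records) {
    for (lesion_id in names(rec$gtvs)) {
      lesion <- rec$gtvs[[lesion_id]]
      for (variant in c("CTACstd", "CTACcba")) {
        contour <- if (isTRUE(config$prognosis_use_study_fraction)) {
          lesion[[variant]]$threshold
        } else {
          tryCatch(
            prognostic_volume(rec$suv[[variant]],
                              lesion[[variant]]$semi_manual, rule,
                              margin_mm = config$margin_mm),
            error = function(e) NULL)
        }
        if (is.null(contour)) next
        st <- suv_stats(rec$suv[[variant]], contour$mask)
        vol <- mask_volume(contour$mask)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          patient_id = rec$patient_id, lesion_id = lesion_id,
          lesion_label = contour$lesion_label, source_image = variant,
          tlg_g = tlg(st$suv_mean, vol)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d patients, %d lesion-method rows\n",
              x$n_patients, nrow(x$contours)))
  cat(sprintf("  whole-image mean SUV difference: %.1f%%\n",
              mean(x$whole_image$mean_pct_diff)))
  cat(sprintf("  corrected alpha: %.4g\n", x$parameters$alpha_corrected[1]))
  print(x$parameters[, c("parameter", "method", "mean_pct", "se_pct", "p",
                         "significant")])
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a study report
#'
#' One row per tested parameter-method combination with the percentage
#' difference summary and paired t-test.
#'
#' @param x a `study_report`.
#' @param ... unused.
#' @export
tidy.study_report <- function(x, ...) x$parameters

#' One-row study report summary
#'
#' @param x a `study_report`.
#' @param ... unused.
#' @export
glance.study_report <- function(x, ...) {
  tibble::tibble(
    n_patients = x$n_patients,
    n_lesions = nrow(dplyr::distinct(x$contours, .data$patient_id,
                                     .data$lesion_id)),
    whole_image_mean_pct = mean(x$whole_image$mean_pct_diff),
    alpha_corrected = bonferroni_alpha(x$config$alpha, x$config$n_tests),
    n_significant = sum(x$parameters$significant),
    n_changed_prognosis = if (nrow(x$prognosis)) sum(x$prognosis$changed_group)
                          else 0L
  )
}
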