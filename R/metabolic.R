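# Metabolic parameters (SUVmax, SUVmean, TLG) per GTV and TLG-based
# prognostic classification against literature cut-offs.

#' SUV statistics inside a mask
#'
#' @param suv `SUV` [image_volume()].
#' @param mask non-empty [binary_mask()] on the same grid.
#' @return named list `suv_max`, `suv_mean` (g/mL).
#' @export
suv_stats <- function(suv, mask) {
  assert_semantic(suv, "SUV")
  assert_same_grid(suv, mask)
  if (!any(mask$values)) abort("mask is empty.")
  v <- suv$values[mask$values]
  list(suv_max = max(v), suv_mean = mean(v))
}

#' Total lesion glycolysis
#'
#' `TLG = SUVmean x volume`; g/mL times cm^3 gives grams.
#'
#' @param suv_mean mean SUV in g/mL (> 0).
#' @param volume_cm3 lesion volume in cm^3 (> 0).
#' @return TLG in grams.
#' @export
tlg <- function(suv_mean, volume_cm3) {
  stopifnot(suv_mean > 0, volume_cm3 > 0)
  suv_mean * volume_cm3
}

#' Metabolic report for one GTV
#'
#' @param suv `SUV` [image_volume()].
#' @param contour a `gtv_contour`.
#' @return one-row tibble: `lesion_label`, `source_image`, `method`,
#'   `suv_max`, `suv_mean`, `volume_cm3`, `tlg_g`.
#' @export
metabolic_report <- function(suv, contour) {
  stopifnot(inherits(contour, "gtv_contour"))
  st <- suv_stats(suv, contour$mask)
  vol <- mask_volume(contour$mask)
  tibble::tibble(
    lesion_label = contour$lesion_label,
    source_image = contour$source_image,
    method = contour$method,
    suv_max = st$suv_max,
    suv_mean = st$suv_mean,
    volume_cm3 = vol,
    tlg_g = tlg(st$suv_mean, vol)
  )
}

#' TLG prognosis rules
#'
#' Literature rules for rectal cancer: `"choi"` thresholds the prognostic
#' volume at 50% of SUVmax and compares the primary-lesion TLG to 125.84 g;
#' `"ogawa"` uses 30% of SUVmax and compares the combined primary + nodal
#' TLG to 341 g. TLG at or above the cut-off classifies the patient as poor
#' prognosis.
#'
#' @param name `"choi"` or `"ogawa"`.
#' @return object of class `prognosis_rule` with fields `name`,
#'   `threshold_fraction`, `cutoff_g`, `scope`.
#' @export
prognosis_rule <- function(name = c("choi", "ogawa")) {
  name <- match.arg(name)
  if (name == "choi") {
    structure(list(name = "choi", threshold_fraction = 0.50,
                   cutoff_g = 125.84, scope = "primary_only"),
              class = "prognosis_rule")
  } else {
    structure(list(name = "ogawa", threshold_fraction = 0.30,
                   cutoff_g = 341, scope = "primary_plus_nodal"),
              class = "prognosis_rule")
  }
}

#' Prognostic volume at a rule's SUVmax fraction
#'
#' Same machinery as [percentage_threshold_gtv()] (strict threshold,
#' expansion limits) but with the rule's own fraction (30% or 50% of
#' SUVmax).
#'
#' @param suv `SUV` [image_volume()].
#' @param manual the semi-manual `gtv_contour`.
#' @param rule a [prognosis_rule()].
#' @param margin_mm,margin_overrides expansion constraints, as in
#'   [percentage_threshold_gtv()].
#' @return a `gtv_contour`.
#' @export
prognostic_volume <- function(suv, manual, rule, margin_mm = 5.0,
                              margin_overrides = NULL) {
  stopifnot(inherits(rule, "prognosis_rule"))
  percentage_threshold_gtv(suv, manual, fraction = rule$threshold_fraction,
                           margin_mm = margin_mm,
                           margin_overrides = margin_overrides)
}

#' Classify prognosis from TLG values
#'
#' Applies a TLG cut-off per patient and image variant and flags patients
#' whose prognosis group depends on the AC-map variant. TLG >= cut-off is
#' poor prognosis. For the primary-only scope, patients without a primary
#' lesion (e.g. post-surgery) are skipped; for the combined scope, TLG is
#' summed over primary and nodal lesions.
#'
#' @param reports tibble with columns `patient_id`, `lesion_label`,
#'   `source_image`, `tlg_g` (one row per lesion per variant).
#' @param rule a [prognosis_rule()].
#' @return tibble with one row per classifiable patient: `patient_id`,
#'   `tlg_std_g`, `tlg_cba_g`, `group_std`, `group_cba`, `changed_group`,
#'   plus attribute `skipped` (patient ids lacking the required lesions).
#' @export
classify_prognosis <- function(reports, rule) {
  stopifnot(inherits(rule, "prognosis_rule"))
  req <- c("patient_id", "lesion_label", "source_image", "tlg_g")
  if (!all(req %in% names(reports))) {
    abort("`reports` needs patient_id, lesion_label, source_image, tlg_g.")
  }
  use <- if (rule$scope == "primary_only") {
    dplyr::filter(reports, .data$lesion_label == "primary")
  } else reports
  per <- use |>
    dplyr::group_by(.data$patient_id, .data$source_image) |>
    dplyr::summarise(tlg_g = sum(.data$tlg_g), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "source_image", values_from = "tlg_g",
                       names_prefix = "tlg_")
  all_ids <- unique(reports$patient_id)
  skipped <- setdiff(all_ids, per$patient_id)
  out <- per |>
    dplyr::mutate(
      group_std = ifelse(.data$tlg_CTACstd >= rule$cutoff_g, "poor", "good"),
      group_cba = ifelse(.data$tlg_CTACcba >= rule$cutoff_g, "poor", "good"),
      changed_group = .data$group_std != .data$group_cba
    ) |>
    dplyr::rename(tlg_std_g = "tlg_CTACstd", tlg_cba_g = "tlg_CTACcba")
  attr(out, "skipped") <- skipped
  out
}
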