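# Spectrum containers and envelope quantification.
#
# A MassSpectrum is a plain tibble with columns `mz` (strictly increasing)
# and `intensity` (>= 0) — profile data from one flow-injection acquisition.

validate_spectrum <- function(spectrum) {
  spectrum <- tibble::as_tibble(spectrum)
  stopifnot(all(c("mz", "intensity") %in% names(spectrum)))
  if (nrow(spectrum) > 1 && any(diff(spectrum$mz) <= 0)) {
    stop("spectrum m/z values must be strictly increasing", call. = FALSE)
  }
  if (any(spectrum$intensity < 0)) stop("intensities must be non-negative", call. = FALSE)
  spectrum
}

#' Read a spectrum from a two-column CSV
#'
#' Expects a header `mz,intensity`; returns the validated spectrum tibble.
#'
#' @param path Path to the CSV file.
#' @return Tibble with columns `mz`, `intensity`.
#' @export
read_spectrum_csv <- function(path) {
  validate_spectrum(utils::read.csv(path))
}

#' Write a spectrum to a two-column CSV
#'
#' @param spectrum Spectrum tibble (`mz`, `intensity`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(validate_spectrum(spectrum)[, c("mz", "intensity")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Summed intensity in a window around a diagnostic m/z
#'
#' Sums all profile intensities with m/z in `[center - window, center + window]`;
#' returns 0 when the window is empty.
#'
#' @param spectrum Spectrum tibble (`mz`, `intensity`).
#' @param center Window centre in m/z.
#' @param window Half-width in m/z (positive).
#' @return Summed intensity (scalar).
#' @export
extract_intensity <- function(spectrum, center, window) {
  if (window <= 0) stop("window must be positive", call. = FALSE)
  spectrum <- validate_spectrum(spectrum)
  inside <- spectrum$mz >= center - window & spectrum$mz <= center + window
  sum(spectrum$intensity[inside])
}

#' Quantify isoform signals from a spectrum
#'
#' For each isoform in the panel, sums [extract_intensity()] over its
#' diagnostic charge-state m/z values ("summing the signals" across the
#' 10+ to 13+ envelope) and calibrates the result to g/L. Deterministic.
#'
#' @param spectrum Spectrum tibble (`mz`, `intensity`), or a tibble with an
#'   additional `sample_id` column holding several spectra, in which case each
#'   sample is quantified separately.
#' @param panel A [blg_panel()].
#' @return Tibble with one row per (sample and) isoform: columns `isoform`,
#'   `units` (arb), `g_per_l`; plus `sample_id` when present in the input.
#' @export
quantify_isoforms <- function(spectrum, panel = blg_panel()) {
  panel <- tibble::as_tibble(panel)
  if (nrow(panel) == 0L) stop("panel is empty", call. = FALSE)
  quant_one <- function(sp) {
    sp <- validate_spectrum(sp)
    panel |>
      dplyr::group_by(.data$isoform) |>
      dplyr::summarise(
        units = sum(purrr::map2_dbl(.data$mz, .data$window,
                                    ~ extract_intensity(sp, .x, .y))),
        .groups = "drop"
      ) |>
      dplyr::mutate(g_per_l = purrr::map2_dbl(
        .data$units, .data$isoform, ~ calibrate_units(.x, .y, panel)
      ))
  }
  if ("sample_id" %in% names(spectrum)) {
    spectrum |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::group_modify(~ quant_one(.x)) |>
      dplyr::ungroup()
  } else {
    quant_one(spectrum)
  }
}

#' Pivot a quantification table to one row per sample
#'
#' Convenience reshape of [quantify_isoforms()] output to the wide layout the
#' screening step consumes (`A_units`, `B_units`, `A_gl`, `B_gl`).
#'
#' @param quant Long quantification tibble with `sample_id`, `isoform`,
#'   `units`, `g_per_l`.
#' @return Wide tibble, one row per sample.
#' @export
quant_wide <- function(quant) {
  quant |>
    tidyr::pivot_wider(
      id_cols = "sample_id", names_from = "isoform",
      values_from = c("units", "g_per_l"),
      names_glue = "{isoform}_{ifelse(.value == 'units', 'units', 'gl')}"
    )
}
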