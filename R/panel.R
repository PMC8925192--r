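#' Diagnostic charge-state panel for the BLG A and B isoforms
#'
#' Builds the panel of diagnostic m/z signals used to quantify the
#' beta-lactoglobulin A and B protein isoforms from a flow-injection ESI
#' spectrum. One row per isoform x charge state. Defaults reproduce the
#' screening assay: the 13+ to 10+ signals of the A isoform at
#' 1413.4 / 1531.1 / 1670.2 / 1837.1 m/z and of the B isoform at
#' 1406.8 / 1523.9 / 1662.4 / 1828.5 m/z, with linear single-point
#' calibrations of 180 arb units = 4.8 g/L (A, the mean of AA milks) and
#' 80 arb units = 3.4 g/L (B, the mean of BB milks).
#'
#' Neutral average masses default to the values deconvoluted from the
#' diagnostic m/z themselves (A: 18361.05 Da, B: 18274.99 Da); the constructor
#' checks that every m/z in the panel is consistent with its isoform's neutral
#' mass and charge under [mz_for_charge()] to within 0.05 m/z.
#'
#' Note the B channel does not discriminate the B protein isoform from the
#' rare C isoform; C-carrying milks contribute to `B_units`.
#'
#' @param neutral_mass Named numeric: neutral average mass (Da) per isoform.
#' @param charges Integer vector of charge states shared by both isoforms.
#' @param mz_list Named list of diagnostic m/z vectors, aligned with `charges`.
#'   Defaults to the printed assay values; pass `NULL` to compute from
#'   `neutral_mass`.
#' @param window Extraction half-width in m/z around each diagnostic signal.
#' @param calibration Named list of `c(units, g_per_l)` single-point
#'   calibration pairs per isoform.
#' @return A tibble of class `blg_panel` with columns `isoform`, `charge`,
#'   `mz`, `neutral_mass`, `window`, `cal_units`, `cal_gl`.
#' @examples
#' blg_panel()
#' @export
blg_panel <- function(neutral_mass = c(A = 18361.05, B = 18274.99),
                      charges = 13:10,
                      mz_list = list(
                        A = c(1413.4, 1531.1, 1670.2, 1837.1),
                        B = c(1406.8, 1523.9, 1662.4, 1828.5)
                      ),
                      window = 1.0,
                      calibration = list(
                        A = c(units = 180, g_per_l = 4.8),
                        B = c(units = 80, g_per_l = 3.4)
                      )) {
  stopifnot(length(neutral_mass) >= 1, !is.null(names(neutral_mass)))
  if (window <= 0) stop("extraction window must be positive", call. = FALSE)
  isoforms <- names(neutral_mass)
  if (is.null(mz_list)) {
    mz_list <- lapply(stats::setNames(isoforms, isoforms), function(i) {
      mz_for_charge(neutral_mass[[i]], charges)
    })
  }
  panel <- purrr::map_dfr(isoforms, function(i) {
    mz <- mz_list[[i]]
    stopifnot(length(mz) == length(charges))
    expected <- mz_for_charge(neutral_mass[[i]], charges)
    off <- abs(mz - expected)
    if (any(off > 0.05)) {
      stop(sprintf(
        "panel m/z for isoform %s inconsistent with its neutral mass (max off %.3f m/z)",
        i, max(off)
      ), call. = FALSE)
    }
    cal <- calibration[[i]]
    if (is.null(cal) || cal[["units"]] <= 0) {
      stop("each isoform needs a calibration pair with positive units", call. = FALSE)
    }
    tibble::tibble(
      isoform = i, charge = as.integer(charges), mz = mz,
      neutral_mass = neutral_mass[[i]], window = window,
      cal_units = cal[["units"]], cal_gl = cal[["g_per_l"]]
    )
  })
  # warn if extraction windows of different isoforms collide at a charge state
  overlap <- panel |>
    dplyr::group_by(.data$charge) |>
    dplyr::summarise(gap = if (dplyr::n() > 1) min(diff(sort(.data$mz))) else Inf,
                     .groups = "drop")
  if (any(overlap$gap < 2 * window)) {
    warning("extraction windows of different isoforms overlap at a shared charge state",
            call. = FALSE)
  }
  class(panel) <- c("blg_panel", class(panel))
  panel
}

#' Convert arbitrary screening units to g/L
#'
#' Linear calibration through the origin using the panel's single-point
#' reference pair for the isoform: `g/L = units * cal_gl / cal_units`.
#'
#' @param units Numeric vector of arb units.
#' @param isoform Isoform label present in the panel.
#' @param panel A [blg_panel()].
#' @return Numeric vector of concentrations in g/L.
#' @examples
#' calibrate_units(80, "B")   # 3.4
#' calibrate_units(180, "A")  # 4.8
#' @export
calibrate_units <- function(units, isoform, panel = blg_panel()) {
  row <- dplyr::filter(tibble::as_tibble(panel), .data$isoform == !!isoform)
  if (nrow(row) == 0L) stop("isoform not in panel: ", isoform, call. = FALSE)
  cal_units <- row$cal_units[1]
  cal_gl <- row$cal_gl[1]
  if (cal_units == 0) stop("calibration units must be nonzero", call. = FALSE)
  units * cal_gl / cal_units
}
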