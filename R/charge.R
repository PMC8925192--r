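# Charge-state arithmetic for intact-protein electrospray envelopes.
# Average proton mass convention: m_p = 1.00728 Da.

PROTON_MASS <- 1.00728

#' m/z of a protonated charge state
#'
#' Computes the m/z at which a neutral protein of average mass `neutral_mass`
#' appears as the \eqn{[M + nH]^{n+}} ion: \eqn{(M + n\,m_p)/n} with proton
#' mass \eqn{m_p = 1.00728} Da.
#'
#' @param neutral_mass Neutral average mass in Da (positive).
#' @param n Charge count (positive integer); vectorised.
#' @return Numeric vector of m/z values (Thomson).
#' @examples
#' mz_for_charge(18361.05, 10:13)
#' @export
mz_for_charge <- function(neutral_mass, n) {
  stopifnot(is.numeric(neutral_mass), all(neutral_mass > 0))
  if (any(n < 1) || any(n != round(n))) {
    stop("charge count `n` must be a positive integer", call. = FALSE)
  }
  (neutral_mass + n * PROTON_MASS) / n
}

#' Deconvolute a neutral mass from observed charge-state peaks
#'
#' Each \eqn{(m/z, n)} pair implies a neutral mass \eqn{n\,(m/z) - n\,m_p};
#' the estimate is their mean, with the maximum absolute per-peak deviation
#' reported as a consistency measure.
#'
#' @param peaks Data frame (or tibble) with columns `mz` and `charge`.
#' @return A one-row tibble with columns `neutral_mass`, `spread`
#'   (max absolute deviation of per-peak masses from the mean) and `n_peaks`.
#' @examples
#' deconvolute_mass(data.frame(mz = c(1828.5, 1662.4, 1523.9), charge = 10:12))
#' @export
deconvolute_mass <- function(peaks) {
  peaks <- tibble::as_tibble(peaks)
  if (nrow(peaks) == 0L) stop("at least one (m/z, charge) peak is required", call. = FALSE)
  stopifnot(all(c("mz", "charge") %in% names(peaks)))
  if (any(peaks$charge < 1)) stop("charges must be >= 1", call. = FALSE)
  masses <- peaks$charge * peaks$mz - peaks$charge * PROTON_MASS
  m <- mean(masses)
  tibble::tibble(
    neutral_mass = m,
    spread = max(abs(masses - m)),
    n_peaks = nrow(peaks)
  )
}
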