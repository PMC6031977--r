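#' PSII maximum quantum yield from dark-adapted fluorescence
#'
#' Fv/Fm = (Fm - F0) / Fm, the maximum photochemical quantum yield of
#' photosystem II measured on a dark-adapted sample during a saturating
#' pulse. Dimensionless, in [0, 1]; invariant to rescaling both readings by
#' a common positive factor.
#'
#' @param f0 minimum fluorescence of the dark-adapted sample (relative units).
#' @param fm maximum fluorescence during the saturating pulse; must exceed 0
#'   and be >= \code{f0}.
#' @return numeric vector of yields in [0, 1].
#' @examples
#' maxQuantumYield(f0 = 200, fm = 500)  # 0.6
#' @export
maxQuantumYield <- function(f0, fm) {
  if (any(f0 < 0 | fm < 0, na.rm = TRUE))
    stop("fluorescence readings must be non-negative")
  if (any(fm == 0, na.rm = TRUE))
    stop("undefined yield: fm = 0")
  if (any(f0 > fm, na.rm = TRUE))
    stop("invalid reading: f0 exceeds fm")
  (fm - f0) / fm
}

#' PSII effective quantum yield under ambient light
#'
#' Delta F / Fm' = (Fm' - F0') / Fm', the effective quantum yield of a
#' light-adapted sample during a saturating pulse.
#'
#' @param f0_prime minimum fluorescence of the light-adapted sample.
#' @param fm_prime maximum fluorescence during the saturating pulse; > 0 and
#'   >= \code{f0_prime}.
#' @return numeric vector of yields in [0, 1].
#' @examples
#' effectiveQuantumYield(f0_prime = 300, fm_prime = 400)  # 0.25
#' @export
effectiveQuantumYield <- function(f0_prime, fm_prime) {
  if (any(f0_prime < 0 | fm_prime < 0, na.rm = TRUE))
    stop("fluorescence readings must be non-negative")
  if (any(fm_prime == 0, na.rm = TRUE))
    stop("undefined yield: fm_prime = 0")
  if (any(f0_prime > fm_prime, na.rm = TRUE))
    stop("invalid reading: f0_prime exceeds fm_prime")
  (fm_prime - f0_prime) / fm_prime
}

#' Light attenuation coefficient from an irradiance-depth profile
#'
#' Two estimators are provided. \code{"exponential"} (the default) fits the
#' Beer-Lambert model I(z) = I_s exp(-K z) by least squares of
#' -log(I(z)/I_s) on depth, returning K in 1/m; it recovers the generating
#' coefficient exactly on noise-free log-linear profiles and is unbounded
#' above, consistent with field K values well beyond 1. \code{"literal"}
#' solves the algebraic relation I_d = I_s (1 - K) / K for each subsurface
#' depth, K = I_s / (I_s + I_d), and averages; that form has no depth term
#' and is confined to (0, 1], so it cannot express strong attenuation - it
#' is kept for comparability with monitoring programmes that use it.
#'
#' @param depths numeric vector of depths (m), strictly increasing, first
#'   element 0 (the surface).
#' @param irradiance PAR at each depth (umol photons / m^2 / s), same length.
#' @param method \code{"exponential"} or \code{"literal"}.
#' @return K: 1/m for \code{"exponential"}, dimensionless in (0, 1] for
#'   \code{"literal"}.
#' @examples
#' z <- c(0, 0.5, 1, 1.5, 2)
#' lightAttenuation(z, 1500 * exp(-0.83 * z))            # 0.83
#' lightAttenuation(c(0, 1), c(100, 100), "literal")     # 0.5
#' @export
lightAttenuation <- function(depths, irradiance,
                             method = c("exponential", "literal")) {
  method <- match.arg(method)
  if (length(depths) != length(irradiance))
    stop("depths and irradiance must have the same length")
  if (length(depths) < 2L) stop("need at least two depths")
  if (is.unsorted(depths, strictly = TRUE))
    stop("depths must be strictly increasing")
  if (depths[1L] != 0) stop("first depth must be the surface (0 m)")
  is0 <- irradiance[1L]
  if (is.na(is0) || is0 <= 0) stop("surface irradiance must be positive")
  if (method == "literal") {
    id <- irradiance[-1L]
    if (any(id < 0, na.rm = TRUE)) stop("irradiance must be non-negative")
    mean(is0 / (is0 + id), na.rm = TRUE)
  } else {
    if (any(irradiance <= 0, na.rm = TRUE))
      stop("exponential method needs strictly positive irradiance at all depths")
    y <- -log(irradiance / is0)
    unname(stats::coef(stats::lm(y ~ depths))[2L])
  }
}
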