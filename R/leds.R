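#' Built-in LED bank
#'
#' Sixteen parametric LED emitters modelled as Gaussian mixtures over
#' wavelength, mirroring a programmable light box: LEDs 6, 11 and 16 are warm
#' white (blue pump plus a strong, red-shifted phosphor lobe), 7, 10 and 13
#' neutral white, 1 and 4 cool white (blue pump dominant), and the remaining
#' eight are monochromatic emitters spread across distinct hues. White
#' variants within a class differ slightly in phosphor width/amplitude,
#' standing in for different colour-rendering grades. Every LED also carries
#' a small broadband pedestal (1% of its peak) modelling diffuser leakage,
#' which keeps mixed illuminants strictly positive on the whole working grid.
#'
#' @return a list of 16 `led_spec` records with fields `id`, `kind`
#'   (`warm_white`, `neutral_white`, `cool_white`, `monochromatic`) and
#'   `peaks`, a data.frame of Gaussian components (center nm, width nm,
#'   amplitude).
#' @export
builtin_led_bank <- function() {
  white <- function(id, kind, phos_center, phos_width, phos_amp, blue_amp) {
    list(id = id, kind = kind,
         peaks = data.frame(center = c(450, phos_center),
                            width = c(15, phos_width),
                            amplitude = c(blue_amp, phos_amp)))
  }
  mono <- function(id, center, width = 18) {
    list(id = id, kind = "monochromatic",
         peaks = data.frame(center = center, width = width, amplitude = 1))
  }
  bank <- list(
    white(1, "cool_white", 550, 50, 0.55, 1.0),
    mono(2, 420), mono(3, 470),
    white(4, "cool_white", 545, 48, 0.60, 1.0),
    mono(5, 500),
    white(6, "warm_white", 600, 62, 1.30, 0.45),
    white(7, "neutral_white", 570, 55, 0.95, 0.75),
    mono(8, 530), mono(9, 560),
    white(10, "neutral_white", 575, 58, 1.00, 0.70),
    white(11, "warm_white", 605, 65, 1.40, 0.40),
    mono(12, 590),
    white(13, "neutral_white", 565, 52, 0.90, 0.80),
    mono(14, 620), mono(15, 650),
    white(16, "warm_white", 595, 60, 1.25, 0.50)
  )
  lapply(bank, function(l) structure(l, class = "led_spec"))
}

#' Evaluate one LED's spectral power on a wavelength grid
#'
#' Gaussian mixture plus the 1%-of-peak broadband pedestal.
#'
#' @param led an entry of [builtin_led_bank()].
#' @param grid a [wavelength_grid()].
#' @return an [illuminant_spectrum()].
#' @export
led_spectrum <- function(led, grid) {
  lam <- as.numeric(grid)
  p <- numeric(length(lam))
  for (i in seq_len(nrow(led$peaks))) {
    pk <- led$peaks[i, ]
    p <- p + pk$amplitude * exp(-0.5 * ((lam - pk$center) / pk$width)^2)
  }
  p <- p + 0.01 * max(p)
  illuminant_spectrum(p, grid)
}

#' Built-in lighting conditions
#'
#' The sixteen LED combinations used to span realistic illumination: eight
#' single-white conditions (three warm, three neutral, two cool), five
#' binary white-white mixes (7+6, 6+1, 7+1, 7+4, 6+4), two tricolor mixes
#' (7-6-1, 7-6-4), and one eleven-LED multicolor mix
#' (1, 2, 3, 5, 6, 7, 8, 9, 12, 14, 15). Mixing weights default to equal.
#'
#' @return a list of 16 `lighting_condition` records with fields `name`,
#'   `members` (LED ids) and `weights`.
#' @export
builtin_conditions <- function() {
  cond <- function(name, members, weights = rep(1, length(members))) {
    stopifnot(length(members) >= 1, all(weights >= 0))
    structure(list(name = name, members = as.integer(members),
                   weights = weights), class = "lighting_condition")
  }
  list(
    cond("warm_6", 6), cond("warm_11", 11), cond("warm_16", 16),
    cond("neutral_7", 7), cond("neutral_10", 10), cond("neutral_13", 13),
    cond("cool_1", 1), cond("cool_4", 4),
    cond("mix_7_6", c(7, 6)), cond("mix_6_1", c(6, 1)),
    cond("mix_7_1", c(7, 1)), cond("mix_7_4", c(7, 4)),
    cond("mix_6_4", c(6, 4)),
    cond("tri_7_6_1", c(7, 6, 1)), cond("tri_7_6_4", c(7, 6, 4)),
    cond("multi_11", c(1, 2, 3, 5, 6, 7, 8, 9, 12, 14, 15))
  )
}

#' Spectral power distribution of a lighting condition
#'
#' Weighted sum of the member LED spectra, normalized to unit maximum
#' (relative SPD convention used throughout the package).
#'
#' @param condition an entry of [builtin_conditions()].
#' @param bank an LED bank, default [builtin_led_bank()].
#' @param grid a [wavelength_grid()].
#' @return an [illuminant_spectrum()] with maximum 1.
#' @export
condition_spectrum <- function(condition, grid, bank = builtin_led_bank()) {
  ids <- vapply(bank, function(l) as.integer(l$id), integer(1))
  p <- numeric(length(grid))
  for (j in seq_along(condition$members)) {
    led <- bank[[match(condition$members[j], ids)]]
    p <- p + condition$weights[j] * led_spectrum(led, grid)$power
  }
  normalize_unit_max(illuminant_spectrum(p, grid))
}
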