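#' Vacuum permittivity (F/m)
#' @export
EPS0 <- 8.8541878128e-12

#' Default tissue electrical parameter table
#'
#' Conductivity (S/m) and relative permittivity of skin, fat, muscle and
#' skeleton at 1 kHz, 10 kHz, 100 kHz and 1 MHz, after the Gabriel tissue
#' dispersion data as tabulated for the four arm tissues. Values between
#' tabulated frequencies are obtained by log-log linear interpolation
#' ([tissue_properties_at()]).
#'
#' @return Object of class `tissue_properties`: a named list of data frames
#'   with columns `frequency_hz`, `sigma`, `eps_r`.
#' @export
tissue_properties <- function() {
  f <- c(1e3, 1e4, 1e5, 1e6)
  tab <- list(
    skin = data.frame(
      frequency_hz = f,
      sigma = c(2.00e-4, 2.04e-4, 4.51e-4, 1.32e-2),
      eps_r = c(1.14e3, 1.13e3, 1.12e3, 9.91e2)),
    fat = data.frame(
      frequency_hz = f,
      sigma = c(2.24e-2, 2.38e-2, 2.44e-2, 2.51e-2),
      eps_r = c(2.41e4, 1.09e3, 9.29e1, 2.72e1)),
    muscle = data.frame(
      frequency_hz = f,
      sigma = c(3.20e-1, 3.40e-1, 3.60e-1, 5.00e-1),
      eps_r = c(4.30e5, 2.60e4, 8.10e3, 1.80e3)),
    skeleton = data.frame(
      frequency_hz = f,
      sigma = c(2.02e-3, 2.04e-3, 2.08e-3, 2.44e-3),
      eps_r = c(2.70e3, 5.22e2, 2.27e2, 1.45e2))
  )
  validate_tissue_properties(tab)
}

#' @rdname tissue_properties
#' @param tables named list of data frames (`frequency_hz`, `sigma`,
#'   `eps_r`) to use instead of the defaults.
#' @export
validate_tissue_properties <- function(tables) {
  for (nm in names(tables)) {
    t <- tables[[nm]]
    if (!all(c("frequency_hz", "sigma", "eps_r") %in% names(t)))
      stop_arm("tissue '%s': table needs frequency_hz, sigma, eps_r", nm)
    if (is.unsorted(t$frequency_hz, strictly = TRUE))
      stop_arm("tissue '%s': frequencies must be strictly increasing", nm)
    if (any(t$sigma <= 0) || any(t$eps_r <= 0))
      stop_arm("tissue '%s': sigma and eps_r must be positive", nm)
  }
  structure(tables, class = "tissue_properties")
}

#' Tissue conductivity and permittivity at a frequency
#'
#' Returns the tabulated value exactly at tabulated frequencies and the
#' log-log linear interpolation between them. No extrapolation: frequencies
#' outside the table range are an error.
#'
#' @param props a [tissue_properties] table.
#' @param tissue tissue name present in `props`.
#' @param f frequency in Hz.
#' @return Named numeric `c(sigma = , eps_r = )`.
#' @export
tissue_properties_at <- function(props, tissue, f) {
  stopifnot(inherits(props, "tissue_properties"))
  t <- props[[tissue]]
  if (is.null(t)) stop_arm("no properties for tissue '%s'", tissue)
  fr <- t$frequency_hz
  if (f < fr[1] || f > fr[length(fr)])
    stop_arm("frequency %g Hz outside tabulated range [%g, %g] for '%s'",
             f, fr[1], fr[length(fr)], tissue)
  hit <- which(fr == f)
  if (length(hit)) {
    return(c(sigma = t$sigma[hit], eps_r = t$eps_r[hit]))
  }
  i <- findInterval(f, fr)
  w <- (log(f) - log(fr[i])) / (log(fr[i + 1]) - log(fr[i]))
  c(sigma = exp((1 - w) * log(t$sigma[i]) + w * log(t$sigma[i + 1])),
    eps_r = exp((1 - w) * log(t$eps_r[i]) + w * log(t$eps_r[i + 1])))
}
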