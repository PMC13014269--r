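#' Potential of mean force specifications
#'
#' Constructors for the one-dimensional potentials of mean force (PMFs) on the
#' interdye/end-to-end distance coordinate used by [simulate_diffusion_1d()].
#' All free energies are in units of kT, distances in nm.
#'
#' @param r0 Center of the harmonic well (nm).
#' @param k Stiffness of the harmonic well (kT/nm^2).
#' @return An object of class `"potential_spec"`.
#' @examples
#' pot <- potential_harmonic(r0 = 2, k = 4)
#' pot_free_energy(pot, seq(1, 3, by = 0.5))
#' @export
potential_harmonic <- function(r0, k) {
  stop_if(k <= 0, "harmonic stiffness k must be positive")
  structure(list(form = "harmonic", r0 = r0, k = k), class = "potential_spec")
}

#' @rdname potential_harmonic
#' @param r Grid of distances (nm), strictly increasing.
#' @param F Free energies at `r` (kT), finite.
#' @export
potential_tabulated <- function(r, F) {
  stop_if(length(r) != length(F), "r and F must have equal length")
  stop_if(any(diff(r) <= 0), "tabulated grid must be strictly increasing")
  stop_if(any(!is.finite(F)), "tabulated free energies must be finite")
  structure(list(form = "tabulated", r = r, F = F), class = "potential_spec")
}

#' @rdname potential_harmonic
#' @param model A [saw_nu_model()]; the PMF is -log P(r) of its end-to-end
#'   distance distribution.
#' @export
potential_sawnu <- function(model) {
  stopifnot(inherits(model, "saw_nu_model"))
  structure(list(form = "saw_nu_pmf", model = model), class = "potential_spec")
}

#' Evaluate a PMF and its derivative
#'
#' @param pot A `"potential_spec"`.
#' @param r Distances (nm) at which to evaluate.
#' @return Free energy in kT (`pot_free_energy`) or its derivative in kT/nm
#'   (`pot_dFdr`, central differences for tabulated forms).
#' @export
pot_free_energy <- function(pot, r) {
  switch(pot$form,
    harmonic = 0.5 * pot$k * (r - pot$r0)^2,
    tabulated = {
      f <- stats::approx(pot$r, pot$F, xout = r, rule = 2)$y
      f
    },
    saw_nu_pmf = {
      p <- saw_nu_pdf(pot$model, pmax(r, 1e-12))
      -log(pmax(p, 1e-300))
    },
    stop("unknown potential form")
  )
}

#' @rdname pot_free_energy
#' @export
pot_dFdr <- function(pot, r) {
  if (pot$form == "harmonic") return(pot$k * (r - pot$r0))
  h <- 1e-5
  (pot_free_energy(pot, r + h) - pot_free_energy(pot, r - h)) / (2 * h)
}

#' Position-dependent diffusivity specifications
#'
#' Constructors for the diffusion-coefficient profile D(r) used by
#' [simulate_diffusion_1d()]. D must be positive on the whole simulation
#' domain; units nm^2/ns.
#'
#' @param D0 Diffusion coefficient (nm^2/ns); for the linear form, the value
#'   at r = 0.
#' @return An object of class `"diffusion_spec"`.
#' @examples
#' diffusion_constant(0.1)
#' diffusion_linear(0.1, a = 1) # D(r) = 0.1 * (1 + r)
#' @export
diffusion_constant <- function(D0) {
  stop_if(D0 <= 0, "D0 must be positive")
  structure(list(form = "constant", D0 = D0), class = "diffusion_spec")
}

#' @rdname diffusion_constant
#' @param a Slope parameter (1/nm): D(r) = D0 (1 + a r).
#' @export
diffusion_linear <- function(D0, a) {
  stop_if(D0 <= 0, "D0 must be positive")
  structure(list(form = "linear", D0 = D0, a = a), class = "diffusion_spec")
}

#' @rdname diffusion_constant
#' @param r,D Grids of distance (nm) and diffusivity (nm^2/ns).
#' @export
diffusion_tabulated <- function(r, D) {
  stop_if(length(r) != length(D), "r and D must have equal length")
  stop_if(any(diff(r) <= 0), "tabulated grid must be strictly increasing")
  stop_if(any(D <= 0), "D must be positive everywhere")
  structure(list(form = "tabulated", r = r, D = D), class = "diffusion_spec")
}

#' @rdname diffusion_constant
#' @param diff A `"diffusion_spec"`.
#' @param r Distances (nm).
#' @export
diffusion_at <- function(diff, r) {
  switch(diff$form,
    constant = rep(diff$D0, length(r)),
    linear = diff$D0 * (1 + diff$a * r),
    tabulated = stats::approx(diff$r, diff$D, xout = r, rule = 2)$y,
    stop("unknown diffusion form")
  )
}
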