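# Buffer composition: acid/base speciation and the immobilized-water
# hydration index (a dielectric-spectroscopy-derived hydrophilicity proxy).

#' Buffer component
#'
#' @param name Component name.
#' @param mole_fraction Mole fraction of this component among the buffer
#'   species, in [0, 1].
#' @param n_immobilized Number of water molecules immobilized per formula
#'   unit (from dielectric relaxation measurements), `>= 0`.
#' @param pKa Optional acid dissociation constant of the relevant
#'   equilibrium.
#' @return An object of class `"buffer_component"`.
#' @export
buffer_component <- function(name, mole_fraction, n_immobilized,
                             pKa = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(mole_fraction), is.numeric(n_immobilized))
  if (!is.finite(mole_fraction) || mole_fraction < 0 || mole_fraction > 1)
    stop("buffer_component: mole_fraction must lie in [0, 1]")
  if (!is.finite(n_immobilized) || n_immobilized < 0)
    stop("buffer_component: n_immobilized must be >= 0")
  structure(list(name = name, mole_fraction = mole_fraction,
                 n_immobilized = n_immobilized, pKa = pKa),
            class = "buffer_component")
}

#' Buffer specification
#'
#' @param label Buffer label (e.g. `"NaP"`, `"NaAc"`).
#' @param components List of [buffer_component()]s; mole fractions must sum
#'   to 1 within 1e-9.
#' @param total_conc_mM Total buffer concentration (mM).
#' @param pH Buffer pH.
#' @return An object of class `"buffer_spec"`.
#' @export
buffer_spec <- function(label, components, total_conc_mM = NA_real_,
                        pH = NA_real_) {
  stopifnot(is.character(label), is.list(components),
            length(components) >= 1L)
  if (!all(vapply(components, inherits, TRUE, "buffer_component")))
    stop("buffer_spec: components must be buffer_component objects")
  xsum <- sum(vapply(components, function(k) k$mole_fraction, 1))
  if (abs(xsum - 1) > 1e-9)
    stop("buffer_spec: component mole fractions must sum to 1 (got ",
         format(xsum), ")")
  structure(list(label = label, components = components,
                 total_conc_mM = total_conc_mM, pH = pH),
            class = "buffer_spec")
}

#' @export
print.buffer_spec <- function(x, ...) {
  cat(sprintf("Buffer %s (%g mM, pH %g):\n", x$label, x$total_conc_mM, x$pH))
  for (k in x$components)
    cat(sprintf("  x = %.3g  %s (%g immobilized waters)\n",
                k$mole_fraction, k$name, k$n_immobilized))
  invisible(x)
}

#' Sodium phosphate buffer at pH 6 (as used for the folded state)
#'
#' 20 mM NaH2PO4/Na2HPO4 at pH 6: mole fractions ~0.9 monosodium dihydrogen
#' phosphate (4 immobilized waters) and ~0.1 disodium hydrogen phosphate
#' (11 immobilized waters); second phosphate pKa 7.21.
#'
#' @param total_conc_mM Total concentration (mM).
#' @return A [buffer_spec()].
#' @export
nap_buffer <- function(total_conc_mM = 20) {
  buffer_spec("NaP", list(
    buffer_component("NaH2PO4", 0.9, 4, pKa = 7.21),
    buffer_component("Na2HPO4", 0.1, 11, pKa = 7.21)),
    total_conc_mM = total_conc_mM, pH = 6)
}

#' Sodium acetate buffer at pH 4 (as used for the molten-globule state)
#'
#' Acetate buffer at pH 4: mole fractions ~0.2 sodium acetate (5 immobilized
#' waters) and ~0.8 acetic acid (1 immobilized water); acetic acid pKa 4.76.
#'
#' @param total_conc_mM Total concentration (mM).
#' @return A [buffer_spec()].
#' @export
naac_buffer <- function(total_conc_mM = 20) {
  buffer_spec("NaAc", list(
    buffer_component("sodium acetate", 0.2, 5, pKa = 4.76),
    buffer_component("acetic acid", 0.8, 1, pKa = 4.76)),
    total_conc_mM = total_conc_mM, pH = 4)
}

#' Acid/base speciation of a monoprotic equilibrium
#'
#' Henderson-Hasselbalch mole fractions of the protonated (acid) and
#' deprotonated (base) forms: `fraction_acid = 1 / (1 + 10^(pH - pKa))`;
#' the two fractions sum to 1 exactly.
#'
#' @param pH Solution pH.
#' @param pKa Acid dissociation constant.
#' @return Named numeric vector `c(fraction_acid, fraction_base)`.
#' @examples
#' speciation(pH = 6, pKa = 7.21)  # phosphate: ~0.94 H2PO4-
#' @export
speciation <- function(pH, pKa) {
  stopifnot(is.numeric(pH), is.numeric(pKa))
  fa <- 1 / (1 + 10^(pH - pKa))
  c(fraction_acid = fa, fraction_base = 1 - fa)
}

#' Immobilized-water hydration index of a buffer
#'
#' Mole-fraction-weighted mean number of immobilized water molecules over
#' the buffer components, `sum(x_i * n_i)`. A larger index indicates a more
#' strongly hydrated (more kosmotropic / hydrophilic) buffer.
#'
#' Note: for the pH 6 phosphate composition (x = 0.9 with 4 waters, x = 0.1
#' with 11) this weighting gives 4.7; see the package vignette for a
#' discussion of this value.
#'
#' @param spec A [buffer_spec()].
#' @return Immobilized water count (molecules).
#' @examples
#' hydration_index(naac_buffer())  # 0.2*5 + 0.8*1 = 1.8
#' @export
hydration_index <- function(spec) {
  stopifnot(inherits(spec, "buffer_spec"))
  sum(vapply(spec$components,
             function(k) k$mole_fraction * k$n_immobilized, 1))
}
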