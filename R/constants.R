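#' Physical constants for electrophysiology calculations
#'
#' Bundles the thermal voltage RT/F and the liquid-junction (LJ) potential
#' used throughout the package. RT/F collapses the gas constant, absolute
#' temperature and Faraday's constant into a single voltage; the default of
#' 25.5 mV corresponds to roughly 23 degrees C (oocyte recordings at room
#' temperature). The LJ potential is the offset at the pipette/bath
#' interface, stored with the bath-positive sign convention.
#'
#' @param rt_over_f Thermal voltage RT/F in millivolts. Must be positive.
#' @param lj_potential Liquid-junction potential in millivolts (bath
#'   positive). Subtracted from the nominal holding potential to obtain the
#'   effective trans-patch potential.
#' @return An object of class `phys_constants`.
#' @examples
#' pc <- phys_constants()
#' nernst_potential(-1, 104, 5, pc)  # Cl- equilibrium potential, approx -77.4
#' @export
phys_constants <- function(rt_over_f = 25.5, lj_potential = 12) {
  stopifnot(is.numeric(rt_over_f), length(rt_over_f) == 1L, rt_over_f > 0,
            is.numeric(lj_potential), length(lj_potential) == 1L)
  structure(list(rt_over_f = rt_over_f, lj_potential = lj_potential),
            class = "phys_constants")
}

#' @export
print.phys_constants <- function(x, ...) {
  cat("Physical constants: RT/F =", x$rt_over_f, "mV; LJ =",
      x$lj_potential, "mV (bath positive)\n")
  invisible(x)
}

#' Bath and pipette solution composition
#'
#' A named ionic composition in mM. Total chloride is stored explicitly
#' (derived once from the salt recipe) rather than recomputed at use time.
#'
#' @param name Solution name.
#' @param ion_mM Named numeric vector of ion concentrations in mM. Allowed
#'   names: Na, K, NMDG, Cl, Ca, Mg, Ba. All values must be non-negative.
#' @return An object of class `solution`.
#' @export
solution <- function(name, ion_mM) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  allowed <- c("Na", "K", "NMDG", "Cl", "Ca", "Mg", "Ba")
  if (is.null(names(ion_mM)) || !all(names(ion_mM) %in% allowed))
    stop("ion_mM must be named with species among: ",
         paste(allowed, collapse = ", "))
  if (any(ion_mM < 0)) stop("ion concentrations must be >= 0")
  structure(list(name = name, ion_mM = ion_mM), class = "solution")
}

#' Built-in solution presets
#'
#' Compositions of the standard oocyte bath and pipette solutions. Chloride
#' totals are pre-computed from the salt recipes (e.g. modified ND96:
#' 96 NaCl + 4 KCl + 1 CaCl2 + 1 MgCl2 gives 104 mM Cl-).
#'
#' @param name One of `"nd96"`, `"nd9"`, `"nmdg_cl"`, `"modified_nd96"`,
#'   `"k_gluconate_pipette"`, `"divalent_free"`.
#' @return A [solution()].
#' @export
solution_preset <- function(name = c("nd96", "nd9", "nmdg_cl",
                                     "modified_nd96", "k_gluconate_pipette",
                                     "divalent_free")) {
  name <- match.arg(name)
  switch(name,
    # 96 NaCl, 2 KCl, 1.8 CaCl2, 1 MgCl2: Cl = 96 + 2 + 3.6 + 2 = 103.6
    nd96 = solution("ND96", c(Na = 96, K = 2, Ca = 1.8, Mg = 1, Cl = 103.6)),
    # low-sodium storage: 9 NaCl, 2 KCl, 87 NMDG-Cl, 1.8 CaCl2, 1 MgCl2
    nd9 = solution("ND9", c(Na = 9, K = 2, NMDG = 87, Ca = 1.8, Mg = 1,
                            Cl = 103.6)),
    # 95 NMDG-Cl, 1 NaCl, 2 KCl, 1.8 CaCl2, 1 MgCl2
    nmdg_cl = solution("NMDG-Cl", c(Na = 1, K = 2, NMDG = 95, Ca = 1.8,
                                    Mg = 1, Cl = 103.6)),
    # single-channel bath: 96 NaCl, 4 KCl, 1 CaCl2, 1 MgCl2: Cl = 104
    modified_nd96 = solution("modified ND96",
                             c(Na = 96, K = 4, Ca = 1, Mg = 1, Cl = 104)),
    # 90 K-gluconate, 5 NaCl: Cl = 5
    k_gluconate_pipette = solution("K-gluconate pipette",
                                   c(K = 90, Na = 5, Cl = 5)),
    # 96 NaCl, 2 KCl, 2 EDTA (no divalents): Cl = 98
    divalent_free = solution("divalent-free ND96",
                             c(Na = 96, K = 2, Ca = 0, Mg = 0, Cl = 98))
  )
}

#' Nernst equilibrium potential
#'
#' E = (RT/zF) * ln(c_out / c_in), returned in millivolts.
#'
#' @param z Integer valence (non-zero).
#' @param c_out,c_in Extracellular / intracellular concentration in mM,
#'   both strictly positive.
#' @param constants A [phys_constants()] object.
#' @return Equilibrium potential in mV.
#' @examples
#' nernst_potential(-1, 104, 5)  # -77.4 mV
#' nernst_potential(+1, 4, 90)   # -79.4 mV
#' @export
nernst_potential <- function(z, c_out, c_in, constants = phys_constants()) {
  if (!is.numeric(z) || z == 0 || z != round(z))
    stop("valence z must be a non-zero integer")
  if (c_out <= 0 || c_in <= 0)
    stop("concentrations must be strictly positive")
  (constants$rt_over_f / z) * log(c_out / c_in)
}

#' Effective trans-patch potential after liquid-junction correction
#'
#' With a bath-positive LJ potential the true potential across the patch is
#' more negative than the nominal holding potential: V_eff = V_hold - LJ.
#'
#' @param holding Nominal holding potential in mV.
#' @param constants A [phys_constants()] object.
#' @return Effective potential in mV.
#' @examples
#' effective_potential(-70)  # -82 mV with the default 12 mV LJ
#' @export
effective_potential <- function(holding, constants = phys_constants()) {
  holding - constants$lj_potential
}
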