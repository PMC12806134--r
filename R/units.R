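#' Physical constants and unit conversions
#'
#' Internal units are nm (length), ps (time), amu (mass) and elementary
#' charges (e). Energies are kJ/mol, pressures are reported in bar and
#' potentials in mV.
#'
#' @name asymem-units
#' @keywords internal
NULL

# Boltzmann constant, kJ mol^-1 K^-1
.kB <- 0.0083144621

# 1 kJ mol^-1 nm^-3 in bar
.PRESSURE_BAR <- 16.6054

# Avogadro's number, mol^-1
.N_AVOGADRO <- 6.02214076e23

# elementary charge, C
.E_CHARGE <- 1.602176634e-19

# vacuum permittivity, C^2 J^-1 m^-1
.EPS0 <- 8.8541878128e-12

# potential conversion: (e/nm^2) * nm / eps0, expressed in mV.
# sigma[e/nm^2] * d[nm] * .POTENTIAL_MV is the plate-capacitor step.
.POTENTIAL_MV <- .E_CHARGE / (.EPS0 * 1e-9) * 1e3

# 1 bar * nm expressed in mN/m (1e5 Pa * 1e-9 m = 1e-4 N/m)
.TENSION_MN_M <- 0.1
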