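# Internal unit system: nm, ps, kJ/mol, amu, elementary charge, Debye-in/out.
# 1 kJ/mol == 1 amu nm^2 ps^-2, so the equations of motion carry no
# conversion factors.  Conversions happen only at I/O and reporting
# boundaries (atm, V, dyn/cm, A^2, kBT).

.kB        <- 0.0083144621    # Boltzmann constant, kJ/(mol K)
.KE_COUL   <- 138.935458      # 1/(4 pi eps0), kJ nm / (mol e^2)
.DEBYE     <- 0.020819434     # e nm per Debye
.ATM       <- 16.38855        # atm per kJ/(mol nm^3)
.INV_EPS0  <- 18.0951262      # 1/eps0, V nm / e   (eps0 = 0.05526350 e/(V nm))
.DYNCM     <- 1.6605391       # dyn/cm per kJ/(mol nm^2)
.AMU_NM3   <- 1 / 602.214076  # g/cm^3 per amu/nm^3

#' Physical constants used by the package
#'
#' Returns the numerical constants (in the package's internal unit system:
#' nm, ps, kJ/mol, amu, elementary charge) used throughout the force field,
#' engine and analysis code.
#'
#' @return Named list with elements `kB` (kJ/mol/K), `ke` (Coulomb constant,
#'   kJ nm/mol/e^2), `debye` (e nm per Debye), `atm_per_kjmolnm3`,
#'   `inv_eps0` (V nm/e), `dyncm_per_kjmolnm2` and `gcm3_per_amunm3`.
#' @export
elba_constants <- function() {
  list(kB = .kB, ke = .KE_COUL, debye = .DEBYE,
       atm_per_kjmolnm3 = .ATM, inv_eps0 = .INV_EPS0,
       dyncm_per_kjmolnm2 = .DYNCM, gcm3_per_amunm3 = .AMU_NM3)
}
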