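# Nearest-neighbor duplex melting temperature for candidate probes.
#
# Two-state model with the unified DNA/DNA nearest-neighbor parameter set
# (Allawi & SantaLucia 1997) and the SantaLucia-1998 entropic salt correction.
# Divalent cations (minus dNTP chelation) enter as a monovalent equivalent,
# 120*sqrt(mM Mg2+ free). The duplex-concentration term uses the total oligo
# concentration CT directly (probe-in-excess convention: in the depletion
# reaction the probes are in large molar excess over their rRNA targets).

# Unified NN stacks, 5'->3' dinucleotides on the top strand.
# dH in kcal/mol, dS in cal/(mol K).
.NN_DH <- c(
  AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
  CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
  GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
  TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9)
.NN_DS <- c(
  AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
  CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
  GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
  TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2)
# Duplex initiation with a terminal G.C vs terminal A.T pair.
.INIT_GC <- c(dH = 0.1, dS = -2.8)
.INIT_AT <- c(dH = 2.3, dS = 4.1)
.GAS_R <- 1.987  # cal/(mol K)

#' Solution conditions for melting-temperature calculation
#'
#' Defaults mirror the ionic conditions of the rRNA digestion reaction the
#' probes are designed for (about 100 mM K+ and 3 mM free Mg2+ after
#' mixing, 0.25 uM of each probe): a 68 degree threshold is only meaningful
#' on the temperature scale of the reaction the probes must perform in.
#' Tiled 32-mers at bacterial rRNA GC content melt in the mid-60s at plain
#' 50 mM Na+, so the published threshold is not attainable genome-wide
#' under low-salt conditions; use
#' `thermo_params(monovalent_mM = 50, divalent_mM = 0)` to evaluate probes
#' under the low-salt convention instead.
#'
#' @param monovalent_mM monovalent cation concentration (Na+ + K+), mM.
#' @param divalent_mM divalent cation concentration (Mg2+), mM.
#' @param oligo_uM total oligonucleotide concentration, uM.
#' @param dntp_mM dNTP concentration (chelates Mg2+), mM.
#' @return an object of class `thermo_params`.
#' @export
#' @examples
#' thermo_params()
#' thermo_params(monovalent_mM = 50, divalent_mM = 0)
thermo_params <- function(monovalent_mM = 100, divalent_mM = 3,
                          oligo_uM = 0.25, dntp_mM = 0) {
  vals <- c(monovalent_mM, divalent_mM, oligo_uM, dntp_mM)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort_validation("thermo_params: all concentrations must be finite and >= 0")
  }
  if (oligo_uM <= 0) abort_validation("thermo_params: oligo_uM must be > 0")
  mon_eff <- monovalent_mM + 120 * sqrt(max(divalent_mM - dntp_mM, 0))
  if (mon_eff <= 0) {
    abort_validation("thermo_params: no salt correction computable (effective monovalent <= 0)")
  }
  structure(list(monovalent_mM = monovalent_mM, divalent_mM = divalent_mM,
                 oligo_uM = oligo_uM, dntp_mM = dntp_mM),
            class = "thermo_params")
}

# Effective monovalent concentration in mol/L.
effective_monovalent_M <- function(params) {
  (params$monovalent_mM +
     120 * sqrt(max(params$divalent_mM - params$dntp_mM, 0))) / 1000
}

#' Nearest-neighbor melting temperature
#'
#' Computes the two-state duplex melting temperature of each sequence
#' against its exact complement, in degrees Celsius. Deterministic for
#' fixed inputs; vectorised over `sequence`.
#'
#' @param sequence character vector of DNA sequences (strictly A/C/G/T,
#'   length >= 8 each).
#' @param params a [thermo_params()] object.
#' @return numeric vector of melting temperatures (degrees C).
#' @export
#' @examples
#' melting_temperature("ATTGAACGCTGGCGGCAGGCCTAACACATGCA")
melting_temperature <- function(sequence, params = thermo_params()) {
  if (!inherits(params, "thermo_params")) params <- do.call(thermo_params, params)
  if (length(sequence) == 0L) return(numeric(0))
  if (!is.character(sequence)) abort_validation("sequence must be character")
  sequence <- toupper(sequence)
  if (any(nchar(sequence) < 8L)) {
    abort_validation("melting_temperature: sequences shorter than 8 nt are outside the nearest-neighbor model")
  }
  if (!all(is_acgt(sequence))) {
    abort_validation("melting_temperature: sequences must contain only A/C/G/T (no ambiguity codes)")
  }
  mon_M <- effective_monovalent_M(params)
  ct <- params$oligo_uM * 1e-6
  vapply(sequence, function(s) {
    n <- nchar(s)
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    steps <- paste0(b[-n], b[-1])
    dH <- sum(.NN_DH[steps])
    dS <- sum(.NN_DS[steps])
    for (term in b[c(1L, n)]) {
      ini <- if (term %in% c("G", "C")) .INIT_GC else .INIT_AT
      dH <- dH + ini[["dH"]]
      dS <- dS + ini[["dS"]]
    }
    dS_salt <- dS + 0.368 * (n - 1) * log(mon_M)
    dH * 1000 / (dS_salt + .GAS_R * log(ct)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}
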