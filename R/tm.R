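# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K), keyed by the 5'->3' top-strand step.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# Duplex initiation, per terminal base pair.
NN_INIT_DH <- c(G = 0.1, C = 0.1, A = 2.3, T = 2.3)
NN_INIT_DS <- c(G = -2.8, C = -2.8, A = 4.1, T = 4.1)

#' Nearest-neighbor melting temperature of a DNA oligo
#'
#' Duplex Tm from the SantaLucia (1998) unified nearest-neighbor
#' thermodynamics, with entropic salt correction
#' \eqn{\Delta S' = \Delta S + 0.368 \, N_{steps} \, \ln[\mathrm{Na^+}]_{eq}}
#' and divalent cations folded into an equivalent monovalent concentration
#' (\eqn{[\mathrm{Na^+}]_{eq} = [\mathrm{mono}] + 120\sqrt{[\mathrm{Mg^{2+}}]}}
#' in mM). Deterministic; used to hold primers and probes inside their Tm
#' windows during assay design.
#'
#' @param oligo Oligo sequence, 5'->3', A/C/G/T, length >= 8.
#' @param mono_mM Monovalent cation concentration (mM; default 50).
#' @param diva_mM Divalent cation concentration (mM; default 3.8).
#' @param oligo_nM Total single-strand concentration (nM; default 250).
#' @return Melting temperature in degrees Celsius.
#' @examples
#' melting_temperature("ACGTACGTACGTACGTACGT")
#' @export
melting_temperature <- function(oligo, mono_mM = 50, diva_mM = 3.8,
                                oligo_nM = 250) {
  oligo <- toupper(oligo)
  n <- nchar(oligo)
  if (n < 8L) stop("oligo must be at least 8 bases")
  if (!grepl("^[ACGT]+$", oligo))
    stop("oligo contains non-ACGT characters (ambiguous bases not allowed)")
  bases <- strsplit(oligo, "", fixed = TRUE)[[1]]
  steps <- paste0(bases[-n], bases[-1])
  dh <- sum(NN_DH[steps]) + NN_INIT_DH[bases[1]] + NN_INIT_DH[bases[n]]
  ds <- sum(NN_DS[steps]) + NN_INIT_DS[bases[1]] + NN_INIT_DS[bases[n]]
  na_eq <- (mono_mM + 120 * sqrt(max(diva_mM, 0))) / 1000  # molar
  ds_salt <- ds + 0.368 * (n - 1) * log(na_eq)
  ct <- oligo_nM * 1e-9
  # non-self-complementary duplex with strands in equal concentration
  tm_k <- dh * 1000 / (ds_salt + 1.987 * log(ct / 4))
  unname(tm_k - 273.15)
}

gc_fraction <- function(s) {
  n <- nchar(s)
  if (n == 0L) return(NA_real_)
  (n - nchar(gsub("[GC]", "", toupper(s)))) / n
}
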