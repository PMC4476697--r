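# Nearest-neighbor DNA melting temperature (Allawi & SantaLucia 1997 unified
# parameters, entropic monovalent-salt correction). Needed because primer
# picking is implemented in-package rather than delegated to an external
# design tool.

# dH kcal/mol, dS cal/(mol K), 5'->3' top-strand dinucleotides.
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# duplex initiation with a terminal G.C or A.T pair
.NN_INIT_DH <- c(G = 0.1, C = 0.1, A = 2.3, T = 2.3)
.NN_INIT_DS <- c(G = -2.8, C = -2.8, A = 4.1, T = 4.1)

#' Nearest-neighbor melting temperature of a DNA oligo
#'
#' Two-state nearest-neighbor Tm with the Allawi-SantaLucia (1997) unified
#' parameter set and the entropic salt correction
#' `dS' = dS + 0.368 (N-1) ln[Na+]`. The duplex is assumed
#' non-self-complementary, so `Tm = 1000 dH / (dS' + R ln(CT/4)) - 273.15`
#' with `R = 1.9872` cal/(mol K) and `CT` the total oligo concentration.
#' An oligo and its reverse complement describe the same duplex and return
#' identical values.
#'
#' @param seq DNA sequence (A/C/G/T only, length >= 8).
#' @param na_mM Monovalent cation concentration in mM.
#' @param oligo_conc_M Total oligo strand concentration in mol/L.
#' @return Melting temperature in degrees Celsius.
#' @examples
#' melting_temperature("ATAGCCTATCCATTCCTCATGCTTT")
#' @export
melting_temperature <- function(seq, na_mM = 50, oligo_conc_M = 2.5e-7) {
  seq <- .as_dna_string(seq)
  .check_acgt(seq)
  n <- nchar(seq)
  if (n < 8) stop("'seq' must be at least 8 bases for a meaningful duplex Tm",
                  call. = FALSE)
  stopifnot(.is_number(na_mM), na_mM > 0, .is_number(oligo_conc_M), oligo_conc_M > 0)

  dimers <- substring(seq, seq_len(n - 1L), seq_len(n - 1L) + 1L)
  first <- substr(seq, 1L, 1L)
  last <- substr(seq, n, n)
  dh <- sum(.NN_DH[dimers]) + .NN_INIT_DH[[first]] + .NN_INIT_DH[[last]]
  ds <- sum(.NN_DS[dimers]) + .NN_INIT_DS[[first]] + .NN_INIT_DS[[last]]
  ds <- ds + 0.368 * (n - 1L) * log(na_mM / 1000)
  tm_k <- dh * 1000 / (ds + 1.9872 * log(oligo_conc_M / 4))
  unname(tm_k - 273.15)
}
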