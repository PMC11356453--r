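# Packaged synthetic toy references.
#
# These are NOT natural FLS/DFR sequences: they are deterministic random
# backgrounds with every screened feature planted at its canonical
# Arabidopsis-numbered position, so that the whole pipeline (anchoring,
# residue rules, motif scans, typing) can be exercised and validated
# without any downloaded data. Real analyses should substitute genuine
# reference proteins via reference_anchor().

#' Synthetic toy reference proteins
#'
#' Deterministically generated toy references. The FLS toy (300 aa) carries
#' the anchor residue H at position 132, the DHQ-binding residues F134,
#' K202, F293, E295, the 2-ODD fold residues G68, H75, P207, G261, the
#' FLS-specific motifs `PxxxIRxxxEQP` and `SxxTxLVP`, a ferrous-iron
#' binding `HX(D/E)XnH` site and a C-terminal `RXS` 2-oxoglutarate binding
#' site. The DFR toy (240 aa) carries N at anchor position 133 inside the
#' 26-residue substrate-binding region (positions 131-156).
#'
#' @param family `"FLS"` or `"DFR"`.
#' @return Protein string.
#' @export
toy_reference <- function(family = c("FLS", "DFR")) {
  family <- match.arg(family)
  if (family == "FLS") {
    n <- 300L
    plant <- c(
      "1" = "M",
      "68" = "G", "75" = "H", "207" = "P", "261" = "G",       # 2-ODD fold
      "132" = "H", "134" = "F", "202" = "K", "293" = "F", "295" = "E", # DHQ binding
      "150" = "H", "152" = "D", "220" = "H",                  # Fe binding HxDx{67}H
      "240" = "R", "242" = "S",                               # 2-OG binding RXS
      "170" = "P", "174" = "I", "175" = "R", "179" = "E", "180" = "Q", "181" = "P",
      "185" = "S", "188" = "T", "190" = "L", "191" = "V", "192" = "P"
    )
    seed <- 40132L
  } else {
    n <- 240L
    plant <- c("1" = "M", "133" = "N")
    seed <- 40133L
  }
  bg <- with_seed(seed, sample(AA20, n, replace = TRUE))
  bg[as.integer(names(plant))] <- plant
  paste(bg, collapse = "")
}
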