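# Bundled reference oligos of the mtDNA copy-number assay family this
# package models: three TaqMan-style assays (two in COI, one in ND4), with
# deliberately long primers for NUMT robustness.

#' Bundled reference assay oligos
#'
#' The primer and probe sequences of the porcine mtDNA copy-number assays
#' the package models: forward/reverse primers of 25-26 nt (the 25-30 nt
#' design constraint in action) and 19-21 nt hydrolysis probes. The two COI
#' assays share primers and differ only in probe; each assay is therefore a
#' (primer pair, probe) combination.
#'
#' @return Data frame with columns `assay`, `role`
#'   (`forward`/`reverse`/`probe`), and `sequence`.
#' @examples
#' oligos <- reference_assay_oligos()
#' nchar(oligos$sequence[oligos$role != "probe"]) # all within 25-30
#' @export
reference_assay_oligos <- function() {
  path <- system.file("extdata", "assay_oligos.csv", package = "mitosignal",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
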