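#' FXR half-site consensus
#'
#' The hexamer half-site recognised by one monomer of the FXR/RXR
#' heterodimer, in bracket form. Two copies arranged as an inverted repeat
#' with a 1 bp spacer form the canonical FXRE (IR1).
#' @format Character scalar.
#' @export
fxre_halfsite <- "[GA]GGT[TC]A"

#' Conserved NDRG2 first-intron IR1 element
#'
#' The exact-consensus IR1 element found at comparable first-intron
#' positions of the human, mouse and rat NDRG2 genes. It is its own reverse
#' complement at the pattern level (self-RC), so it reads identically from
#' either strand.
#' @format Character scalar (13 nt).
#' @export
ndrg2_ir1 <- "GGGTTAGTGACCC"

#' Second, human-specific IR1-like element in NDRG2
#'
#' Found just downstream of [ndrg2_ir1] in the human gene only; deviates
#' from the consensus at one position.
#' @format Character scalar (13 nt).
#' @export
ndrg2_ir1_like <- "AGGTTGATGACCC"

#' Reported gene-relative start offsets of the NDRG2 IR1 elements
#'
#' First-intron start positions of the conserved element in human, mouse
#' and rat (+1 = first base of the gene's first exon). Reproducing them
#' requires the circa-2012 genome builds; they are kept as reference values,
#' not as test expectations.
#' @format Named integer vector.
#' @export
ndrg2_ir1_offsets <- c(human = 1560L, mouse = 757L, rat = 1394L)

#' Wild-type NDRG2 response-element reporter insert (66 bp, top strand)
#'
#' The 66 bp fragment from the human NDRG2 first intron cloned into the
#' luciferase reporter: carries the exact-consensus IR1 at 0-based offset 15
#' and the 1-mismatch IR1-like element at offset 32.
#' @format Character scalar (66 nt).
#' @export
ndrg2_re_wt <- "GTACCACACTGGGGAGGGTTAGTGACCCGAGGAGGTTGATGACCCTGGGAGTCTGGGTCTTGGCTC"

#' Mutated NDRG2 response-element reporter insert (66 bp, top strand)
#'
#' The reporter insert with both IR1 sites disrupted; confers only marginal
#' inducibility and contains no IR1 match within a 1-mismatch budget.
#' @format Character scalar (66 nt).
#' @export
ndrg2_re_mut <- "GTACCACACTGGGGACCCTTAGTGAGGGGAGGAGGTTGATGAGGGTGGGAGTCTGGGTCTTGGCTC"

#' IBABP response-element reporter insert (top strand)
#'
#' Top strand of the fragment from the human IBABP (FABP6) promoter carrying
#' two copies of its IR1-type element GGGTGAATAACCT, each one mismatch off
#' the consensus (the cloned duplex with restriction overhangs is 68 bp; the
#' printed top strand is 60 nt).
#' @format Character scalar (60 nt).
#' @export
ibabp_re <- "CCCCAGGGTGAATAACCTCGGGGCTCTGTCCCTCCAATCCCAGGGTGAATAACCTCGGGA"

#' ChIP PCR primer pair for the NDRG2 IR1 locus
#'
#' Forward/reverse primers used to amplify a 196 bp fragment spanning the
#' IR1 site(s) in the human NDRG2 first intron.
#' @format Named character vector with elements `forward` and `reverse`.
#' @export
ndrg2_chip_primers <- c(forward = "GAACTGATGCCCTTGTAGCC",
                        reverse = "CAACGAGGTGAATGACATGG")
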