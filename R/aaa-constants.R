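# Package-wide constants; this file loads before the others.

#' Unified developmental stages, in order
#'
#' The five early developmental stages used to align the four species:
#' early cleavage (EC, ~1-16 cells), late cleavage (LC, ~60 cells), early
#' blastula (EB), late blastula (LB, hatching/mesenchyme blastula) and
#' early gastrula (EG). The ordering EC < LC < EB < LB < EG is relied on
#' throughout the dynamics classifier.
#'
#' @format Character vector of length 5.
#' @export
UNIFIED_STAGES <- c("EC", "LC", "EB", "LB", "EG")

#' Recognized abundance units
#' @format Character vector.
#' @export
EXPRESSION_UNITS <- c("RPM", "FPKM", "TPM", "COUNTS", "UNKNOWN")

#' The four study species
#' @format Character vector.
#' @export
SPECIES_IDS <- c("M. franciscanus", "P. lividus", "L. variegatus",
                 "S. purpuratus")

#' Neurotransmitter systems covered by the gene catalog
#' @format Character vector.
#' @export
NT_SYSTEMS <- c("serotonergic", "dopaminergic", "adrenergic", "cholinergic",
                "GABAergic", "histaminergic", "glutamatergic")

#' Component roles in the gene catalog
#' @format Character vector.
#' @export
GENE_ROLES <- c("synthesis_enzyme", "degradation_enzyme", "receptor",
                "transporter")
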