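# Curated catalog of neurotransmitter-system genes examined in the early
# sea urchin embryo: synthesis/degradation enzymes, receptors, transporters
# across seven systems. Canonical symbols are ASCII; typographic variants
# from the literature (Greek subunit letters, hyphens, spaces) resolve
# through aliases.

#' Normalize a gene symbol for matching
#'
#' Matching is case-insensitive and ignores hyphens, spaces and other
#' punctuation; Greek letters are transliterated (alpha -> a, beta -> b),
#' so `"nAChR α7"`, `"nachr_a7"` and `"NACHRA7"` all normalize alike.
#'
#' @param x Character vector of symbols.
#' @return Normalized character vector.
#' @export
normalize_symbol <- function(x) {
  x <- tolower(x)
  for (sub in list(c("α", "a"), c("β", "b"), c("Α", "a"),
                   c("Β", "b")))
    x <- gsub(sub[1], sub[2], x, fixed = TRUE)
  gsub("[^a-z0-9]", "", x)
}

.catalog_raw <- function() {
  # canonical | aliases (;-separated) | system | role
  txt <- '
TPH|TPH1;TPH1 isoform X2|serotonergic|synthesis_enzyme
AADC|DDC|serotonergic|synthesis_enzyme
MAOA|MAO|serotonergic|degradation_enzyme
HTR1A|5-HT1A|serotonergic|receptor
HTR1B|5-HT1B|serotonergic|receptor
HTR1D|5-HT1D|serotonergic|receptor
HTR1F|5-HT1F|serotonergic|receptor
HTR6|5-HT6|serotonergic|receptor
SERT|SLC6A4|serotonergic|transporter
VMAT2|SLC18A2|serotonergic|transporter
TH||dopaminergic|synthesis_enzyme
PAH||dopaminergic|synthesis_enzyme
COMT||dopaminergic|degradation_enzyme
DRD1|D1;D1-like|dopaminergic|receptor
DRD2|D2|dopaminergic|receptor
DRD3|D3;D3-like|dopaminergic|receptor
DRD4|D4|dopaminergic|receptor
DRD5|D5;D5-like|dopaminergic|receptor
DAT|SLC6A3|dopaminergic|transporter
DBH||adrenergic|synthesis_enzyme
ADRA1A|α1A-adrR;a1A-adrR|adrenergic|receptor
ADRA1B|α1B-adrR|adrenergic|receptor
ADRA1D|α1D-adrR|adrenergic|receptor
ADRA2A|α2A-adrR|adrenergic|receptor
ADRA2B|α2B-adrR|adrenergic|receptor
ADRA2C|α2C-adrR|adrenergic|receptor
ADRB1|β1-adrR|adrenergic|receptor
ADRB2|β2-adrR|adrenergic|receptor
ADRB3|β3-adrR|adrenergic|receptor
NET|SLC6A2|adrenergic|transporter
CHAT|ChAT|cholinergic|synthesis_enzyme
ACHE|AChE|cholinergic|degradation_enzyme
CHRM1|M1-AChR;M1|cholinergic|receptor
CHRM2|M2-AChR;M2|cholinergic|receptor
CHRM3|M3-AChR;M3|cholinergic|receptor
CHRM4|M4-AChR;M4|cholinergic|receptor
CHRM5|M5-AChR;M5|cholinergic|receptor
CHRNA1|nAChR α1|cholinergic|receptor
CHRNA2|nAChR α2|cholinergic|receptor
CHRNA3|nAChR α3|cholinergic|receptor
CHRNA6|nAChR α6|cholinergic|receptor
CHRNA7|nAChR α7|cholinergic|receptor
CHRNA8|nAChR α8|cholinergic|receptor
CHRNA9|nAChR α9|cholinergic|receptor
CHRNA10|nAChR α10|cholinergic|receptor
CHRNB3|nAChR β3|cholinergic|receptor
VACHT|VAChT;SLC18A3|cholinergic|transporter
GAD|GAD1;GAD isoform X2|GABAergic|synthesis_enzyme
GABRA|GABA A|GABAergic|receptor
GABBR1|GABA B1|GABAergic|receptor
GABBR2|GABA B2|GABAergic|receptor
GAT2|GABA transporter 2;SLC6A13|GABAergic|transporter
HDC||histaminergic|synthesis_enzyme
HNMT||histaminergic|degradation_enzyme
DAO||histaminergic|degradation_enzyme
HRH1|H1|histaminergic|receptor
HRH2|H2|histaminergic|receptor
HRH3|H3|histaminergic|receptor
HRH4|H4|histaminergic|receptor
GRM1|Grm1|glutamatergic|receptor
GRM2|Grm2|glutamatergic|receptor
GRM3|Grm3|glutamatergic|receptor
GRM4|Grm4|glutamatergic|receptor
GRM5|Grm5|glutamatergic|receptor
GRM6|Grm6|glutamatergic|receptor
GRM7|Grm7|glutamatergic|receptor
GRM8|Grm8|glutamatergic|receptor
GRIA1|AMPA GluA1|glutamatergic|receptor
GLUR2|GluR2|glutamatergic|receptor
GLUR3|GluR3|glutamatergic|receptor
GRIK|kainate receptor|glutamatergic|receptor
GRIN|NMDA receptor|glutamatergic|receptor
SLC7A11|cystine/glutamate transporter;xCT|glutamatergic|transporter
'
  lines <- strsplit(trimws(txt), "\n")[[1]]
  parts <- strsplit(lines, "|", fixed = TRUE)
  data.frame(
    canonical_symbol = vapply(parts, `[`, "", 1),
    aliases = vapply(parts, `[`, "", 2),
    system = vapply(parts, `[`, "", 3),
    role = vapply(parts, `[`, "", 4),
    stringsAsFactors = FALSE
  )
}

#' Built-in gene catalog
#'
#' One record per neurotransmitter-system gene examined in the early
#' embryos: canonical symbol, semicolon-separated aliases, system and
#' component role (synthesis enzyme, degradation enzyme, receptor,
#' transporter). Isoform labels from the source annotations (e.g.
#' "TPH1 isoform X2") are stored as aliases of the parent gene, not as
#' separate records.
#'
#' @return Data frame with columns `canonical_symbol`, `aliases`,
#'   `system`, `role`.
#' @examples
#' cat <- load_builtin_gene_catalog()
#' subset(cat, system == "serotonergic")$canonical_symbol
#' @export
load_builtin_gene_catalog <- function() {
  df <- .catalog_raw()
  stopifnot(!anyDuplicated(df$canonical_symbol),
            all(df$system %in% NT_SYSTEMS), all(df$role %in% GENE_ROLES))
  df
}

#' Look up a gene symbol in the catalog
#'
#' Resolves canonical symbols and aliases after [normalize_symbol()]
#' normalization.
#'
#' @param symbol A gene symbol or alias.
#' @param catalog Catalog data frame (default: the built-in one).
#' @return One catalog row (data frame), or an error if unresolvable.
#' @examples
#' lookup_gene("MAOA")$role            # degradation_enzyme
#' lookup_gene("nachr_a7")$canonical_symbol
#' @export
lookup_gene <- function(symbol, catalog = load_builtin_gene_catalog()) {
  key <- normalize_symbol(symbol)
  norm_canon <- normalize_symbol(catalog$canonical_symbol)
  i <- match(key, norm_canon)
  if (is.na(i)) {
    alias_lists <- strsplit(catalog$aliases, ";", fixed = TRUE)
    for (j in seq_along(alias_lists)) {
      al <- alias_lists[[j]]
      if (length(al) && any(normalize_symbol(al) == key, na.rm = TRUE)) {
        i <- j; break
      }
    }
  }
  if (is.na(i)) stop("gene symbol not in catalog: ", symbol, call. = FALSE)
  catalog[i, , drop = FALSE]
}
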