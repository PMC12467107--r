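# Built-in reference tables: sampling-stage map and the per-stage geometric
# mean of the three housekeeping genes (GHG) for the four study species.
# "ND" cells (no data) are NA here and stay missing everywhere downstream.

# native stage label and hpf per (species, unified stage); NA = ND
.stage_map_data <- local({
  rows <- list(
    list("M. franciscanus", c("Egg", "7 hpf", NA, "16 hpf", "29 hpf"),
         c(0, 7, NA, 16, 29)),
    list("P. lividus", c("Egg", NA, "12 hpf", "18 hpf", "24 hpf"),
         c(0, NA, 12, 18, 24)),
    list("L. variegatus", c("1 hpf", "2.5 hpf", "4 hpf", "7 hpf", "12 hpf"),
         c(1, 2.5, 4, 7, 12)),
    list("S. purpuratus", c("Egg", "10 hpf", "18 hpf", "24 hpf", "30 hpf"),
         c(0, 10, 18, 24, 30))
  )
  do.call(rbind, lapply(rows, function(r) {
    data.frame(species = r[[1]], unified_stage = UNIFIED_STAGES,
               native_label = r[[2]], hpf = r[[3]],
               available = !is.na(r[[2]]), stringsAsFactors = FALSE)
  }))
})

.ghg_reference_data <- local({
  m <- rbind(
    "M. franciscanus" = c(559.068, 2711.161, NA, 1443.028, 2004.563),
    "P. lividus"      = c(97.394, NA, 108.306, 91.15, 99.959),
    "L. variegatus"   = c(4056.580, 5140.630, 4184.16, 4166.32, 7714.20),
    "S. purpuratus"   = c(1388.124, 5121.778, 4838.051, 6287.357, 7629.709)
  )
  colnames(m) <- UNIFIED_STAGES
  m
})

.match_species <- function(species) {
  norm <- function(s) gsub("[^a-z]", "", tolower(s))
  i <- match(norm(species), norm(SPECIES_IDS))
  if (is.na(i))
    stop("unknown species '", species, "'; supported: ",
         paste(SPECIES_IDS, collapse = ", "), call. = FALSE)
  SPECIES_IDS[i]
}

#' Built-in developmental stage map for the four study species
#'
#' Returns the sampling-stage correspondence for one species: which native
#' stage label (and hours post fertilization) was sampled at each unified
#' stage EC/LC/EB/LB/EG. Two cells have no data (ND): EB for
#' *M. franciscanus* and LC for *P. lividus*; these rows carry
#' `available = FALSE` and propagate as missing through harmonization.
#'
#' @param species One of `"M. franciscanus"`, `"P. lividus"`,
#'   `"L. variegatus"`, `"S. purpuratus"` (matching is punctuation- and
#'   case-insensitive).
#' @return A `stage_map` data frame with columns `species`,
#'   `unified_stage`, `native_label`, `hpf`, `available`.
#' @examples
#' load_builtin_stage_map("M. franciscanus")
#' @export
load_builtin_stage_map <- function(species) {
  sp <- .match_species(species)
  out <- .stage_map_data[.stage_map_data$species == sp, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("stage_map", "data.frame")
  out
}

#' Make a stage map from native labels
#'
#' Builds a `stage_map` for arbitrary (e.g. synthetic) data. Each unified
#' stage may appear at most once; omitted unified stages are marked
#' unavailable.
#'
#' @param species Species identifier.
#' @param native_labels Named character vector: names are unified stages
#'   (subset of [UNIFIED_STAGES]), values the native column labels.
#' @param hpf Optional named numeric vector of hours post fertilization,
#'   same names.
#' @return A `stage_map` data frame.
#' @export
stage_map <- function(species, native_labels, hpf = NULL) {
  if (is.null(names(native_labels)) ||
      !all(names(native_labels) %in% UNIFIED_STAGES))
    stop("`native_labels` must be named by unified stages (",
         paste(UNIFIED_STAGES, collapse = ", "), ")", call. = FALSE)
  if (anyDuplicated(names(native_labels)))
    stop("each unified stage may appear at most once", call. = FALSE)
  out <- data.frame(
    species = species, unified_stage = UNIFIED_STAGES,
    native_label = native_labels[UNIFIED_STAGES],
    hpf = if (is.null(hpf)) NA_real_ else unname(hpf[UNIFIED_STAGES]),
    stringsAsFactors = FALSE
  )
  out$available <- !is.na(out$native_label)
  rownames(out) <- NULL
  class(out) <- c("stage_map", "data.frame")
  out
}

#' Built-in GHG reference values
#'
#' The per-stage geometric mean of the three housekeeping genes (GAPDH,
#' ODC, HPRT) used as the normalization denominator, for each species and
#' unified stage, in the source dataset's own unit. 18 cells carry values;
#' the two ND cells (*M. franciscanus* EB, *P. lividus* LC) are `NA`.
#'
#' @return Numeric matrix, species x unified stage, with `NA` for ND.
#' @examples
#' load_builtin_ghg_reference()["M. franciscanus", "EC"]  # 559.068
#' @export
load_builtin_ghg_reference <- function() .ghg_reference_data

#' Published NRPM anchor values
#'
#' Per-gene NRPM values (unit: GHG multiples) reported in the comparative
#' analysis, each tied to a species and the unified stage it was reported
#' at. Used for round-trip fixtures: a raw abundance constructed as
#' `nrpm * GHG(species, stage)` must normalize back to the printed value.
#'
#' @return Data frame with columns `gene`, `species`, `stage`, `nrpm`.
#' @export
published_nrpm_anchors <- function() {
  df <- read.csv(text = '
gene,species,stage,nrpm
GABBR1,M. franciscanus,EC,1.778
GABBR2,M. franciscanus,EC,0.829
CHRNB3,M. franciscanus,EC,2.9
CHRNA2,M. franciscanus,EC,38
CHRNA3,M. franciscanus,EC,5203
CHRNA7,M. franciscanus,EC,0.035
CHRNA10,M. franciscanus,EC,1167
TPH,S. purpuratus,LC,0.22
HDC,S. purpuratus,LC,1.78
HRH3,S. purpuratus,EC,0.483
HRH2,M. franciscanus,EC,0.377
HRH1,S. purpuratus,EC,0.0447
GABBR1,S. purpuratus,EC,0.4373
GAT2,M. franciscanus,EC,1.15
GAT2,L. variegatus,EC,0.45
', stringsAsFactors = FALSE)
  df$gene <- trimws(df$gene)
  df
}
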