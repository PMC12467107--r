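#' Default expression thresholds
#'
#' The presence/absence threshold: roughly 300 transcripts per embryo,
#' approximately FPKM 5 in the reference dataset, corresponding to about
#' 0.003 GHG multiples after normalization. A transcript at or above
#' `nrpm` is called EXPRESSED; below it, NEGLIGIBLE.
#'
#' @param abs_transcripts_per_embryo Absolute threshold, transcripts per
#'   embryo (default 300).
#' @param fpkm_equivalent Approximate source-unit equivalent (default 5).
#' @param nrpm Normalized threshold in GHG multiples (default 0.003).
#' @return A list of class `nrpm_thresholds`.
#' @export
default_thresholds <- function(abs_transcripts_per_embryo = 300,
                               fpkm_equivalent = 5, nrpm = 0.003) {
  stopifnot(abs_transcripts_per_embryo > 0, fpkm_equivalent > 0, nrpm > 0)
  structure(list(abs_transcripts_per_embryo = abs_transcripts_per_embryo,
                 fpkm_equivalent = fpkm_equivalent, nrpm = nrpm),
            class = "nrpm_thresholds")
}

#' Compute the per-stage geometric mean of housekeeping genes (GHG)
#'
#' The normalization denominator: at each stage, the geometric mean of the
#' housekeeping genes' abundances, computed in log space
#' (`exp(mean(log(x)))`) for overflow safety. A stage where any
#' housekeeping gene is missing or non-positive is excluded from the
#' profile (with a warning) rather than failing the run, mirroring how ND
#' stages are handled.
#'
#' @param table An [expression_table()].
#' @param hkgs Character vector of housekeeping gene symbols, length >= 2
#'   (default GAPDH, ODC, HPRT). Matched case-insensitively via
#'   [normalize_symbol()].
#' @return An object of class `ghg_profile`: list with `species`,
#'   `values` (named per-stage positive numeric), `hkgs`,
#'   `excluded_stages`.
#' @examples
#' m <- matrix(c(2, 4, 8), 3, 1, dimnames = list(c("GAPDH","ODC","HPRT"), "EC"))
#' compute_ghg(expression_table(m, "demo", "RPM"))$values  # 4
#' @export
compute_ghg <- function(table, hkgs = c("GAPDH", "ODC", "HPRT")) {
  stopifnot(inherits(table, "expression_table"))
  if (length(hkgs) < 2) stop("need >= 2 housekeeping genes", call. = FALSE)
  idx <- match(normalize_symbol(hkgs), normalize_symbol(rownames(table$values)))
  if (anyNA(idx))
    stop("housekeeping gene(s) absent from table: ",
         paste(hkgs[is.na(idx)], collapse = ", "), call. = FALSE)
  h <- table$values[idx, , drop = FALSE]
  usable <- apply(h, 2, function(col) all(!is.na(col) & col > 0))
  excluded <- colnames(h)[!usable]
  if (length(excluded) > 0)
    warning("stage(s) excluded from GHG (housekeeping gene missing or <= 0): ",
            paste(excluded, collapse = ", "), call. = FALSE)
  if (!any(usable))
    stop("no stage has all housekeeping genes present and positive",
         call. = FALSE)
  vals <- apply(h[, usable, drop = FALSE], 2, function(col) exp(mean(log(col))))
  structure(list(species = table$species, values = vals, hkgs = hkgs,
                 excluded_stages = excluded),
            class = "ghg_profile")
}

#' @export
print.ghg_profile <- function(x, ...) {
  cat(sprintf("<ghg_profile> %s (HKGs: %s)\n", x$species,
              paste(x$hkgs, collapse = ", ")))
  print(round(x$values, 3))
  invisible(x)
}

#' Normalize an expression table to NRPM (GHG multiples)
#'
#' Divides every value by the stage's GHG. The resulting unit,
#' "GHG multiples", is comparable across datasets quantified in RPM, FPKM
#' or TPM, because any per-stage library-size factor cancels in the ratio.
#' Stages without a GHG value (ND or excluded) become all-MISSING.
#'
#' @param table An [expression_table()].
#' @param ghg A `ghg_profile` from [compute_ghg()] covering >= 1 stage of
#'   the table.
#' @return An object of class `normalized_profile`: list with `species`,
#'   `nrpm` (gene x stage matrix, `NA` where missing), `calls` (character
#'   matrix, initially MISSING where undefined, `NA` elsewhere until
#'   [call_expression()] fills it), `unit = "GHG multiples"`.
#' @export
normalize_to_nrpm <- function(table, ghg) {
  stopifnot(inherits(table, "expression_table"), inherits(ghg, "ghg_profile"))
  stages <- colnames(table$values)
  covered <- stages %in% names(ghg$values)
  if (!any(covered))
    stop("GHG profile covers no stage of the table", call. = FALSE)
  nrpm <- table$values
  nrpm[, !covered] <- NA_real_
  for (s in stages[covered]) nrpm[, s] <- table$values[, s] / ghg$values[[s]]
  calls <- matrix(NA_character_, nrow(nrpm), ncol(nrpm), dimnames = dimnames(nrpm))
  calls[is.na(nrpm)] <- "MISSING"
  structure(list(species = table$species, nrpm = nrpm, calls = calls,
                 unit = "GHG multiples"),
            class = "normalized_profile")
}

#' @export
print.normalized_profile <- function(x, ...) {
  cat(sprintf("<normalized_profile> %s: %d genes x %d stages [%s]\n",
              x$species, nrow(x$nrpm), ncol(x$nrpm), x$unit))
  if (!anyNA(x$calls)) {
    tab <- table(factor(x$calls, c("EXPRESSED", "NEGLIGIBLE", "MISSING")))
    cat("calls:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Call transcripts expressed or negligible
#'
#' Fills the calls matrix: EXPRESSED where `nrpm >= threshold` (the
#' boundary value itself is kept), NEGLIGIBLE where `0 <= nrpm <
#' threshold`, MISSING preserved. Idempotent.
#'
#' @param profile A `normalized_profile`.
#' @param thresholds A `nrpm_thresholds` list (default
#'   [default_thresholds()]); only the `nrpm` component is used.
#' @return The profile with `calls` filled.
#' @export
call_expression <- function(profile, thresholds = default_thresholds()) {
  stopifnot(inherits(profile, "normalized_profile"))
  tau <- if (inherits(thresholds, "nrpm_thresholds")) thresholds$nrpm
         else as.numeric(thresholds)
  calls <- ifelse(is.na(profile$nrpm), "MISSING",
                  ifelse(profile$nrpm >= tau, "EXPRESSED", "NEGLIGIBLE"))
  dimnames(calls) <- dimnames(profile$nrpm)
  profile$calls <- calls
  profile$nrpm_threshold <- tau
  profile
}

#' Convert a threshold between scales
#'
#' Pure unit conversion between the three scales the threshold lives on:
#' absolute transcripts per embryo (`ABS_PER_EMBRYO`), the source
#' dataset's unit (`SOURCE_UNIT`), and GHG multiples (`NRPM`).
#' ABS <-> SOURCE uses the calibration factor (source units per transcript
#' per embryo; the reference-dataset equivalence 300 transcripts ~ FPKM 5
#' fixes the default at 1/60). SOURCE <-> NRPM divides/multiplies by the
#' stage GHG. Conversions compose associatively and invert exactly.
#'
#' @param value Positive threshold value on `from_scale`.
#' @param from_scale,to_scale One of `"ABS_PER_EMBRYO"`, `"SOURCE_UNIT"`,
#'   `"NRPM"`.
#' @param ghg_value Positive GHG value (needed when NRPM is involved).
#' @param abs_to_unit_factor Positive calibration, source unit per
#'   transcript-per-embryo (default 1/60).
#' @return The converted value.
#' @examples
#' convert_threshold(300, "ABS_PER_EMBRYO", "SOURCE_UNIT")       # 5
#' convert_threshold(5, "SOURCE_UNIT", "NRPM", ghg_value = 5000) # 0.001
#' @export
convert_threshold <- function(value, from_scale, to_scale, ghg_value = NULL,
                              abs_to_unit_factor = 1 / 60) {
  scales <- c("ABS_PER_EMBRYO", "SOURCE_UNIT", "NRPM")
  from_scale <- match.arg(from_scale, scales)
  to_scale <- match.arg(to_scale, scales)
  if (!is.numeric(value) || value <= 0)
    stop("`value` must be positive", call. = FALSE)
  if (abs_to_unit_factor <= 0)
    stop("`abs_to_unit_factor` must be positive", call. = FALSE)
  needs_ghg <- xor(from_scale == "NRPM", to_scale == "NRPM")
  if (needs_ghg && (is.null(ghg_value) || ghg_value <= 0))
    stop("`ghg_value` must be positive when converting to/from NRPM",
         call. = FALSE)
  # route everything through SOURCE_UNIT
  src <- switch(from_scale,
    ABS_PER_EMBRYO = value * abs_to_unit_factor,
    SOURCE_UNIT = value,
    NRPM = value * ghg_value)
  switch(to_scale,
    ABS_PER_EMBRYO = src / abs_to_unit_factor,
    SOURCE_UNIT = src,
    NRPM = src / ghg_value)
}
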