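#' Re-key a normalized profile onto the unified stage axis
#'
#' Pure re-indexing: each native stage column is placed at its unified
#' stage (EC, LC, EB, LB, EG) per the stage map; unified stages with no
#' data (ND) are present as all-`NA` columns. Values are unchanged.
#'
#' @param profile A `normalized_profile` (native stage columns).
#' @param map A `stage_map` covering every native stage of the profile.
#' @return The profile with columns `UNIFIED_STAGES`, `calls` re-keyed
#'   alike, and `harmonized = TRUE`.
#' @export
harmonize_stages <- function(profile, map) {
  stopifnot(inherits(profile, "normalized_profile"), inherits(map, "stage_map"))
  native <- colnames(profile$nrpm)
  pos <- match(native, map$native_label)
  if (anyNA(pos))
    stop("native stage(s) absent from stage map: ",
         paste(native[is.na(pos)], collapse = ", "), call. = FALSE)
  n_genes <- nrow(profile$nrpm)
  nrpm <- matrix(NA_real_, n_genes, length(UNIFIED_STAGES),
                 dimnames = list(rownames(profile$nrpm), UNIFIED_STAGES))
  calls <- matrix("MISSING", n_genes, length(UNIFIED_STAGES),
                  dimnames = dimnames(nrpm))
  for (k in seq_along(native)) {
    u <- map$unified_stage[pos[k]]
    nrpm[, u] <- profile$nrpm[, k]
    calls[, u] <- profile$calls[, k]
  }
  profile$nrpm <- nrpm
  profile$calls <- calls
  profile$harmonized <- TRUE
  profile
}

# Floored consecutive ratios and their move signs for one trajectory.
# v: non-missing NRPM values in stage order. Returns list(ratios, signs)
# where signs[i] is -1/0/+1 for down-move / no move / up-move.
.trajectory_moves <- function(v, fold_threshold, floor) {
  f <- pmax(v, floor)
  ratios <- f[-1] / f[-length(f)]
  signs <- integer(length(ratios))
  is_move <- abs(log2(ratios)) >= log2(fold_threshold)
  signs[is_move] <- sign(log2(ratios[is_move]))
  list(ratios = ratios, signs = signs)
}

#' Classify one gene's NRPM trajectory across the unified stages
#'
#' Deterministic decision sequence on the non-missing stages, in stage
#' order:
#' \enumerate{
#'   \item all calls NEGLIGIBLE: \code{ABSENT};
#'   \item first EXPRESSED stage at EB or later, with at least one earlier
#'     non-missing stage, all NEGLIGIBLE: \code{LATE_ONSET} (zygotic-only
#'     expression);
#'   \item otherwise from consecutive ratios \eqn{r_i = v_{i+1}/v_i}
#'     (values floored at one tenth of the expression threshold so zeros
#'     give finite ratios): a "move" is \eqn{|log2 r_i| \ge}
#'     \code{log2(fold_threshold)}, ties counting as moves. No moves:
#'     \code{FLAT}; only down-moves: \code{MATERNAL_DECLINE}; a down-move
#'     before the first up-move: \code{U_SHAPED} (maternal decay followed
#'     by zygotic resynthesis); a rise first (up-move before any
#'     down-move), including rise-only profiles already expressed at the
#'     start: \code{PEAK_INTERIOR}.
#' }
#' Classification is scale-free: rescaling the whole trajectory by c > 0
#' while scaling the threshold alike leaves the pattern unchanged.
#'
#' @param values Named numeric vector of NRPM values, names from
#'   [UNIFIED_STAGES] (missing stages `NA` or omitted).
#' @param fold_threshold Minimum fold change counting as a move
#'   (default 2).
#' @param nrpm_threshold Expression threshold in GHG multiples
#'   (default 0.003).
#' @return A one-row data frame: `pattern`, `insufficient_stages`,
#'   `n_stages`, `mzt_upswing`, `mzt_stage`, `max_stage`, `min_stage`,
#'   and `fold_changes` (list column of consecutive ratios).
#' @examples
#' classify_trajectory(c(EC = 1, LC = .5, EB = .25, LB = .12, EG = .06))
#' @export
classify_trajectory <- function(values, fold_threshold = 2,
                                nrpm_threshold = 0.003) {
  stopifnot(fold_threshold > 1, nrpm_threshold > 0)
  stages <- UNIFIED_STAGES[UNIFIED_STAGES %in% names(values)]
  v_all <- values[stages]
  keep <- !is.na(v_all)
  v <- v_all[keep]
  if (length(v) < 1) stop("trajectory has no non-missing stage", call. = FALSE)
  calls <- ifelse(v >= nrpm_threshold, "EXPRESSED", "NEGLIGIBLE")
  insufficient <- length(v) < 3

  mzt <- detect_mzt_upswing(v_all, fold_threshold = fold_threshold)

  pattern <- if (all(calls == "NEGLIGIBLE")) {
    "ABSENT"
  } else {
    first_expr <- names(v)[which(calls == "EXPRESSED")[1]]
    earlier <- seq_len(match(first_expr, names(v)) - 1)
    late_onset <- match(first_expr, UNIFIED_STAGES) >=
      match("EB", UNIFIED_STAGES) &&
      length(earlier) >= 1 && all(calls[earlier] == "NEGLIGIBLE")
    if (late_onset) {
      "LATE_ONSET"
    } else {
      mv <- .trajectory_moves(v, fold_threshold, nrpm_threshold / 10)
      s <- mv$signs[mv$signs != 0]
      if (length(s) == 0) "FLAT"
      else if (all(s < 0)) "MATERNAL_DECLINE"
      else if (s[1] < 0) "U_SHAPED"
      else "PEAK_INTERIOR"
    }
  }

  ratios <- if (length(v) >= 2)
    .trajectory_moves(v, fold_threshold, nrpm_threshold / 10)$ratios
  else numeric(0)
  out <- data.frame(pattern = pattern, insufficient_stages = insufficient,
                    n_stages = length(v),
                    mzt_upswing = isTRUE(mzt$flag),
                    mzt_stage = if (isTRUE(mzt$flag)) mzt$stage else NA_character_,
                    max_stage = names(v)[which.max(v)],
                    min_stage = names(v)[which.min(v)],
                    stringsAsFactors = FALSE)
  out$fold_changes <- list(ratios)
  out
}

#' Detect a maternal-to-zygotic-transition upswing
#'
#' Flags a gene whose NRPM at the early or late blastula stage (EB or LB)
#' reaches at least `fold_threshold` times the minimum over all strictly
#' earlier non-missing stages -- the widespread transcript-abundance
#' increase at the blastula stage that marks the major wave of zygotic
#' genome activation. The earliest qualifying stage is reported.
#'
#' @param values Named numeric vector of NRPM values keyed by unified
#'   stage (`NA` = missing).
#' @param fold_threshold Minimum fold increase (default 2); ties count.
#' @return A list: `evaluable` (FALSE when neither EB nor LB has a value
#'   with at least one earlier non-missing stage), `flag`, `stage`
#'   (`"EB"` or `"LB"` or `NA`).
#' @examples
#' detect_mzt_upswing(c(EC = 1, LC = .5, EB = .25, LB = .6, EG = .9))
#' @export
detect_mzt_upswing <- function(values, fold_threshold = 2) {
  v <- values[UNIFIED_STAGES[UNIFIED_STAGES %in% names(values)]]
  evaluable <- FALSE
  for (st in c("EB", "LB")) {
    if (!st %in% names(v) || is.na(v[[st]])) next
    earlier_stages <- UNIFIED_STAGES[seq_len(match(st, UNIFIED_STAGES) - 1)]
    earlier <- v[names(v) %in% earlier_stages]
    earlier <- earlier[!is.na(earlier)]
    if (length(earlier) == 0) next
    evaluable <- TRUE
    if (v[[st]] >= fold_threshold * min(earlier))
      return(list(evaluable = TRUE, flag = TRUE, stage = st))
  }
  list(evaluable = evaluable, flag = FALSE, stage = NA_character_)
}

#' Classify every gene of a harmonized profile
#'
#' Applies [classify_trajectory()] row-wise to a harmonized
#' `normalized_profile`.
#'
#' @param profile A harmonized `normalized_profile`
#'   (see [harmonize_stages()]).
#' @param fold_threshold,nrpm_threshold Passed to [classify_trajectory()].
#' @return Data frame with one row per gene (`gene`, `species`, plus the
#'   [classify_trajectory()] columns).
#' @export
classify_dynamics <- function(profile, fold_threshold = 2,
                              nrpm_threshold = 0.003) {
  stopifnot(inherits(profile, "normalized_profile"), isTRUE(profile$harmonized))
  rows <- lapply(rownames(profile$nrpm), function(g) {
    res <- classify_trajectory(profile$nrpm[g, ], fold_threshold,
                               nrpm_threshold)
    cbind(data.frame(gene = g, species = profile$species,
                     stringsAsFactors = FALSE), res)
  })
  do.call(rbind, rows)
}
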