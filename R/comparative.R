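#' Assemble a cross-species comparison matrix for one system
#'
#' One row per catalog gene of the chosen neurotransmitter system, one
#' entry per species. A species in whose table the gene does not appear
#' gets `data_present = FALSE` (the gene was not detected in that
#' transcriptome); otherwise the entry records whether the gene is ever
#' EXPRESSED in the early window (EC-EG), its dynamics pattern, and its
#' maximum NRPM.
#'
#' @param profiles Named list (by species) of harmonized
#'   `normalized_profile` objects with calls filled.
#' @param dynamics Named list (by species, same names) of
#'   [classify_dynamics()] data frames.
#' @param system One of `r paste(NT_SYSTEMS, collapse = ", ")`.
#' @param catalog Gene catalog (default built-in).
#' @return A `comparison_matrix`: list with `system`, `genes`, `species`,
#'   and `cells`, a data frame with one row per (gene, species):
#'   `gene`, `species`, `data_present`, `ever_expressed`, `pattern`,
#'   `max_nrpm`.
#' @export
build_comparison <- function(profiles, dynamics, system,
                             catalog = load_builtin_gene_catalog()) {
  if (!system %in% NT_SYSTEMS)
    stop("unknown system '", system, "'; expected one of: ",
         paste(NT_SYSTEMS, collapse = ", "), call. = FALSE)
  if (length(profiles) < 2)
    stop("need >= 2 species with data to compare", call. = FALSE)
  stopifnot(!is.null(names(profiles)),
            setequal(names(profiles), names(dynamics)))
  genes <- catalog$canonical_symbol[catalog$system == system]
  cells <- expand.grid(gene = genes, species = names(profiles),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$data_present <- FALSE
  cells$ever_expressed <- NA
  cells$pattern <- NA_character_
  cells$max_nrpm <- NA_real_
  for (i in seq_len(nrow(cells))) {
    sp <- cells$species[i]
    prof <- profiles[[sp]]
    ridx <- match(normalize_symbol(cells$gene[i]),
                  normalize_symbol(rownames(prof$nrpm)))
    if (is.na(ridx)) next
    v <- prof$nrpm[ridx, ]
    cl <- prof$calls[ridx, ]
    if (all(is.na(v))) next
    cells$data_present[i] <- TRUE
    cells$ever_expressed[i] <- any(cl == "EXPRESSED", na.rm = TRUE)
    cells$max_nrpm[i] <- max(v, na.rm = TRUE)
    dyn <- dynamics[[sp]]
    j <- match(normalize_symbol(cells$gene[i]), normalize_symbol(dyn$gene))
    if (!is.na(j)) cells$pattern[i] <- dyn$pattern[j]
  }
  structure(list(system = system, genes = genes, species = names(profiles),
                 cells = cells),
            class = "comparison_matrix")
}

#' @export
print.comparison_matrix <- function(x, ...) {
  cat(sprintf("<comparison_matrix> %s: %d genes x %d species\n",
              x$system, length(x$genes), length(x$species)))
  invisible(x)
}

#' Classify cross-species conservation of expression
#'
#' Pure function of the number of species in which the gene is ever
#' expressed (`n_expressed`) and the number with data (`n_with_data`):
#' \itemize{
#'   \item `NOT_DETECTED`: expressed in none;
#'   \item `CONSERVED_ALL`: expressed in all species with data, requiring
#'     at least 3 (with fewer, "all" is uninformative; configurable via
#'     `min_all`);
#'   \item `SPECIES_SPECIFIC`: expressed in exactly one;
#'   \item `MAJORITY`: anything else.
#' }
#'
#' @param n_expressed Number of species where the gene is ever expressed.
#' @param n_with_data Number of species with data for the gene (>= 1,
#'   >= n_expressed).
#' @param min_all Minimum `n_with_data` for a CONSERVED_ALL call
#'   (default 3).
#' @return Character scalar (vectorized over the inputs).
#' @examples
#' classify_conservation(4, 4)  # CONSERVED_ALL
#' classify_conservation(3, 4)  # MAJORITY
#' classify_conservation(1, 4)  # SPECIES_SPECIFIC
#' @export
classify_conservation <- function(n_expressed, n_with_data, min_all = 3) {
  stopifnot(all(n_with_data >= 1), all(n_expressed >= 0),
            all(n_expressed <= n_with_data))
  out <- rep("MAJORITY", length(n_expressed))
  out[n_expressed == 0] <- "NOT_DETECTED"
  out[n_expressed == n_with_data & n_with_data >= min_all &
        n_expressed > 0] <- "CONSERVED_ALL"
  out[n_expressed == 1 & out == "MAJORITY"] <- "SPECIES_SPECIFIC"
  out
}

#' Summarize conservation for every gene of a comparison matrix
#'
#' @param cm A `comparison_matrix`.
#' @param min_all Passed to [classify_conservation()].
#' @return Data frame: `gene`, `n_expressed`, `n_with_data`, `class`
#'   (`NO_DATA` when no species has the gene).
#' @export
summarize_conservation <- function(cm, min_all = 3) {
  stopifnot(inherits(cm, "comparison_matrix"))
  rows <- lapply(cm$genes, function(g) {
    sub <- cm$cells[cm$cells$gene == g, , drop = FALSE]
    nd <- sum(sub$data_present)
    ne <- sum(sub$ever_expressed, na.rm = TRUE)
    data.frame(gene = g, n_expressed = ne, n_with_data = nd,
               class = if (nd == 0) "NO_DATA"
                       else classify_conservation(ne, nd, min_all),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Render a per-system report and stream plot
#'
#' Produces (a) a machine-readable report: per gene and species the NRPM
#' trajectory over the unified stages, the dynamics pattern and the
#' conservation class; and (b) a stream plot: x = unified stages, one
#' band per gene and species, band half-width proportional to NRPM on a
#' scale shared across the system, missing stages gapped. Since no
#' replicate spread is available, the NRPM value itself is the band
#' half-width.
#'
#' @param cm A `comparison_matrix`.
#' @param profiles The named list of harmonized profiles used to build it.
#' @param log10_scale Plot `log10(1 + NRPM)` band widths instead of
#'   linear NRPM (NRPM spans ~0.003 to >5000, so linear view is dominated
#'   by the top genes).
#' @param path Optional path for the JSON report.
#' @return List with `report` (nested list, JSON-ready) and `plot`
#'   (a ggplot object).
#' @export
render_system_report <- function(cm, profiles, log10_scale = FALSE,
                                 path = NULL) {
  stopifnot(inherits(cm, "comparison_matrix"))
  present <- cm$cells[cm$cells$data_present, , drop = FALSE]
  if (nrow(present) == 0)
    stop("comparison matrix has no data to report", call. = FALSE)
  cons <- summarize_conservation(cm)

  genes_out <- lapply(cm$genes, function(g) {
    per_species <- lapply(cm$species, function(sp) {
      cell <- cm$cells[cm$cells$gene == g & cm$cells$species == sp, ]
      if (!cell$data_present)  # unset fields omitted, not null
        return(list(species = sp, data_present = FALSE))
      prof <- profiles[[sp]]
      ridx <- match(normalize_symbol(g), normalize_symbol(rownames(prof$nrpm)))
      list(species = sp, data_present = TRUE,
           ever_expressed = cell$ever_expressed, pattern = cell$pattern,
           max_nrpm = cell$max_nrpm, nrpm = as.list(prof$nrpm[ridx, ]))
    })
    list(gene = g,
         conservation = cons$class[cons$gene == g],
         n_expressed = cons$n_expressed[cons$gene == g],
         n_with_data = cons$n_with_data[cons$gene == g],
         species = per_species)
  })
  report <- list(system = cm$system, stages = UNIFIED_STAGES,
                 unit = "GHG multiples", genes = genes_out)
  if (!is.null(path))
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null", pretty = TRUE)

  plot_df <- do.call(rbind, lapply(seq_len(nrow(present)), function(i) {
    g <- present$gene[i]; sp <- present$species[i]
    prof <- profiles[[sp]]
    ridx <- match(normalize_symbol(g), normalize_symbol(rownames(prof$nrpm)))
    v <- prof$nrpm[ridx, ]
    data.frame(gene = g, species = sp, stage = names(v),
               stage_idx = match(names(v), UNIFIED_STAGES),
               nrpm = unname(v), stringsAsFactors = FALSE)
  }))
  plot_df$width <- if (log10_scale) log10(1 + plot_df$nrpm) else plot_df$nrpm
  plot_df$band <- paste(plot_df$gene, plot_df$species, sep = " / ")
  p <- ggplot2::ggplot(plot_df,
         ggplot2::aes(x = stage_idx, ymin = -width, ymax = width,
                      fill = gene)) +
    ggplot2::geom_ribbon(alpha = 0.8, na.rm = FALSE) +
    ggplot2::facet_grid(rows = ggplot2::vars(band)) +
    ggplot2::scale_x_continuous(breaks = seq_along(UNIFIED_STAGES),
                                labels = UNIFIED_STAGES) +
    ggplot2::labs(x = "unified stage",
                  y = if (log10_scale) "log10(1 + NRPM)" else "NRPM",
                  title = paste(cm$system, "system")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   strip.text.y = ggplot2::element_text(angle = 0),
                   legend.position = "none")
  list(report = report, plot = p)
}
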