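# Fixtures built in code from the built-in reference tables.

# Expression table for one species whose housekeeping rows reproduce the
# published GHG exactly (all three HKGs set to the GHG value, so their
# geometric mean is that value) and whose gene rows are published NRPM
# anchors times the GHG -- normalization must round-trip to the printed
# value.
make_anchor_table <- function(species) {
  ghg <- load_builtin_ghg_reference()[species, ]
  ghg <- ghg[!is.na(ghg)]
  anchors <- published_nrpm_anchors()
  anchors <- anchors[anchors$species == species, , drop = FALSE]
  hk <- matrix(rep(ghg, each = 3), nrow = 3,
               dimnames = list(c("GAPDH", "ODC", "HPRT"), names(ghg)))
  gene_rows <- t(vapply(seq_len(nrow(anchors)),
                        function(i) anchors$nrpm[i] * ghg,
                        numeric(length(ghg))))
  rownames(gene_rows) <- make.unique(anchors$gene)
  expression_table(rbind(hk, gene_rows), species = species, unit = "RPM")
}

# Random valid expression table with HKG rows, for property tests.
random_table <- function(n_genes = 50, n_stages = 5, seed = 1,
                         species = "random") {
  set.seed(seed)
  stages <- paste0("s", seq_len(n_stages))
  v <- matrix(stats::rlnorm(n_genes * n_stages, 3, 2), n_genes, n_stages,
              dimnames = list(paste0("g", seq_len(n_genes)), stages))
  hk <- matrix(stats::rlnorm(3 * n_stages, 6, 1), 3, n_stages,
               dimnames = list(c("GAPDH", "ODC", "HPRT"), stages))
  expression_table(rbind(hk, v), species = species, unit = "RPM")
}

run_default_simulation <- function(seed = 42, species = "S. purpuratus",
                                   drop_native_stage = NULL) {
  cfg <- generator_config(seed = seed)
  sim <- generate_bulk_dataset(cfg, species)
  tbl <- sim$table
  if (!is.null(drop_native_stage))
    tbl$values <- tbl$values[, colnames(tbl$values) != drop_native_stage]
  prof <- call_expression(normalize_to_nrpm(tbl, compute_ghg(tbl)))
  harm <- harmonize_stages(prof, sim$stage_map)
  dyn <- classify_dynamics(harm)
  truth <- sim$truth[sim$truth$class != "housekeeping", ]
  dyn <- dyn[match(truth$gene, dyn$gene), ]
  list(sim = sim, profile = harm, dynamics = dyn, truth = truth)
}

# Map a dynamics call back onto the generator truth classes.
predicted_class <- function(dyn) {
  ifelse(dyn$pattern == "ABSENT", "absent",
  ifelse(dyn$pattern == "MATERNAL_DECLINE", "maternal",
  ifelse(dyn$pattern == "U_SHAPED", "mixed",
  ifelse(dyn$pattern == "LATE_ONSET" | dyn$mzt_upswing, "zygotic",
         "other"))))
}
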