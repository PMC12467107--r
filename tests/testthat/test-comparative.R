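# Two tiny species profiles over serotonergic genes, harmonized, with
# calls filled; gene sets differ so data_present is exercised.
make_species_profile <- function(species, genes, values) {
  v <- matrix(values, length(genes), 5, byrow = TRUE,
              dimnames = list(genes, UNIFIED_STAGES))
  calls <- ifelse(is.na(v), "MISSING",
                  ifelse(v >= 0.003, "EXPRESSED", "NEGLIGIBLE"))
  structure(list(species = species, nrpm = v, calls = calls,
                 unit = "GHG multiples", harmonized = TRUE),
            class = "normalized_profile")
}

fixture_pair <- function() {
  a <- make_species_profile("sp1", c("MAOA", "HTR6", "SERT"),
                            c(1, .8, .6, .5, .4,
                              1.2, .9, .3, .35, .7,
                              .001, .001, .001, .001, .001))
  b <- make_species_profile("sp2", c("MAOA", "HTR6"),
                            c(2, 1.5, 1, .8, .9,
                              .5, .4, .2, .25, .45))
  profiles <- list(sp1 = a, sp2 = b)
  dynamics <- lapply(profiles, classify_dynamics)
  list(profiles = profiles, dynamics = dynamics)
}

test_that("conservation classes match an exhaustive truth table", {
  # independently enumerated expectation for every (n_expressed,
  # n_with_data) pair with n_with_data <= 4
  truth <- data.frame(
    ne = c(0, 1,
           0, 1, 2,
           0, 1, 2, 3,
           0, 1, 2, 3, 4),
    nd = c(1, 1,
           2, 2, 2,
           3, 3, 3, 3,
           4, 4, 4, 4, 4),
    class = c("NOT_DETECTED", "SPECIES_SPECIFIC",
              "NOT_DETECTED", "SPECIES_SPECIFIC", "MAJORITY",
              "NOT_DETECTED", "SPECIES_SPECIFIC", "MAJORITY",
              "CONSERVED_ALL",
              "NOT_DETECTED", "SPECIES_SPECIFIC", "MAJORITY", "MAJORITY",
              "CONSERVED_ALL"),
    stringsAsFactors = FALSE)
  got <- classify_conservation(truth$ne, truth$nd)
  expect_equal(got, truth$class)
  # the published archetypes: expressed in 4/4 (MAOA-like), 3/4
  # (HTR1B-like), 1/4 (alpha2A-adrenoreceptor-like)
  expect_equal(classify_conservation(4, 4), "CONSERVED_ALL")
  expect_equal(classify_conservation(3, 4), "MAJORITY")
  expect_equal(classify_conservation(1, 4), "SPECIES_SPECIFIC")
  expect_error(classify_conservation(3, 2))
})

test_that("comparison matrix has one row per catalog gene of the system", {
  fx <- fixture_pair()
  cm <- build_comparison(fx$profiles, fx$dynamics, "serotonergic")
  sero <- load_builtin_gene_catalog()
  sero <- sero$canonical_symbol[sero$system == "serotonergic"]
  expect_setequal(cm$genes, sero)
  expect_equal(nrow(cm$cells), length(sero) * 2)

  # gene present in only one species
  sert <- cm$cells[cm$cells$gene == "SERT", ]
  expect_equal(sort(sert$data_present), c(FALSE, TRUE))
  # all-negligible gene has data but is never expressed
  expect_false(sert$ever_expressed[sert$data_present])
  # gene absent from every table
  tph <- cm$cells[cm$cells$gene == "TPH", ]
  expect_true(all(!tph$data_present))

  expect_error(build_comparison(fx$profiles["sp1"], fx$dynamics["sp1"],
                                "serotonergic"), ">= 2")
  expect_error(build_comparison(fx$profiles, fx$dynamics, "xenobiotic"),
               "unknown system")
})

test_that("conservation summary is stable under species permutation", {
  fx <- fixture_pair()
  cm1 <- build_comparison(fx$profiles, fx$dynamics, "serotonergic")
  cm2 <- build_comparison(rev(fx$profiles), rev(fx$dynamics), "serotonergic")
  s1 <- summarize_conservation(cm1)
  s2 <- summarize_conservation(cm2)
  expect_equal(s1[order(s1$gene), ], s2[order(s2$gene), ],
               ignore_attr = TRUE)
})

test_that("system report round-trips through JSON and the plot is structural", {
  fx <- fixture_pair()
  cm <- build_comparison(fx$profiles, fx$dynamics, "serotonergic")
  path <- withr::local_tempfile(fileext = ".json")
  out <- render_system_report(cm, fx$profiles, path = path)

  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$system, "serotonergic")
  expect_equal(unlist(parsed$stages), UNIFIED_STAGES)
  # emit -> parse -> emit is lossless
  tmp2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(parsed, tmp2, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
  expect_identical(jsonlite::read_json(tmp2), parsed)

  # trajectories in the report equal the profile values
  maoa <- Filter(function(g) g$gene == "MAOA", parsed$genes)[[1]]
  sp1 <- Filter(function(s) s$species == "sp1", maoa$species)[[1]]
  expect_equal(unlist(sp1$nrpm), fx$profiles$sp1$nrpm["MAOA", ])

  p <- out$plot
  expect_s3_class(p, "ggplot")
  expect_true(any(vapply(p$layers, function(l)
    inherits(l$geom, "GeomRibbon"), logical(1))))
  built <- ggplot2::ggplot_build(p)
  dat <- built$data[[1]]
  # one band per (gene, species) with data: MAOA x2, HTR6 x2, SERT x1
  expect_equal(length(unique(dat$PANEL)), 5)
  # all-negligible SERT band has (near-)zero width
  expect_error(render_system_report(
    structure(list(system = "serotonergic", genes = character(0),
                   species = character(0),
                   cells = data.frame(gene = character(0),
                                      species = character(0),
                                      data_present = logical(0))),
              class = "comparison_matrix"), fx$profiles),
    "no data")
})
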