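test_that("GHG is the log-space geometric mean of the housekeeping rows", {
  m <- matrix(c(2, 4, 8), 3, 1, dimnames = list(c("GAPDH", "ODC", "HPRT"), "EC"))
  expect_equal(unname(compute_ghg(expression_table(m, "x"))$values), 4)

  for (x in c(0.001, 1, 537.2)) {
    m2 <- matrix(rep(x, 3), 3, 1,
                 dimnames = list(c("GAPDH", "ODC", "HPRT"), "EC"))
    expect_equal(unname(compute_ghg(expression_table(m2, "x"))$values), x)
  }

  # a zero housekeeping value excludes that stage with a warning
  m3 <- matrix(c(5, 0, 7, 2, 4, 8), 3, 2,
               dimnames = list(c("GAPDH", "ODC", "HPRT"), c("EC", "LC")))
  expect_warning(g <- compute_ghg(expression_table(m3, "x")), "excluded")
  expect_equal(g$excluded_stages, "EC")
  expect_equal(names(g$values), "LC")

  expect_error(compute_ghg(random_table(), hkgs = c("GAPDH", "NOPE")),
               "NOPE")
  m4 <- matrix(c(5, 0, 7), 3, 1,
               dimnames = list(c("GAPDH", "ODC", "HPRT"), "EC"))
  expect_error(suppressWarnings(compute_ghg(expression_table(m4, "x"))),
               "no stage")
})

test_that("NRPM is the raw value over the stage GHG, missing where GHG is", {
  tbl <- random_table(seed = 3)
  ghg <- compute_ghg(tbl)
  prof <- normalize_to_nrpm(tbl, ghg)
  expect_equal(prof$unit, "GHG multiples")
  # self-ratio: a gene equal to GHG at a stage has NRPM 1
  g1 <- tbl
  g1$values["g1", ] <- ghg$values[colnames(g1$values)]
  p1 <- normalize_to_nrpm(g1, compute_ghg(g1))
  expect_equal(unname(p1$nrpm["g1", ]), rep(1, 5))
  # zero raw stays zero
  g1$values["g2", 1] <- 0
  expect_equal(unname(normalize_to_nrpm(g1, ghg)$nrpm["g2", 1]), 0)
  # stage without GHG -> all MISSING
  partial <- ghg
  partial$values <- ghg$values[-1]
  pp <- normalize_to_nrpm(tbl, partial)
  expect_true(all(is.na(pp$nrpm[, 1])))
  expect_true(all(pp$calls[, 1] == "MISSING"))
})

test_that("housekeeping self-normalization is the fixed point of NRPM", {
  for (seed in 1:5) {
    tbl <- random_table(seed = seed)
    prof <- normalize_to_nrpm(tbl, compute_ghg(tbl))
    hk <- prof$nrpm[c("GAPDH", "ODC", "HPRT"), ]
    gm <- exp(colMeans(log(hk)))
    expect_true(max(abs(gm - 1)) < 1e-12)
    # GHG lies between the housekeeping extremes at every stage
    g <- compute_ghg(tbl)
    h <- tbl$values[c("GAPDH", "ODC", "HPRT"), ]
    expect_true(all(g$values >= apply(h, 2, min) - 1e-12))
    expect_true(all(g$values <= apply(h, 2, max) + 1e-12))
  }
})

test_that("NRPM is invariant to per-stage rescaling of the whole library", {
  tbl <- random_table(seed = 11)
  ref <- normalize_to_nrpm(tbl, compute_ghg(tbl))$nrpm
  for (c_s in c(0.01, 1, 100)) {
    scaled <- tbl
    scaled$values[, 2] <- scaled$values[, 2] * c_s
    out <- normalize_to_nrpm(scaled, compute_ghg(scaled))$nrpm
    expect_true(max(abs(out - ref)) < 1e-12)
  }
})

test_that("pipeline NRPM equals brute-force per-cell recomputation", {
  for (seed in 1:10) {
    tbl <- random_table(n_genes = 50, n_stages = 5, seed = seed)
    prof <- normalize_to_nrpm(tbl, compute_ghg(tbl))
    v <- tbl$values
    hk <- v[c("GAPDH", "ODC", "HPRT"), ]
    for (s in colnames(v)) {
      denom <- (hk[1, s] * hk[2, s] * hk[3, s])^(1 / 3)
      expect_true(max(abs(prof$nrpm[, s] - v[, s] / denom)) < 1e-12)
    }
  }
})

test_that("expression calls are inclusive at the threshold and monotone", {
  v <- matrix(c(0.0029, 0.003, 0.0031, 0.22, 0, NA), 6, 1,
              dimnames = list(paste0("g", 1:6), "EC"))
  prof <- structure(list(species = "x", nrpm = v,
                         calls = matrix(NA_character_, 6, 1),
                         unit = "GHG multiples"),
                    class = "normalized_profile")
  out <- call_expression(prof)
  expect_equal(unname(out$calls[, 1]),
               c("NEGLIGIBLE", "EXPRESSED", "EXPRESSED", "EXPRESSED",
                 "NEGLIGIBLE", "MISSING"))
  # idempotent
  expect_identical(call_expression(out)$calls, out$calls)
  # monotone: higher nrpm never downgrades the call
  ord <- order(v[1:5, 1])
  codes <- match(out$calls[ord, 1], c("NEGLIGIBLE", "EXPRESSED"))
  expect_true(all(diff(codes) >= 0))
})

test_that("threshold conversion matches the published calibration and inverts", {
  expect_equal(convert_threshold(300, "ABS_PER_EMBRYO", "SOURCE_UNIT"), 5)
  expect_equal(convert_threshold(5, "SOURCE_UNIT", "NRPM",
                                 ghg_value = 1666.667),
               5 / 1666.667)
  x <- 0.003
  back <- convert_threshold(
    convert_threshold(x, "NRPM", "SOURCE_UNIT", ghg_value = 559.068),
    "SOURCE_UNIT", "NRPM", ghg_value = 559.068)
  expect_true(abs(back - x) < 1e-12)
  # composition ABS -> NRPM equals the two-step route
  one <- convert_threshold(300, "ABS_PER_EMBRYO", "NRPM", ghg_value = 1000)
  two <- convert_threshold(
    convert_threshold(300, "ABS_PER_EMBRYO", "SOURCE_UNIT"),
    "SOURCE_UNIT", "NRPM", ghg_value = 1000)
  expect_equal(one, two)
  expect_error(convert_threshold(-1, "NRPM", "SOURCE_UNIT", 10), "positive")
  expect_error(convert_threshold(1, "NRPM", "SOURCE_UNIT", ghg_value = 0),
               "ghg")
})

test_that("published NRPM anchors round-trip through the full pipeline", {
  anchors <- published_nrpm_anchors()
  for (sp in unique(anchors$species)) {
    tbl <- make_anchor_table(sp)
    prof <- call_expression(normalize_to_nrpm(tbl, compute_ghg(tbl)))
    sub <- anchors[anchors$species == sp, ]
    rn <- make.unique(sub$gene)
    for (i in seq_len(nrow(sub))) {
      got <- prof$nrpm[rn[i], sub$stage[i]]
      expect_equal(unname(got), sub$nrpm[i], tolerance = 1e-9)
      expect_true(abs(got - sub$nrpm[i]) < 5e-4)  # 3-decimal agreement
    }
  }
})
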