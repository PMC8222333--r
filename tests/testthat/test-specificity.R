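test_that("lnKA and delta-d reproduce hand-computed log ratios", {
  # bound: variant 50, ref 100; unbound: variant 200, ref 100
  m <- matrix(c(100, 50, 100, 200), 2, 2,
              dimnames = list(c("WT", "v"), NULL))
  fc <- handCounts(m, fraction = c("bound", "unbound"))
  lnka <- computeLnKA(fc, alpha = 1e-9)
  expect_equal(lnka$value[lnka$variant_id == "v"], log(0.25),
               tolerance = 1e-6)
  expect_equal(lnka$value[lnka$variant_id == "WT"], 0)
  # uncut: variant 80, ref 20; input: variant 100, ref 100
  m2 <- matrix(c(100, 100, 20, 80), 2, 2,
               dimnames = list(c("WT", "v"), NULL))
  fc2 <- handCounts(m2, fraction = c("input", "uncut"))
  dd <- computeDeltaD(fc2, alpha = 1e-9)
  expect_equal(dd$value[dd$variant_id == "v"], log(4), tolerance = 1e-6)
  # same ratio as reference -> 0; uncut identical to input -> all zero
  m3 <- matrix(c(100, 60, 50, 30), 2, 2,
               dimnames = list(c("WT", "v"), NULL))
  fc3 <- handCounts(m3, fraction = c("bound", "unbound"))
  expect_equal(computeLnKA(fc3, alpha = 1e-9)$value, c(0, 0),
               tolerance = 1e-6)
  m4 <- matrix(c(100, 60, 100, 60), 2, 2,
               dimnames = list(c("WT", "v"), NULL))
  fc4 <- handCounts(m4, fraction = c("input", "uncut"))
  expect_equal(computeDeltaD(fc4, alpha = 1e-9)$value, c(0, 0),
               tolerance = 1e-6)
  expect_error(computeLnKA(fc, reference = "missing"), "reference")
  expect_error(computeDeltaD(fc), "fraction")
})

test_that("binding matrix fit is exact on noiseless additive data", {
  lib <- enumerateMismatchLibrary("ACGTAC", 4)
  eps <- energyTruth(lib, c(0.9, 0.3, 1.4, 0.7, 0.2, 1.1))
  mm <- parseMismatches(variants(lib)$mismatches)
  E <- vapply(mm, function(d)
    if (nrow(d)) sum(eps[cbind(d$alt, d$position)]) else 0, numeric(1))
  measures <- S4Vectors::DataFrame(
    variant_id = variantIds(lib), kind = "lnKA", value = -E,
    se = rep(1, length(E)), replicate = "1")
  measures$se[measures$variant_id == "WT"] <- 0
  em <- fitBindingEnergyMatrix(measures, lib)
  ok <- penaltyFlags(em) == "ok"
  expect_true(all(ok | penaltyFlags(em) == "ref"))
  expect_lt(max(abs(penalties(em)[ok] - eps[ok])), 1e-8)
  expect_equal(matrixKind(em), "binding")
  # single-mismatch identity: one lnKA of -1.2 maps to a penalty of 1.2
  lib1 <- enumerateMismatchLibrary("ACGTACGT", 1)
  v1 <- variants(lib1)$variant_id[variants(lib1)$n_mismatch == 1][1]
  meas1 <- S4Vectors::DataFrame(
    variant_id = c("WT", v1), kind = "lnKA", value = c(0, -1.2),
    se = c(0, 1), replicate = "1")
  em1 <- fitBindingEnergyMatrix(meas1, lib1)
  expect_equal(penalties(em1)[penaltyFlags(em1) == "ok"], 1.2)
  # everything else is unidentifiable, not zero
  expect_equal(sum(penaltyFlags(em1) == "unidentifiable"), 23L)
  # all-zero measures give an all-zero matrix
  meas0 <- measures; meas0$value <- 0
  em0 <- fitBindingEnergyMatrix(meas0, lib)
  expect_true(all(penalties(em0)[penaltyFlags(em0) == "ok"] == 0))
})

test_that("cleavage model inverts its saturating form exactly on noiseless data", {
  lib <- enumerateMismatchLibrary("ACGTAC", 4)
  eps <- energyTruth(lib, 0.5)
  Ctrue <- 2
  mm <- parseMismatches(variants(lib)$mismatches)
  E <- vapply(mm, function(d)
    if (nrow(d)) sum(eps[cbind(d$alt, d$position)]) else 0, numeric(1))
  measures <- S4Vectors::DataFrame(
    variant_id = variantIds(lib), kind = "delta_d",
    value = Ctrue * (1 - exp(-E)), se = rep(1, length(E)),
    replicate = "1")
  measures$se[measures$variant_id == "WT"] <- 0
  em <- fitCleavagePenaltyModel(measures, lib)
  ok <- penaltyFlags(em) == "ok"
  expect_lt(max(abs(penalties(em)[ok] - eps[ok])), 1e-6)
  expect_lt(abs(saturationScale(em)[[1]] - Ctrue), 1e-6)
  # forward-then-invert check at uniform eps=0.5, C=2: each single mismatch
  # sits at C(1-e^-0.5) ~ 0.787 and round-trips to 0.5 (double mismatches
  # provide the curvature that pins C)
  lib2 <- enumerateMismatchLibrary("ACGTACGT", 2)
  eps2 <- energyTruth(lib2, 0.5); eps2[eps2 > 0] <- 0.5
  mm2 <- parseMismatches(variants(lib2)$mismatches)
  E2 <- vapply(mm2, function(d)
    if (nrow(d)) sum(eps2[cbind(d$alt, d$position)]) else 0, numeric(1))
  expect_equal(unique(round(2 * (1 - exp(-E2[E2 > 0 & E2 < 1])), 3)), 0.787)
  meas2 <- S4Vectors::DataFrame(
    variant_id = variantIds(lib2), kind = "delta_d",
    value = 2 * (1 - exp(-E2)), se = ifelse(E2 == 0, 1, 1), replicate = "1")
  meas2$se[variantIds(lib2) == "WT"] <- 0
  em2 <- fitCleavagePenaltyModel(meas2, lib2)
  ok2 <- penaltyFlags(em2) == "ok"
  expect_equal(unname(penalties(em2)[ok2]), rep(0.5, sum(ok2)),
               tolerance = 1e-6)
  expect_equal(unname(saturationScale(em2)[[1]]), 2, tolerance = 1e-6)
  # all delta_d zero: penalties zero, C reported unidentifiable
  meas0 <- measures; meas0$value <- 0
  em0 <- fitCleavagePenaltyModel(meas0, lib)
  expect_true(all(penalties(em0)[penaltyFlags(em0) == "ok"] == 0))
  expect_true(all(is.na(saturationScale(em0))))
})

test_that("matrix fits are invariant to measure ordering", {
  lib <- enumerateMismatchLibrary("ACGTAC", 3)
  tr <- simTruth(depth = 1e5, seed = 21)
  fc <- simulateSpecSeq(tr, lib)
  m <- computeLnKA(fc)
  em1 <- fitBindingEnergyMatrix(m, lib)
  set.seed(1)
  em2 <- fitBindingEnergyMatrix(m[sample(nrow(m)), ], lib)
  expect_equal(penalties(em1), penalties(em2), tolerance = 1e-10)
})

test_that("probability conversion and logo follow Boltzmann weights", {
  lib <- enumerateMismatchLibrary("ACGTACGT", 1)
  ids <- variants(lib)$variant_id
  meas <- S4Vectors::DataFrame(
    variant_id = ids, kind = "lnKA", value = ifelse(ids == "WT", 0, -1),
    se = ifelse(ids == "WT", 0, 1), replicate = "1")
  em <- fitBindingEnergyMatrix(meas, lib)
  p <- matrixToPwm(em)
  expect_equal(unname(colSums(p)), rep(1, 8), tolerance = 1e-12)
  # eps = (0,1,1,1): reference probability 1/(1+3e^-1)
  expect_equal(max(p[, 1]), 1 / (1 + 3 * exp(-1)), tolerance = 1e-12)
  # all-zero matrix -> uniform
  meas0 <- meas; meas0$value <- 0
  p0 <- matrixToPwm(fitBindingEnergyMatrix(meas0, lib))
  expect_true(all(abs(p0 - 0.25) < 1e-12))
  # saturated entries behave as infinite penalties
  emSat <- em
  fl <- penaltyFlags(emSat); fl[fl == "ok"] <- "saturated"
  emSat@flags <- fl
  pSat <- matrixToPwm(emSat)
  expect_true(all(pSat[penaltyFlags(em) == "ref"] == 1))
  gg <- plotEnergyLogo(em)
  expect_s3_class(gg, "ggplot")
})

test_that("energy matrix comparison reports differences and mean reduction", {
  lib <- enumerateMismatchLibrary("ACGTAC", 2)
  eps <- energyTruth(lib, 1)
  mm <- parseMismatches(variants(lib)$mismatches)
  E <- vapply(mm, function(d)
    if (nrow(d)) sum(eps[cbind(d$alt, d$position)]) else 0, numeric(1))
  mk <- function(scale) {
    meas <- S4Vectors::DataFrame(
      variant_id = variantIds(lib), kind = "lnKA", value = -E * scale,
      se = ifelse(variantIds(lib) == "WT", 0, 1), replicate = "1")
    fitBindingEnergyMatrix(meas, lib)
  }
  A <- mk(1); Bhalf <- mk(0.5)
  same <- compareEnergyMatrices(A, A)
  expect_true(all(same$delta == 0, na.rm = TRUE))
  expect_equal(same$meanReductionPercent, 0)
  halved <- compareEnergyMatrices(A, Bhalf)
  expect_equal(halved$meanReductionPercent, 50, tolerance = 1e-6)
  expect_error(compareEnergyMatrices(A, fitCleavagePenaltyModel(
    S4Vectors::DataFrame(variant_id = variantIds(lib), kind = "delta_d",
                         value = 0 * E, se = ifelse(variantIds(lib) == "WT", 0, 1),
                         replicate = "1"), lib)), "kinds")
})

test_that("matrix TSV writer emits the full long layout", {
  lib <- enumerateMismatchLibrary("ACGTACGT", 1)
  ids <- variants(lib)$variant_id
  meas <- S4Vectors::DataFrame(
    variant_id = ids, kind = "lnKA", value = ifelse(ids == "WT", 0, -1),
    se = ifelse(ids == "WT", 0, 1), replicate = "1")
  em <- fitBindingEnergyMatrix(meas, lib)
  path <- tempfile(fileext = ".tsv")
  writeEnergyMatrixTSV(em, path)
  df <- utils::read.delim(path, comment.char = "#")
  expect_equal(nrow(df), 4L * 8L)
  expect_true(all(c("position", "base", "epsilon", "se", "flag") %in%
                  colnames(df)))
  unlink(path)
})
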