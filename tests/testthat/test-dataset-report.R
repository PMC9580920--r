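# scaling-law fits, Gaussian geometry fits, dataset summary

test_that("power-law fit recovers generator constants exactly on noiseless data", {
  L <- c(20, 35, 60, 100, 180, 300, 500)
  expect_equal(fitPowerLaw(L, 6.7 * L^0.31), c(a = 6.7, b = 0.31),
               tolerance = 1e-9)
  Ls <- c(12, 25, 40, 60, 85)
  expect_equal(fitPowerLaw(Ls, 5.1 * Ls^0.37), c(a = 5.1, b = 0.37),
               tolerance = 1e-9)
  # constant Rg gives exponent 0
  expect_equal(unname(fitPowerLaw(L, rep(8, length(L)))["b"]), 0,
               tolerance = 1e-12)
  expect_error(fitPowerLaw(c(-5, 10), c(1, 2)), "positive")
  expect_error(fitPowerLaw(c(10, 10), c(1, 2)), "distinct")
})

test_that("power-law fit is within 2 sd under seeded noise", {
  set.seed(606)
  L <- round(seq(20, 500, length.out = 120))
  rg <- 6.7 * L^0.31 * exp(rnorm(length(L), sd = 0.1))
  fit <- fitPowerLaw(L, rg)
  # sd of the log-log slope at this design is well under 0.02
  expect_lt(abs(fit["b"] - 0.31), 0.04)
  expect_lt(abs(log(fit["a"]) - log(6.7)), 0.25)
})

test_that("through-origin slope recovery, including the single-point case", {
  L <- c(30, 60, 90, 200)
  expect_equal(fitLinearThroughOrigin(L, 0.48 * L), 0.48, tolerance = 1e-12)
  expect_equal(fitLinearThroughOrigin(L, 0.21 * L), 0.21, tolerance = 1e-12)
  expect_equal(fitLinearThroughOrigin(100, 50), 0.5)
  expect_error(fitLinearThroughOrigin(numeric(), numeric()), "one point")
})

test_that("pair-geometry Gaussians: identical records, wraparound, sampling", {
  g <- data.frame(class = "AU cWW", rho = c(7, 7), theta = c(0, 0),
                  z = c(0, 0))
  f <- fitPairGaussians(g)
  expect_equal(f$rho_mean, 7); expect_equal(f$rho_sd, 0)
  expect_equal(f$theta_mean, 0); expect_equal(f$theta_sd, 0)
  expect_equal(f$z_sd, 0)
  # circular wraparound
  f2 <- fitPairGaussians(data.frame(class = "x", rho = 1,
                                    theta = c(350, 10), z = 0))
  expect_equal(f2$theta_mean, 0, tolerance = 1e-9)
  # classes below the threshold are reported unfitted
  f3 <- fitPairGaussians(data.frame(class = c("a", "b", "b"), rho = 1,
                                    theta = 0, z = 0), minN = 2)
  expect_true(is.na(f3$rho_mean[f3$class == "a"]))
  expect_false(is.na(f3$rho_mean[f3$class == "b"]))
  # seeded sampling check against the generator
  set.seed(777)
  n <- 1e4
  gs <- data.frame(class = "s", rho = rnorm(n, 7, 0.3),
                   theta = (rnorm(n, 0, 5)) %% 360, z = rnorm(n, 0, 0.2))
  fs <- fitPairGaussians(gs)
  expect_lt(abs(fs$rho_mean - 7), 3 * 0.3 / sqrt(n))
  expect_equal(fs$rho_sd, 0.3, tolerance = 0.02)
  expect_true(fs$theta_mean < 1 || fs$theta_mean > 359)
  expect_equal(fs$theta_sd, 5, tolerance = 0.2)
})

test_that("dataset summary aggregates, fits, and is permutation invariant", {
  seqs <- c("GGCAUCGC", "GCGCAUGCGAUC", "GGGAAACCCAUAUGCG", "AUGCAUGGCC")
  anns <- lapply(seqs, function(sq)
    annotateStructure(makeDuplex(sq, id = sq)$structure))
  summ <- summarizeDataset(anns)
  expect_s4_class(summ, "DatasetSummary")
  expect_equal(summ@nStructures, 4L)
  expect_equal(nrow(summ@perStructure), 4L)
  expect_equal(sum(summ@frequencies$nucleotide), 1, tolerance = 1e-12)
  expect_equal(sum(summ@frequencies$pair), 1, tolerance = 1e-12)
  expect_false(is.null(summ@fits$power_law))
  # permutation invariance
  summ2 <- summarizeDataset(anns[c(3, 1, 4, 2)])
  expect_equal(summ@perStructure, summ2@perStructure)
  expect_equal(summ@fits, summ2@fits)
  expect_equal(summ@frequencies, summ2@frequencies)
})

test_that("single-structure summary skips fits with a warning; duplicates are stable", {
  ann <- annotateStructure(makeDuplex("GGCAUGC", id = "one")$structure)
  expect_warning(s1 <- summarizeDataset(list(ann)), "fits skipped")
  expect_equal(s1@nStructures, 1L)
  expect_null(s1@fits$power_law)
  s2 <- suppressWarnings(summarizeDataset(list(ann, ann)))
  expect_equal(s2@perStructure$rg[1], s2@perStructure$rg[2])
  expect_equal(s2@frequencies$nucleotide, s1@frequencies$nucleotide)
})

test_that("asphericity threshold fraction is computed from the table", {
  ann <- annotateStructure(makeDuplex("GGCAUGC", id = "a")$structure)
  fake <- function(a, d) { a$shape@asphericity <- d; a$id <- paste0("s", d); a }
  anns <- list(fake(ann, 0.1), fake(ann, 0.3))
  s <- suppressWarnings(summarizeDataset(anns))
  expect_equal(s@asphericityBelow02, 0.5)
})
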