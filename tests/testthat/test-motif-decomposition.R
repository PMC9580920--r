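# pseudoknot resolution, stem/loop decomposition, histograms

test_that("pseudoknot resolver handles the crossing-block example and edge cases", {
  # two crossing blocks of 2: the resolver must keep one whole block
  res <- resolvePseudoknots(cbind(i = c(1, 2, 5, 6), j = c(10, 9, 14, 13)))
  expect_equal(nrow(res$nested), 2L)
  expect_equal(nrow(res$removed), 2L)
  expect_setequal(c(res$nested[, 1], res$removed[, 1]), c(1, 2, 5, 6))
  # nested input passes through
  res2 <- resolvePseudoknots(cbind(i = 1:3, j = 12:10))
  expect_equal(nrow(res2$removed), 0L)
  expect_equal(nrow(res2$nested), 3L)
  # empty input
  res3 <- resolvePseudoknots(matrix(integer(), 0, 2,
                                    dimnames = list(NULL, c("i", "j"))))
  expect_equal(nrow(res3$nested), 0L)
  expect_equal(nrow(res3$removed), 0L)
  # residue in two pairs is rejected
  expect_error(resolvePseudoknots(cbind(i = c(1, 1), j = c(5, 8))),
               "more than one")
})

test_that("resolver is a maximum-cardinality crossing-free subset (vs brute force)", {
  set.seed(314)
  for (trial in 1:150) {
    m <- sample(1:8, 1)
    p <- randomPairInstance(m)
    res <- resolvePseudoknots(p)
    expect_equal(nrow(res$nested), maxNonCrossingBruteForce(p),
                 info = paste("trial", trial))
    # nested union removed is the input
    expect_setequal(paste(res$nested[, 1], res$nested[, 2]) |>
                      c(paste(res$removed[, 1], res$removed[, 2])),
                    paste(p[, 1], p[, 2]))
    # nested set really is crossing-free
    n <- res$nested
    if (nrow(n) > 1)
      for (a in 1:(nrow(n) - 1)) {
        b <- (a + 1):nrow(n)
        expect_false(any(n[a, 1] < n[b, 1] & n[b, 1] < n[a, 2] &
                         n[a, 2] < n[b, 2]))
      }
  }
})

test_that("decomposition reproduces hand-worked stem/loop oracles", {
  # 12-nt hairpin: stem of 3, hairpin loop of 6 at positions 4..9
  ss <- decomposeSecondaryStructure(12, cbind(i = 1:3, j = 12:10))
  expect_equal(length(ss@stems), 1L)
  expect_equal(nrow(ss@stems[[1]]), 3L)
  expect_equal(ss@loops$kind, "hairpin")
  expect_equal(ss@loops$length, 6L)
  expect_equal(ss@loops$positions[[1]], 4:9)
  expect_equal(ss@dotbracket, "(((......)))")

  # 20-nt: stems of 3 and 2, bulge of 1 at position 4, hairpin of 9 at 7..15
  ss2 <- decomposeSecondaryStructure(
    20, cbind(i = c(1, 2, 3, 5, 6), j = c(20, 19, 18, 17, 16)))
  expect_setequal(vapply(ss2@stems, nrow, integer(1)), c(3L, 2L))
  expect_equal(sort(ss2@loops$kind), c("bulge", "hairpin"))
  expect_equal(ss2@loops$length[ss2@loops$kind == "bulge"], 1L)
  expect_equal(ss2@loops$positions[[which(ss2@loops$kind == "bulge")]], 4L)
  expect_equal(ss2@loops$length[ss2@loops$kind == "hairpin"], 9L)

  # symmetric 2+2 internal loop between two stems
  ss3 <- decomposeSecondaryStructure(
    20, cbind(i = c(1, 2, 5, 6), j = c(20, 19, 16, 15)))
  intl <- ss3@loops[ss3@loops$kind == "internal", ]
  expect_equal(nrow(intl), 1L)
  expect_equal(intl$length, 4L)

  # four-way junction: three inner stems plus the closing stem
  ss4 <- decomposeSecondaryStructure(
    30, cbind(i = c(1, 2, 4, 5, 12, 13, 20, 21),
              j = c(30, 29, 10, 9, 18, 17, 27, 26)))
  expect_true("junction" %in% ss4@loops$kind)
  j <- ss4@loops[ss4@loops$kind == "junction", ]
  expect_equal(j$branches, 4L)
})

test_that("lone pairs are separated from stems and pseudoknots enter bracket tiers", {
  ss <- decomposeSecondaryStructure(
    16, cbind(i = c(1, 2, 8), j = c(16, 15, 12)),
    pseudoknot = cbind(i = 5, j = 14))
  expect_equal(length(ss@stems), 1L)
  expect_equal(nrow(ss@lonePairs), 1L)
  expect_equal(unname(ss@lonePairs[1, ]), c(8L, 12L))
  expect_equal(ss@dotbracket, "((..[..(...).]))")
})

test_that("every residue is classified exactly once (partition property)", {
  set.seed(99)
  for (trial in 1:40) {
    L <- sample(10:60, 1)
    m <- sample(0:(L %/% 3), 1)
    p <- if (m > 0) randomPairInstance(m, L) else
      matrix(integer(), 0, 2, dimnames = list(NULL, c("i", "j")))
    res <- resolvePseudoknots(p)
    ss <- decomposeSecondaryStructure(L, res$nested, res$removed)
    stemPaired <- sum(vapply(ss@stems, nrow, integer(1))) * 2 +
      nrow(ss@lonePairs) * 2
    loopTotal <- sum(ss@loops$length)
    inLoop <- unlist(ss@loops$positions)
    expect_false(any(duplicated(inLoop)))
    paired <- c(unlist(lapply(ss@stems, function(s) c(s))),
                c(ss@lonePairs))
    expect_false(any(inLoop %in% paired))
    exterior <- L - stemPaired - loopTotal
    expect_gte(exterior, 0)
    expect_equal(stemPaired + loopTotal + exterior, L)
  }
})

test_that("motif histograms and frequency tables behave as distributions", {
  hp <- makeHairpin(3, 4, seed = 1, stemSeq = c("G", "G", "C"),
                    loopSeq = c("U", "U", "C", "G"))
  ann <- annotateStructure(hp$structure)
  h1 <- motifHistograms(list(ann))
  expect_equal(h1$stem, c("3" = 1L))
  expect_equal(h1$hairpin, c("4" = 1L))
  expect_equal(sum(h1$nucleotide), 1)
  expect_equal(sum(h1$pair), 1)
  # duplicating the structure doubles counts but leaves frequencies alone
  h2 <- motifHistograms(list(ann, ann))
  expect_equal(h2$stem, 2L * h1$stem)
  expect_equal(h2$hairpin, 2L * h1$hairpin)
  expect_equal(h2$nucleotide, h1$nucleotide)
  # a set with only G-C pairs has pair frequency 1 for C-G
  dxGC <- makeDuplex("GGCC")
  annGC <- annotateStructure(dxGC$structure)
  hGC <- motifHistograms(list(annGC))
  expect_equal(unname(hGC$pair["C-G"]), 1)
})

test_that("hairpin fixtures decompose to their declared ground truth", {
  for (cfg in list(c(3, 4), c(2, 7), c(4, 5))) {
    hp <- makeHairpin(cfg[1], cfg[2], seed = cfg[1] * 10 + cfg[2])
    ann <- annotateStructure(hp$structure)
    ss <- ann$secstruct[["A"]]
    if (cfg[1] >= 2) {
      expect_equal(length(ss@stems), 1L)
      expect_equal(nrow(ss@stems[[1]]), cfg[1])
    } else {
      expect_equal(nrow(ss@lonePairs), 1L)
    }
    expect_equal(ss@loops$kind, "hairpin")
    expect_equal(ss@loops$length, cfg[2])
  }
})
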