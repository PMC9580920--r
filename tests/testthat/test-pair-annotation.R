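# geometric pair/stack detection and DSSR JSON ingestion

test_that("detector recovers exactly the constructed pairs of an ideal duplex", {
  dx <- makeDuplex("GGCAGCUC")
  found <- detectBasePairs(dx$structure)
  expect_equal(nrow(found), nrow(dx$pairs))
  expect_setequal(paste(found$i, found$j), paste(dx$pairs$i, dx$pairs$j))
  expect_true(all(found$canonical))
  expect_true(all(found$sector_i == "WC" & found$sector_j == "WC"))
})

test_that("a built-in G.U wobble is reported canonical", {
  dx <- makeDuplex("GGUGC", wobbleAt = 3L)
  found <- detectBasePairs(dx$structure)
  wob <- found[found$base_i == "U" | found$base_j == "U", ]
  expect_true(nrow(wob) >= 1)
  expect_true(all(wob$canonical))
})

test_that("a random coil with no close base contacts yields an empty pair list", {
  hp <- makeHairpin(1, 8, seed = 3)   # mostly loop on a wide arc
  ann <- atomTable(hp$structure)
  loopRes <- (2):(9)
  coil <- new("RNAStructure", id = "coil",
              atoms = transform(ann[ann$residx %in% loopRes, ],
                                residx = residx - 1L),
              log = character())
  expect_equal(nrow(detectBasePairs(coil)), 0L)
  # sanity: the single WC pair of a 1-bp duplex is still found
  expect_equal(nrow(detectBasePairs(makeDuplex("G")$structure)), 1L)
})

test_that("detector precision/recall is 1 over seeded random helices and placements", {
  set.seed(77)
  for (k in 1:10) {
    n <- sample(4:12, 1)
    seqA <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                  collapse = "")
    dx <- makeDuplex(seqA)
    R <- randomRotation(); t <- rnorm(3, sd = 30)
    sR <- applyRigidStructure(dx$structure, R, t)
    found <- detectBasePairs(sR)
    expect_setequal(paste(found$i, found$j), paste(dx$pairs$i, dx$pairs$j))
    expect_true(all(found$canonical))
  }
})

test_that("detector output is independent of atom ordering", {
  dx <- makeDuplex("GCAU")
  a <- atomTable(dx$structure)
  set.seed(8)
  perm <- a[sample.int(nrow(a)), ]
  perm <- perm[order(perm$residx), ]   # residue order is structural
  s2 <- new("RNAStructure", id = "perm", atoms = perm, log = character())
  f1 <- detectBasePairs(dx$structure)
  f2 <- detectBasePairs(s2)
  expect_equal(f1[, c("i", "j", "rho", "theta", "z", "canonical")],
               f2[, c("i", "j", "rho", "theta", "z", "canonical")],
               tolerance = 1e-12)
})

test_that("stacking: adjacent intra-strand neighbours stack, coplanar bases do not", {
  dx <- makeDuplex("GGCAGC")
  st <- detectStacking(dx$structure)
  truthStacks <- makeDuplex("GGCAGC")$stacks
  adj <- st[st$adjacent, c("i", "j")]
  expect_true(all(paste(truthStacks$i, truthStacks$j) %in%
                  paste(adj$i, adj$j)))
  expect_true(all(abs(st$z) >= 2.5 & abs(st$z) <= 4.5))
  # two coplanar side-by-side bases: the paired partner (z ~ 0) never stacks
  pairKeys <- paste(dx$pairs$i, dx$pairs$j)
  expect_false(any(paste(st$i, st$j) %in% pairKeys))
  # isolated single base: nothing to stack
  single <- makeDuplex("G")$structure
  a <- atomTable(single)
  lone <- new("RNAStructure", id = "lone",
              atoms = a[a$chain == "A", ], log = character())
  expect_equal(nrow(detectStacking(lone)), 0L)
})

test_that("DSSR JSON ingestion maps pairs and recomputes canonical flags", {
  dx <- makeDuplex("GGCAUGCGGGCC")
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(pairs = list(
    list(nt1 = "A.G1", nt2 = "B.C12", LW = "cWW", name = "WC"),
    list(nt1 = "A.G2", nt2 = "B.C11", LW = "tHS", name = "other"))),
    f, auto_unbox = TRUE)
  ing <- readDSSRAnnotation(f, dx$structure)
  expect_equal(nrow(ing$pairs), 2L)
  expect_equal(ing$pairs$lw_label, c("cWW", "tHS"))
  expect_equal(ing$pairs$canonical, c(TRUE, FALSE))
  expect_equal(ing$pairs$source, c("dssr", "dssr"))
  # zero pairs is a valid annotation
  jsonlite::write_json(list(pairs = list()), f, auto_unbox = TRUE)
  expect_equal(nrow(readDSSRAnnotation(f, dx$structure)$pairs), 0L)
})

test_that("malformed DSSR JSON reports the missing section", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines("{\"stems\": []}", f)
  expect_error(readDSSRAnnotation(f), "pairs")
  writeLines("not json {", f)
  expect_error(readDSSRAnnotation(f), "malformed")
})

test_that("exported annotations survive a round trip", {
  dx <- makeDuplex("GGCAUGC")
  p0 <- detectBasePairs(dx$structure)
  f <- withr::local_tempfile(fileext = ".json")
  writeAnnotationJSON(p0, dx$structure, f)
  p1 <- readDSSRAnnotation(f, dx$structure)$pairs
  expect_equal(p1[, c("i", "j", "base_i", "base_j", "canonical")],
               p0[, c("i", "j", "base_i", "base_j", "canonical")])
})

test_that("detection thresholds are validated", {
  expect_error(pairDetectionParams(hbDist = -1), "positive")
  p <- pairDetectionParams(hbDist = 3.0, hbMin = 3)
  expect_equal(p$hbDist, 3.0)
  expect_equal(p$hbMin, 3)
})
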