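test_that("embedding benzene gives a planar ring with aromatic bond lengths", {
  bz <- embedConformers(c(benzene = "c1ccccc1"))[["benzene"]]
  expect_equal(nAtoms(bz), 12L)
  d <- fieldQSAR:::bondLengths(bz)
  cc <- d[bz@atoms$element[bz@bonds[, "from"]] == "C" &
          bz@atoms$element[bz@bonds[, "to"]] == "C"]
  expect_true(all(cc > 1.38 & cc < 1.42))
  # planarity: smallest principal component of the carbons ~ 0
  xyz <- atomCoords(bz)[bz@atoms$element == "C", ]
  expect_lt(min(svd(scale(xyz, scale = FALSE))$d), 1e-2)
})

test_that("embedding is deterministic", {
  smi <- c(`3` = compoundSmiles(1, "COOMe", "CH2"))
  a <- embedConformers(smi)[[1]]
  b <- embedConformers(smi)[[1]]
  expect_identical(atomCoords(a), atomCoords(b))
  expect_identical(atomCharges(a), atomCharges(b))
})

test_that("the embedded series is chemically sane", {
  confs <- seriesConformers()
  expect_length(confs, 26L)
  # neutral molecules: charges conserve to < 1e-3 e
  for (cf in confs) expect_lt(abs(sum(atomCharges(cf))), 1e-3)
  # every compound contains the 14-heavy-atom benzylideneaniline fragment
  frag <- benzylideneFragment()
  expect_equal(igraph::vcount(frag), 14L)
  for (cf in confs)
    expect_silent(fieldQSAR:::.fragmentMatches(cf, frag))
  # the template has one azomethine C=N of 1.25-1.35 A
  c10 <- confs[["10"]]
  b <- c10@bonds
  el <- c10@atoms$element
  cn2 <- which(b[, "order"] == 2 &
               ((el[b[, "from"]] == "C" & el[b[, "to"]] == "N") |
                (el[b[, "from"]] == "N" & el[b[, "to"]] == "C")))
  expect_equal(length(cn2), 1L)
  expect_gt(fieldQSAR:::bondLengths(c10)[cn2], 1.25)
  expect_lt(fieldQSAR:::bondLengths(c10)[cn2], 1.35)
})

test_that("Gasteiger charges show the expected electronegativity patterns", {
  ch4 <- embedConformers(c(methane = "C"))[[1]]
  qc <- atomCharges(ch4)[ch4@atoms$element == "C"]
  qh <- atomCharges(ch4)[ch4@atoms$element == "H"]
  expect_lt(qc, 0)
  expect_true(all(qh > 0))
  expect_lt(abs(sum(atomCharges(ch4))), 1e-3)
  # in the template's ester, all oxygens are negative and the sp3 (alkyl /
  # bridge) oxygens carry more negative Gasteiger charge than the carbonyl
  # oxygen (direction cross-checked against the RDKit Gasteiger
  # implementation: -0.465/-0.454 sp3 vs -0.246 carbonyl)
  c10 <- seriesConformers()[["10"]]
  qO2 <- atomCharges(c10)[c10@atoms$type == "O.2"]   # carbonyl
  qO3 <- atomCharges(c10)[c10@atoms$type == "O.3"]   # ether/ester sp3
  expect_length(qO2, 1L)
  expect_length(qO3, 2L)
  expect_true(all(c(qO2, qO3) < 0))
  expect_gt(qO2, max(qO3))
})

test_that("self- and rigid-motion alignment are exact", {
  c10 <- seriesConformers()[["10"]]
  self <- alignToTemplate(c10, c10)
  expect_lt(self$result$rmsd, 1e-9)
  expect_equal(self$result$rotation, diag(3), tolerance = 1e-9)
  expect_equal(nrow(self$result$matchedPairs), 14L)
  shifted <- c10
  atomCoords(shifted) <- atomCoords(c10) +
    matrix(c(5, 0, 0), nAtoms(c10), 3, byrow = TRUE)
  fit <- alignToTemplate(shifted, c10)
  expect_lt(fit$result$rmsd, 1e-9)
  expect_equal(atomCoords(fit$conformer), atomCoords(c10), tolerance = 1e-9)
})

test_that("Kabsch superposition is optimal and idempotent", {
  set.seed(7)
  P <- matrix(rnorm(30), 10, 3)
  R0 <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R0) < 0) R0[, 1] <- -R0[, 1]
  Q <- P %*% t(R0) + matrix(c(1, -2, 3), 10, 3, byrow = TRUE) +
       matrix(rnorm(30, sd = 0.05), 10, 3)
  best <- kabsch(P, Q)
  expect_equal(det(best$rotation), 1, tolerance = 1e-9)
  # no random rigid motion does better
  rss <- function(R, t) sqrt(mean(rowSums((P %*% t(R) +
    matrix(t, 10, 3, byrow = TRUE) - Q)^2)))
  for (i in 1:50) {
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    expect_gte(rss(R, rnorm(3)), best$rmsd - 1e-12)
  }
  # idempotence on the real series
  ali <- seriesAligned()
  a2 <- alignToTemplate(ali$conformers[["17"]], ali$conformers[["10"]])
  expect_lt(max(abs(atomCoords(a2$conformer) -
                    atomCoords(ali$conformers[["17"]]))), 1e-6)
})

test_that("conformers round-trip through SDF V2000 with charges", {
  confs <- seriesConformers()[c("1", "10")]
  f <- tempfile(fileext = ".sdf")
  writeConformerSDF(confs, f)
  back <- readConformerSDF(f)
  expect_named(back, c("1", "10"))
  for (id in names(back)) {
    expect_equal(atomCoords(back[[id]]), atomCoords(confs[[id]]),
                 tolerance = 1e-4, ignore_attr = TRUE)
    expect_equal(atomCharges(back[[id]]), atomCharges(confs[[id]]),
                 tolerance = 1e-6)
    expect_equal(nrow(back[[id]]@bonds), nrow(confs[[id]]@bonds))
  }
})
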