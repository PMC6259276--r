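test_that("grid construction honours spacing, margin and input order", {
  one <- singleAtomConformer()
  g <- makeGrid(list(one), spacing = 1, margin = 4)
  expect_equal(g@dims, c(9L, 9L, 9L))
  expect_equal(nrow(gridPoints(g)), 729L)
  expect_equal(g@origin, c(-4, -4, -4))
  g0 <- makeGrid(list(one), spacing = 1, margin = 0)
  expect_equal(g0@dims, c(1L, 1L, 1L))
  expect_error(makeGrid(list()), "empty")
  # permutation invariance on the aligned series
  ali <- seriesAligned()$conformers
  g1 <- makeGrid(ali)
  g2 <- makeGrid(rev(ali))
  expect_identical(g1@origin, g2@origin)
  expect_identical(g1@dims, g2@dims)
})

test_that("grid points enumerate x-fastest", {
  g <- new("GridSpec", origin = c(0, 0, 0), spacing = 2,
           dims = c(2L, 2L, 2L), margin = 0)
  p <- gridPoints(g)
  expect_equal(p[1:2, 1], c(0, 2))      # x varies first
  expect_equal(p[c(1, 3), 2], c(0, 2))  # then y
  expect_equal(p[c(1, 5), 3], c(0, 2))  # then z
})

test_that("the steric field matches Lennard-Jones closed forms", {
  one <- singleAtomConformer("C")
  # far point: r^-6 decay
  far <- comfaSteric(one, pointGrid(16))
  expect_lt(abs(far$energy), 1e-3)
  expect_false(far$clamped)
  # coincident point: exactly the +30 truncation
  onAtom <- comfaSteric(one, pointGrid(0))
  expect_identical(onAtom$energy, 30)
  expect_true(onAtom$clamped)
  # minimum-energy distance R* = R_probe + R_C = 3.4 A: E = -eps = -0.107
  atMin <- comfaSteric(one, pointGrid(3.4))
  expect_equal(atMin$energy, -0.107, tolerance = 1e-9)
})

test_that("the electrostatic field matches Coulomb arithmetic and symmetry", {
  ion <- conformer("N", c(0, 0, 0), charge = 1, netCharge = 1)
  # 332.0636 * 1 * 1 / 3.32^2 = 30.12 -> clamped at +30
  expect_identical(comfaElectrostatic(ion, pointGrid(3.32)), 30)
  # unclamped point: exact arithmetic with D(r) = r
  e5 <- comfaElectrostatic(ion, pointGrid(5))
  expect_equal(e5, 332.0636 / 25, tolerance = 1e-9)
  # constant dielectric option: 1/r (r chosen below the clamp)
  e6c <- comfaElectrostatic(ion, pointGrid(6), dielectric = 2)
  expect_equal(e6c, 332.0636 / 12, tolerance = 1e-9)
  # neutral atoms give exactly zero
  neutral <- conformer(c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)),
                       charge = 0)
  expect_equal(comfaElectrostatic(neutral, pointGrid(4)), 0)
  # charge antisymmetry away from the clamp
  dipole <- conformer(c("N", "O"), rbind(c(0, 0, 0), c(1.2, 0, 0)),
                      charge = c(0.3, -0.3))
  flipped <- conformer(c("N", "O"), rbind(c(0, 0, 0), c(1.2, 0, 0)),
                       charge = c(-0.3, 0.3))
  g <- pointGrid(4, 1, 0)
  expect_equal(comfaElectrostatic(dipole, g), -comfaElectrostatic(flipped, g))
})

test_that("similarity indices follow the Gaussian kernel closed form", {
  one <- singleAtomConformer("C")
  one@atoms$steric <- 1  # unit weight for the closed-form check
  expect_equal(comsiaField(one, pointGrid(0), property = "steric"), -1)
  expect_equal(comsiaField(one, pointGrid(2), property = "steric"),
               -exp(-0.3 * 4), tolerance = 1e-12)
  expect_equal(round(-exp(-0.3 * 4), 4), -0.3012)
  # empty molecule: empty sum
  empty <- conformer(character(0), matrix(numeric(0), 0, 3), weights = FALSE)
  empty@atoms$steric <- numeric(0)
  expect_equal(comsiaField(empty, pointGrid(0), property = "steric"), 0)
  expect_error(comsiaField(one, pointGrid(0), property = "magnetic"),
               "unknown CoMSIA channel")
})

test_that("steric energy and steric similarity rank near-surface points oppositely", {
  one <- singleAtomConformer("C")
  r <- seq(2, 3.4, by = 0.2)
  lj <- vapply(r, function(x) comfaSteric(one, pointGrid(x))$energy, 0)
  si <- vapply(r, function(x)
    comsiaField(one, pointGrid(x), property = "steric"), 0)
  expect_lt(cor(lj, si, method = "spearman"), 0)
})

test_that("the assembled field matrix obeys its shape and invariance contracts", {
  ali <- seriesAligned()$conformers
  fm <- seriesPipeline()$fieldMatrix
  np <- prod(fm@grid@dims)
  expect_equal(dim(fieldValues(fm)), c(26L, np * 7L))
  expect_length(channelOfColumn(fm), np * 7L)
  # CoMFA channels bounded by the truncation interval
  comfa <- fieldValues(fm)[, grepl("^comfa", channelOfColumn(fm))]
  expect_gte(min(comfa), -30)
  expect_lte(max(comfa), 30)
  expect_true(all(is.finite(fieldValues(fm))))
  # translation invariance: shift conformers and grid together
  sub <- ali[c("1", "2")]
  g <- makeGrid(sub, spacing = 2, margin = 3)
  fm1 <- assembleFieldMatrix(sub, g)
  shift <- c(3, -1, 2)
  sub2 <- lapply(sub, function(cf) {
    atomCoords(cf) <- atomCoords(cf) +
      matrix(shift, nAtoms(cf), 3, byrow = TRUE)
    cf
  })
  g2 <- new("GridSpec", origin = g@origin + shift, spacing = g@spacing,
            dims = g@dims, margin = g@margin)
  fm2 <- assembleFieldMatrix(sub2, g2)
  expect_equal(fieldValues(fm1), fieldValues(fm2), tolerance = 1e-9)
  # atom order invariance
  rev1 <- lapply(sub, function(cf) {
    n <- nAtoms(cf)
    perm <- rev(seq_len(n))
    cf@atoms <- cf@atoms[perm, ]
    rownames(cf@atoms) <- NULL
    b <- cf@bonds
    b[, "from"] <- n + 1L - b[, "from"]
    b[, "to"] <- n + 1L - b[, "to"]
    cf@bonds <- b
    cf
  })
  fm3 <- assembleFieldMatrix(rev1, g)
  expect_equal(fieldValues(fm1), fieldValues(fm3), tolerance = 1e-9)
})

test_that("doubling the spacing keeps values at coincident points", {
  sub <- seriesAligned()$conformers[c("1", "26")]
  g1 <- new("GridSpec", origin = c(-8, -8, -8), spacing = 1,
            dims = c(17L, 17L, 17L), margin = 0)
  g2 <- new("GridSpec", origin = c(-8, -8, -8), spacing = 2,
            dims = c(9L, 9L, 9L), margin = 0)
  expect_equal(prod(g2@dims) / prod(g1@dims), 1 / 8, tolerance = 0.2)
  fm1 <- assembleFieldMatrix(sub, g1, channels = "comsia_steric")
  fm2 <- assembleFieldMatrix(sub, g2, channels = "comsia_steric")
  p1 <- gridPoints(g1); p2 <- gridPoints(g2)
  key <- function(p) paste(p[, 1], p[, 2], p[, 3])
  idx <- match(key(p2), key(p1))
  expect_false(anyNA(idx))
  expect_equal(fieldValues(fm2), fieldValues(fm1)[, idx], tolerance = 1e-9)
})

test_that("electrostatic values at sterically clamped points use the column mean", {
  sub <- seriesAligned()$conformers[c("1", "2", "26")]
  g <- makeGrid(sub, spacing = 2, margin = 2)
  fm <- assembleFieldMatrix(sub, g,
                            channels = c("comfa_steric", "comfa_elec"))
  fmKeep <- assembleFieldMatrix(sub, g,
    channels = c("comfa_steric", "comfa_elec"), elecAtClamped = "keep")
  v <- fieldValues(fm); vk <- fieldValues(fmKeep)
  ch <- channelOfColumn(fm)
  st <- v[, ch == "comfa_steric"]
  el <- v[, ch == "comfa_elec"]; elk <- vk[, ch == "comfa_elec"]
  clamped <- st >= 30 - 1e-9
  expect_gt(sum(clamped), 0)
  # at a point where one compound is clamped and others are not, the clamped
  # entry equals the mean of the unclamped ones
  j <- which(colSums(clamped) == 1 & colSums(!clamped) == 2)[1]
  expect_false(is.na(j))
  i <- which(clamped[, j])
  expect_equal(el[i, j], mean(elk[-i, j]), tolerance = 1e-9,
               ignore_attr = TRUE)
  # unclamped entries are untouched
  expect_equal(el[!clamped], elk[!clamped], tolerance = 1e-12,
               ignore_attr = TRUE)
})
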