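test_that("the supervised input set is the union of DE and eQTL genes", {
  set.seed(4)
  y <- matrix(rnorm(10 * 8), 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
  pe <- asProcessed(y)
  x <- buildInputSet(paste0("g", 1:3), paste0("g", 4:7), pe)
  expect_equal(attr(x, "size"), 7L)
  x2 <- buildInputSet(paste0("g", c(1, 2, 3)), paste0("g", c(2, 3, 4)), pe)
  expect_equal(attr(x2, "size"), 4L)
  x3 <- buildInputSet(paste0("g", 1:3), paste0("g", 1:3), pe)
  expect_equal(attr(x3, "size"), 3L)
  expect_equal(rownames(x), paste0("g", 1:7))  # expression order kept
  expect_error(buildInputSet("nope", "g1", pe), "absent")
})

test_that("scale-free fit is exact on an exactly log-log-linear histogram", {
  # one distinct connectivity value per bin, counts proportional to 1/k:
  # log10 p(k) = -log10 k + c exactly
  k <- rep(1:10, times = 2520 / (1:10))
  f <- scaleFreeFit(k)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  expect_equal(f$slope, -1, tolerance = 1e-10)
  # a positive log-log slope is reported as a negative index
  kpos <- rep(1:10, times = (1:10) * 5)
  expect_lt(scaleFreeFit(kpos)$r_squared, 0)
})

test_that("soft-threshold scan picks the smallest adequate power", {
  sm <- moduleMatrix(3, n = 60L, sizes = c(40L, 40L), noise = 10L,
                     load = 0.95)
  # selection contract: the smallest power whose fit reaches the target
  probe <- suppressWarnings(softThresholdScan(sm$x))
  tab <- probe$fit_table
  target <- max(tab$r_squared, na.rm = TRUE) - 0.01
  scan <- softThresholdScan(sm$x, targetR2 = target)
  first <- min(tab$beta[!is.na(tab$r_squared) & tab$r_squared >= target])
  expect_equal(scan$beta, first)
  # constant genes are removed with a warning
  x2 <- sm$x; x2[1, ] <- 5
  expect_warning(softThresholdScan(x2, candidateBetas = 1:3), "constant")
  # raising beta increases sparsity: mean adjacency non-increasing
  expect_true(all(diff(tab$mean_k) <= 1e-9))
})

test_that("TOM matches hand values and the triple-loop oracle", {
  # complete graph: all overlaps are 1
  a1 <- matrix(1, 4, 4)
  expect_equal(unname(topologicalOverlap(a1)), matrix(1, 4, 4))
  # empty off-diagonal: zero overlap
  a0 <- diag(3)
  t0 <- topologicalOverlap(a0)
  expect_equal(unname(t0[upper.tri(t0)]), rep(0, 3))
  # three-gene hand evaluation
  a3 <- rbind(c(1, 0.5, 0.5), c(0.5, 1, 0), c(0.5, 0, 1))
  t3 <- topologicalOverlap(a3)
  expect_equal(t3[1, 2], 0.5 / (0.5 + 1 - 0.5), tolerance = 1e-12)
  # disjoint union of edges: TOM equals adjacency
  a2 <- diag(4); a2[1, 2] <- a2[2, 1] <- 0.7; a2[3, 4] <- a2[4, 3] <- 0.2
  expect_equal(unname(topologicalOverlap(a2)), unname(a2),
               tolerance = 1e-12)
  # random matrices against the oracle
  set.seed(31)
  for (r in 1:20) {
    a <- matrix(runif(144), 12); a <- (a + t(a)) / 2; diag(a) <- 1
    expect_lt(max(abs(topologicalOverlap(a) - tomOracle(a))), 1e-12)
  }
})

test_that("module detection recovers planted block structure", {
  # two perfect blocks
  n1 <- 30L; n2 <- 40L
  tom <- diag(n1 + n2)
  tom[1:n1, 1:n1] <- 1
  tom[(n1 + 1):(n1 + n2), (n1 + 1):(n1 + n2)] <- 1
  rownames(tom) <- colnames(tom) <- paste0("g", seq_len(n1 + n2))
  lab <- detectModules(tom, minSize = 25L)
  expect_equal(length(unique(lab)), 2L)
  expect_equal(unname(lab[1:n1]), rep(2L, n1))     # smaller block second
  expect_equal(unname(lab[(n1 + 1):(n1 + n2)]), rep(1L, n2))
  # too few genes
  expect_warning(l0 <- detectModules(tom[1:20, 1:20], minSize = 25L),
                 "unassigned")
  expect_true(all(l0 == 0L))
  # small clusters go to the unassigned pool
  tom2 <- diag(40); tom2[1:30, 1:30] <- 1
  rownames(tom2) <- colnames(tom2) <- paste0("g", 1:40)
  lab2 <- detectModules(tom2, minSize = 25L)
  expect_equal(sum(lab2 > 0), 30L)
  expect_equal(sum(lab2 == 0), 10L)
})

test_that("module labels are invariant to gene order up to renaming", {
  sm <- moduleMatrix(8)
  scan <- suppressWarnings(softThresholdScan(sm$x))
  tom <- topologicalOverlap(adjacencyFromCor(scan$cor, scan$beta))
  lab <- detectModules(tom, minSize = 25L)
  perm <- sample(nrow(tom))
  lab2 <- detectModules(tom[perm, perm], minSize = 25L)
  expect_equal(adjustedRandIndex(lab, lab2[names(lab)]), 1)
})

test_that("module eigengenes summarize module expression", {
  n <- 20L
  set.seed(6)
  prof <- rnorm(n)
  x <- rbind(matrix(rep(prof, 5), 5, byrow = TRUE),
             matrix(rnorm(3 * n), 3))
  rownames(x) <- paste0("g", 1:8); colnames(x) <- paste0("s", 1:n)
  lab <- stats::setNames(c(rep(1L, 5), rep(0L, 3)), rownames(x))
  eg <- moduleEigengenes(x, lab)
  e <- eg$eigengenes["ME1", ]
  expect_equal(eg$var_explained[1], 1, tolerance = 1e-12)
  expect_equal(abs(cor(e, prof)), 1, tolerance = 1e-12)
  expect_gt(cor(e, prof), 0)  # sign oriented towards members
  expect_equal(sd(e), 1, tolerance = 1e-12)
  # two perfectly anti-correlated genes are collinear after
  # standardization: one component carries everything, and the eigengene
  # matches the first right singular vector of the standardized matrix
  x2 <- rbind(g1 = prof, g2 = -prof + rnorm(n, 0, 1e-8))
  colnames(x2) <- paste0("s", 1:n)
  lab2 <- stats::setNames(c(1L, 1L), rownames(x2))
  eg2 <- moduleEigengenes(x2, lab2)
  expect_equal(eg2$var_explained[1], 1, tolerance = 1e-4)
  sv <- svd(t(scale(t(x2))))$v[, 1]
  expect_equal(abs(cor(eg2$eigengenes["ME1", ], sv)), 1,
               tolerance = 1e-8)
  # kME sign property: own-module mean kME non-negative
  sm <- moduleMatrix(12)
  egm <- moduleEigengenes(sm$x, sm$labels)
  kme <- computeKME(sm$x, egm$eigengenes)
  for (m in 1:3) {
    genes <- names(sm$labels)[sm$labels == m]
    expect_gte(mean(kme[genes, paste0("ME", m)]), 0)
  }
})

test_that("module-trait relationships apply the strict selection rule", {
  set.seed(9)
  n <- 36L
  oi <- rnorm(n)
  eg <- rbind(ME1 = oi, ME2 = rnorm(n))
  colnames(eg) <- paste0("s", 1:n)
  mtr <- moduleTraitRelationships(eg, data.frame(oi = oi))
  expect_equal(mtr$cor[mtr$module == "ME1"], 1, tolerance = 1e-12)
  expect_true(mtr$selected[mtr$module == "ME1"])
  # exact |cor| = 0.5 is not selected
  x <- c(rep(1, 18), rep(-1, 18))
  y <- 0.5 * x + sqrt(0.75) * (c(rep(1, 9), rep(-1, 9), rep(1, 9),
                                 rep(-1, 9)))
  expect_equal(cor(x, y), 0.5, tolerance = 1e-12)
  mtr2 <- moduleTraitRelationships(rbind(ME1 = y), data.frame(tr = x))
  expect_false(mtr2$selected[1])
  # constant trait reported as missing
  mtr3 <- moduleTraitRelationships(eg, data.frame(flat = rep(1, n)))
  expect_true(all(is.na(mtr3$cor)))
  expect_false(any(mtr3$selected))
})

test_that("planted OI modules reach strong module-trait correlations", {
  hits <- logical(20)
  for (s in 1:20) {
    set.seed(4000 + s)
    oi <- rnorm(36)
    sm <- moduleMatrix(4000 + s, load = 0.7, oi = oi)
    eg <- moduleEigengenes(sm$x, sm$labels)
    mtr <- moduleTraitRelationships(eg$eigengenes, data.frame(oi = oi))
    hits[s] <- abs(mtr$cor[mtr$module == "ME1" & mtr$trait == "oi"]) > 0.5
  }
  expect_gte(mean(hits), 0.9)
})

test_that("kME membership filtering applies own and cross-module rules", {
  kme <- rbind(gA = c(0.65, 0.30), gB = c(0.55, 0.10),
               gC = c(0.90, 0.80), gD = c(0.95, 0.20))
  colnames(kme) <- c("ME1", "ME2")
  labels <- stats::setNames(rep(1L, 4), rownames(kme))
  out <- filterModuleMembership(labels, kme)
  expect_equal(unname(out[c("gA", "gD")]), c(1L, 1L))  # retained
  expect_equal(unname(out["gB"]), 0L)  # own kME 0.55 <= 0.6
  expect_equal(unname(out["gC"]), 0L)  # other-module kME 0.8 >= 0.6
  # literal published reading: cross-module kME must be ABOVE the threshold
  lit <- filterModuleMembership(labels, kme, literalCrossModuleRule = TRUE)
  expect_equal(unname(lit["gC"]), 1L)
  expect_equal(unname(lit["gA"]), 0L)
})

test_that("hub genes use connectivity with kME/trait eligibility", {
  a <- diag(4)
  a[1, 2] <- a[2, 1] <- 0.9
  a[1, 3] <- a[3, 1] <- 0.8
  a[2, 3] <- a[3, 2] <- 0.1
  a[4, 1] <- a[1, 4] <- 0.05
  rownames(a) <- colnames(a) <- c("gB", "gA", "gC", "gD")
  labels <- stats::setNames(c(1L, 1L, 1L, 1L), rownames(a))
  kme <- matrix(c(0.85, 0.80, 0.9, 0.2), ncol = 1,
                dimnames = list(rownames(a), "ME1"))
  traitCor <- stats::setNames(c(0.65, 0.7, 0.5, 0.1), rownames(a))
  hubs <- identifyHubGenes(labels, a, kme, traitCor)
  expect_equal(hubs$hub, "gB")  # highest intramodular connectivity
  # eligibility strict: gA kME 0.80 exactly -> out; gC trait 0.5 -> out
  expect_equal(hubs$eligible, "gB")
  # connectivity tie broken lexicographically
  a2 <- diag(3); a2[1, 2] <- a2[2, 1] <- 0.5
  rownames(a2) <- colnames(a2) <- c("gZ", "gY", "gX")
  lab2 <- stats::setNames(rep(1L, 3), rownames(a2))
  kme2 <- matrix(0.9, 3, 1, dimnames = list(rownames(a2), "ME1"))
  tc2 <- stats::setNames(rep(0.9, 3), rownames(a2))
  h2 <- identifyHubGenes(lab2, a2, kme2, tc2)
  expect_equal(h2$hub, "gY")  # gY and gZ tie at 0.5; gY sorts first
})
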