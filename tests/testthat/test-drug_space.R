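makeSmallFct <- function(noiseSd = 0, seed = 2, nProbes = 20,
                         networks = list()) {
  cfg <- syntheticConfig(nProbes = nProbes, drugs = c("A", "B"),
                         networks = networks, noiseSd = noiseSd, seed = seed)
  sim <- generateExperiment(cfg)
  foldChanges(normalizeExpression(sim$experiment, quantile = FALSE,
                                  batch = FALSE))
}

test_that("drug profile matrices have the contracted shape and order", {
  fct <- makeSmallFct()
  transcripts <- fct@probes[1:3]
  prof <- buildDrugProfiles(fct, transcripts)
  expect_equal(dim(prof), c(2, 12))             # 2 drugs x 3 transcripts x 4 t
  expect_equal(colnames(prof)[1:4],
               paste0(transcripts[1], "@", c(1, 2, 4, 8)))
  # zero-noise, no planted structure: all-zero rows
  expect_true(all(abs(prof) < 1e-12))
  expect_error(buildDrugProfiles(fct, "nope"), "unknown transcript")
})

test_that("clustering merges identical profiles first and matches hand
           agglomeration", {
  prof <- rbind(d1 = c(0, 0), d2 = c(0, 0), d3 = c(5, 0))
  hc <- clusterDrugs(prof)
  expect_equal(hc$height[1], 0)                 # identical rows merge at 0

  # three drugs with pairwise distances 1, 2, 3: complete linkage merges the
  # closest pair at 1, then the rest at max(2, 3) = 3
  prof2 <- rbind(a = 0, b = 1, c = 3)
  hc2 <- clusterDrugs(prof2)
  expect_equal(hc2$height, c(1, 3))
  expect_equal(sort(hc2$merge[1, ]), c(-2, -1)) # a and b first
  expect_error(clusterDrugs(prof2[1, , drop = FALSE]), ">= 2 drugs")
  expect_error(clusterDrugs(rbind(a = NA_real_, b = 1)), "non-finite")
})

test_that("dendrograms export to Newick with drug labels", {
  prof <- rbind(a = c(0, 0), b = c(1, 0), c = c(4, 4))
  path <- withr::local_tempfile(fileext = ".nwk")
  writeDendrogramNewick(clusterDrugs(prof), path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, c("a", "b", "c"))
})

test_that("PCA satisfies its algebraic contracts", {
  # collinear rows: first component carries all variance
  prof <- outer(c(1, 2, 3, 5), c(2, -1, 0.5))
  rownames(prof) <- paste0("d", 1:4)
  pca <- pcaDrugs(prof, 1)
  expect_equal(pca@varFrac[1], 1.0, tolerance = 1e-12)

  withr::with_seed(8, prof2 <- matrix(rnorm(5 * 7), 5, 7,
                                      dimnames = list(paste0("d", 1:5), NULL)))
  full <- pcaDrugs(prof2, 4)
  # variance fractions over all min(n-1, p) components sum to 1
  expect_equal(sum(full@totalVarFrac), 1.0, tolerance = 1e-12)
  # reconstruction from all components reproduces the centered matrix
  centered <- sweep(prof2, 2, colMeans(prof2))
  recon <- full@scores %*% t(full@loadings)
  expect_equal(unname(recon), unname(centered), tolerance = 1e-8)
  # orthonormal loadings (validity) and deterministic sign convention
  expect_true(validObject(full))
  for (j in 1:4) {
    v <- full@loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  expect_error(pcaDrugs(prof2, 5), "exceeds")
})

test_that("planted mechanism structure concentrates variance in few
           components", {
  # shared (flat) time shape: the three module signatures are the only
  # directions of variation, so the drug-profile matrix is rank 3
  cfg <- syntheticConfig(noiseSd = 0.02, shapeWidth = 10, seed = 12)
  sim <- generateExperiment(cfg)
  x <- suppressWarnings(normalizeExpression(sim$experiment))
  fct <- foldChanges(x)
  sc <- suppressWarnings(g2mScore(fct))
  sel <- selectTranscripts(sc, "top_k", 170)
  prof <- buildDrugProfiles(fct, sel$probe_id)
  pca <- pcaDrugs(prof, 3)
  expect_gte(sum(pca@varFrac), 0.95)
})

test_that("component correlations behave at the extremes", {
  fct <- makeSmallFct(noiseSd = 0.2, seed = 4)
  prof <- buildDrugProfiles(fct, fct@probes)
  pca <- pcaDrugs(prof, 1)
  cors <- correlateComponents(pca, fct, fct@probes[1:5])
  expect_true(all(abs(cors) <= 1 + 1e-12, na.rm = TRUE))

  # a transcript whose per-drug response equals the component scores
  # correlates perfectly; with 2 drugs any non-constant response does
  resp <- drugResponseMatrix(fct, fct@probes[1:5])
  expect_equal(dim(resp), c(5, 2))

  # zero-variance transcript: NA with a warning
  fct0 <- makeSmallFct(noiseSd = 0, seed = 4)
  withr::with_seed(99, jitter_m <- matrix(rnorm(2 * 80, sd = 1e-6), 2))
  pca0_prof <- buildDrugProfiles(fct0, fct0@probes) + jitter_m
  pca0 <- pcaDrugs(pca0_prof, 1)
  expect_warning(c0 <- correlateComponents(pca0, fct0, fct0@probes[1:3]),
                 "zero-variance")
  expect_true(all(is.na(c0)))
})

test_that("component correlation is equivariant under component sign flips", {
  fct <- makeSmallFct(noiseSd = 0.3, seed = 6)
  prof <- buildDrugProfiles(fct, fct@probes)
  pca <- pcaDrugs(prof, 1)
  flipped <- pca
  flipped@scores <- -pca@scores
  flipped@loadings <- -pca@loadings
  a <- correlateComponents(pca, fct, fct@probes)
  b <- correlateComponents(flipped, fct, fct@probes)
  expect_equal(a, -b, tolerance = 1e-12)
})
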