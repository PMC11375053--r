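hexGrid <- function(extent, pitch = 100) {
  idx <- expand.grid(col = seq_len(extent), row = seq_len(extent))
  SpotGrid(sprintf("spot_%03d_%03d", idx$row, idx$col),
           (idx$col + 0.5 * (idx$row %% 2)) * pitch,
           idx$row * pitch * sqrt(3) / 2, platform = "visium-hex",
           pitch = pitch)
}

test_that("stereo binning sums counts in windows and flags partial bins", {
  # 250 x 250 raw spots at 0.5 um, binned by 100 -> 2x2 full + partial edge
  n <- 250
  idx <- expand.grid(x = seq_len(n) - 1, y = seq_len(n) - 1)
  grid <- SpotGrid(sprintf("r%06d", seq_len(n^2)), idx$x * 0.5, idx$y * 0.5,
                   platform = "stereo-raw", pitch = 0.5)
  counts <- Matrix::Matrix(1, nrow = 2, ncol = n^2, sparse = TRUE,
                           dimnames = list(c("gA", "gB"), spotIds(grid)))
  res <- binStereoSpots(counts, grid, binWidth = 100)
  expect_equal(gridPitch(res$grid), 50)
  full <- !res$partial
  expect_equal(sum(full), 4L)
  expect_true(all(res$counts["gA", full] == 10000))
  expect_true(all(res$counts["gA", res$partial] < 10000))
  # totals conserved
  expect_equal(sum(res$counts), sum(counts))
  expect_error(binStereoSpots(res$counts, res$grid), "already binned")
  expect_error(binStereoSpots(counts, grid, binWidth = 0), "positive")
  # random field: per-bin totals equal brute-force window sums
  withr::local_seed(5)
  rc <- counts
  rc[1, ] <- rpois(n^2, 2)
  res2 <- binStereoSpots(rc, grid, binWidth = 100)
  key <- paste(floor(idx$x * 0.5 / 50), floor(idx$y * 0.5 / 50), sep = "_")
  brute <- tapply(as.numeric(rc[1, ]), key, sum)
  expect_equal(as.numeric(res2$counts[1, paste0("bin_", names(brute))]),
               as.numeric(brute))
})

test_that("region calling follows z thresholds and tie precedence", {
  sc <- rbind(c(3, 0, 0),   # clear TCA
              c(0, 3, 0),   # clear TLS (B)
              c(0, 0, 3),   # clear TLS (T)
              c(0, 0, 0),   # stroma
              matrix(0, 8, 3))
  sc <- sc + matrix(rnorm(36, 0, 0.01), 12, 3)
  colnames(sc) <- c("malignant", "B", "T")
  rownames(sc) <- sprintf("s%02d", 1:12)
  r <- callRegions(sc, zThreshold = 0.5)
  expect_equal(as.character(r[1:4]), c("TCA", "TLS", "TLS", "stroma"))
  # exact tie of malignant and B above threshold -> TCA
  scTie <- matrix(0, 6, 3, dimnames = list(sprintf("t%d", 1:6),
                                           c("malignant", "B", "T")))
  scTie[, "malignant"] <- c(5, 0.01, 0.02, 0.03, 0.04, 0.05)
  scTie[, "B"] <- scTie[, "malignant"]  # identical columns -> exact z tie
  scTie[, "T"] <- c(0.1, 0.2, 0.15, 0.12, 0.18, 0.11)
  rTie <- callRegions(scTie, zThreshold = 0.5)
  expect_equal(as.character(rTie[1]), "TCA")
  # constant score column is rejected
  scConst <- sc; scConst[, "B"] <- 1
  expect_error(callRegions(scConst), "constant")
  expect_error(callRegions(sc[, 1:2]), "malignant, B, T")
})

test_that("TCA components match flood fill and are stable under spot permutation", {
  withr::local_seed(6)
  for (platform in c("hex", "square")) {
    extent <- 12
    grid <- if (platform == "hex") hexGrid(extent) else {
      idx <- expand.grid(col = seq_len(extent), row = seq_len(extent))
      SpotGrid(sprintf("spot_%03d_%03d", idx$row, idx$col),
               idx$col * 49.72, idx$row * 49.72, platform = "square",
               pitch = 49.72)
    }
    for (i in 1:5) {
      regions <- factor(sample(c("TCA", "stroma"), length(grid), TRUE,
                               prob = c(0.4, 0.6)),
                        levels = c("TLS", "TCA", "stroma"))
      names(regions) <- spotIds(grid)
      comp <- findTcaComponents(regions, grid)
      oracle <- oracleComponents(regions, grid)
      expect_identical(comp, oracle)
      # permuted spot order: identical partition and labels per spot id
      perm <- sample(length(grid))
      gridP <- SpotGrid(spotIds(grid)[perm], spotCoords(grid)[perm, 1],
                        spotCoords(grid)[perm, 2], platform = gridPlatform(grid),
                        pitch = gridPitch(grid))
      compP <- findTcaComponents(regions[perm], gridP)
      expect_identical(compP[names(comp)], comp)
    }
  }
})

test_that("isolated and distant TCA spots form separate components", {
  grid <- hexGrid(8)
  regions <- factor(rep("stroma", length(grid)),
                    levels = c("TLS", "TCA", "stroma"))
  names(regions) <- spotIds(grid)
  regions["spot_002_002"] <- "TCA"
  comp <- findTcaComponents(regions, grid)
  expect_equal(sum(!is.na(comp)), 1L)
  regions["spot_002_005"] <- "TCA"  # 3 pitches away
  comp2 <- findTcaComponents(regions, grid)
  expect_equal(length(unique(comp2[!is.na(comp2)])), 2L)
})

test_that("EBV quartile stratification matches the quantile definition", {
  comp <- setNames(rep(1:4, each = 25), sprintf("s%03d", 1:100))
  score <- setNames(sample(1:100), names(comp))
  res <- stratifyEbv(comp, score)
  expect_equal(sum(res$spotClass == "high"), 25)
  expect_equal(sum(res$spotClass == "low"), 25)
  expect_equal(sum(res$spotClass == "mid"), 50)
  # brute-force quantile oracle on random scores
  withr::local_seed(8)
  for (i in 1:5) {
    s2 <- setNames(rnorm(100), names(comp))
    r2 <- stratifyEbv(comp, s2)
    qs <- quantile(s2, c(0.25, 0.75))
    expect_equal(as.character(r2$spotClass),
                 unname(ifelse(s2 > qs[2], "high",
                               ifelse(s2 < qs[1], "low", "mid"))))
  }
  # all-equal scores -> all mid
  rEq <- stratifyEbv(comp, setNames(rep(1, 100), names(comp)))
  expect_true(all(rEq$spotClass == "mid"))
  # < 4 TCA spots -> warning, all mid
  small <- setNames(c(1L, 1L, 2L), c("a", "b", "c"))
  expect_warning(rSm <- stratifyEbv(small, setNames(1:3, c("a", "b", "c"))),
                 "fewer than 4")
  expect_true(all(rSm$componentClass$ebvClass == "mid"))
})

test_that("quartile spot counts stay within one of n/4 for distinct scores", {
  comp <- setNames(rep(1L, 37), sprintf("s%02d", 1:37))
  withr::local_seed(9)
  for (n in c(17, 37, 80)) {
    cmp <- setNames(rep(1L, n), sprintf("s%03d", 1:n))
    sc <- setNames(rnorm(n), names(cmp))
    r <- stratifyEbv(cmp, sc)
    expect_lte(abs(sum(r$spotClass == "high") - floor(n / 4)), 1)
    expect_lte(abs(sum(r$spotClass == "low") - floor(n / 4)), 1)
  }
})

test_that("plasma co-occurrence uses the occupancy quantile with a halo", {
  grid <- hexGrid(10)
  comp <- rep(NA_integer_, length(grid))
  names(comp) <- spotIds(grid)
  comp[c("spot_002_002", "spot_002_003")] <- 1L
  comp["spot_008_008"] <- 2L
  plasma <- setNames(rep(0, length(grid)), spotIds(grid))
  plasma["spot_003_002"] <- 10  # one pitch from component 1
  plasma <- plasma + seq_along(plasma) * 1e-9  # break ties, keep order
  res <- classifyPlasmaCooccurrence(comp, plasma, grid, q = 0.99)
  expect_equal(res$plasmaFlag[res$component == 1], "wP")
  expect_equal(res$plasmaFlag[res$component == 2], "woP")
  # q = 0 -> every component wP
  res0 <- classifyPlasmaCooccurrence(comp, plasma, grid, q = 0)
  expect_true(all(res0$plasmaFlag == "wP"))
})

test_that("apoptosis comparison summarises classes and ranks the planted uplift", {
  withr::local_seed(12)
  spots <- sprintf("s%03d", 1:80)
  region <- factor(rep("TCA", 80), levels = c("TLS", "TCA", "stroma"))
  names(region) <- spots
  compId <- setNames(rep(1:4, each = 20), spots)
  cc <- data.frame(component = 1:4,
                   ebvClass = c("high", "high", "low", "low"),
                   plasmaFlag = c("wP", "woP", "wP", "woP"))
  cmap <- new("CompartmentMap", region = region, componentId = compId,
              componentClass = cc)
  score <- setNames(rnorm(80, 0, 0.1), spots)
  score[compId == 1] <- score[compId == 1] + 2   # planted uplift in high-wP
  res <- compareApoptosis(cmap, score)
  expect_equal(res$topClass, "EBVhigh-wP")
  expect_equal(nrow(res$tests), 6)
  expect_true(all(c("n", "mean", "median", "IQR") %in% colnames(res$summary)))
  pHW <- res$tests$pValue[res$tests$classA == "EBVhigh-wP" |
                            res$tests$classB == "EBVhigh-wP"]
  expect_true(all(pHW < 0.01))
  # a single class is an error
  one <- new("CompartmentMap", region = region, componentId = compId,
             componentClass = data.frame(component = 1:4,
                                         ebvClass = "high",
                                         plasmaFlag = "wP"))
  expect_error(compareApoptosis(one, score), "at least 2")
})

test_that("normalised connection and infiltration bins follow their closed forms", {
  expect_equal(normalizedConnection(6, 2, 3), 1)
  expect_equal(normalizedConnection(0, 5, 7), 0)
  expect_equal(normalizedConnection(6, 2, 3), normalizedConnection(6, 3, 2))
  expect_error(normalizedConnection(1, 0, 3), "at least 1")
  expect_equal(infiltrationBin(c(0, 0.10, 0.25, 0.26, 0.5, 0.60, 0.75, 0.76, 1)),
               c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_error(infiltrationBin(1.2), "\\[0, 1\\]")
})
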