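#' Default planted compartment layout
#'
#' Sixteen disc positions on a fractional lattice of the grid: eight TCA
#' discs spanning the EBV classes (2 high, 4 mid, 2 low; half with plasma
#' co-occurrence), four TLS discs, and two stromal plasma patches (plasma
#' cells also populate TLS and stroma in these tumours, which keeps the
#' plasma-high area above the default occupancy quantile). Disc radius
#' scales with the grid so compartments stay separated by more than one
#' lattice neighbourhood.
#'
#' @param extent spots per grid side (at least 8).
#' @return list of compartment descriptors (`region`, `ebv`, `plasma`,
#'   `centre` = c(row, col), `radius`), in spot units.
#' @export
defaultCompartmentLayout <- function(extent) {
  stopifnot(extent >= 8)
  radius <- 0.0975 * extent
  pos <- round(extent * c(0.15, 0.40, 0.65, 0.90))
  # rounding can push an edge disc off the grid; clamp centres inward
  pos <- pmin(pmax(pos, ceiling(radius + 0.5)), floor(extent + 0.5 - radius))
  centres <- expand.grid(row = pos, col = pos)
  spec <- list(
    list("TCA", "high", TRUE),  list("TCA", "high", FALSE),
    list("TCA", "mid",  TRUE),  list("TCA", "mid",  FALSE),
    list("TLS", "none", TRUE),  list("stroma", "none", TRUE),
    list("TCA", "mid",  TRUE),  list("TCA", "mid",  FALSE),
    list("TCA", "low",  TRUE),  list("TCA", "low",  FALSE),
    list("TLS", "none", TRUE),  list("stroma", "none", TRUE),
    list("TLS", "none", TRUE),  list("TLS", "none", TRUE))
  lapply(seq_along(spec), function(i) {
    list(region = spec[[i]][[1L]], ebv = spec[[i]][[2L]],
         plasma = spec[[i]][[3L]],
         centre = c(centres$row[i], centres$col[i]), radius = radius)
  })
}

#' Configuration for the spatial simulator
#'
#' Bundles and validates the parameters of [generateSpatialSample()]. The
#' geometry follows the two platforms analysed: offset-row hexagonal
#' lattice at 100 micron pitch (Visium) or square lattice at 49.72 micron
#' pitch (Stereo-seq bin100). Counts are negative binomial with
#' `variance = mu + mu^2 / dispersion`; per-spot sequencing depth is
#' log-normal around `depth`.
#'
#' @param geometry `"hex"` (100 um pitch) or `"square"` (49.72 um pitch).
#' @param extent spots per side (>= 8).
#' @param compartments planted disc list; default
#'   [defaultCompartmentLayout()]. Overlapping discs with conflicting
#'   labels are rejected at generation time.
#' @param nGenes total gene count.
#' @param markersPerRole marker genes allocated to each of the roles
#'   malignant, B, T, EBV, plasma, apoptosis.
#' @param foldChange multiplicative up-regulation of marker genes inside
#'   their compartment (>= 1).
#' @param dispersion negative-binomial dispersion (theta > 0).
#' @param depth mean UMIs per spot.
#' @param libsizeSigma log-normal sigma of per-spot depth (default 0.3).
#' @param apoptosisFoldChange apoptosis up-regulation in plasma-flagged
#'   TCAs, further scaled by EBV level via `ebvApoptosisScale`.
#' @param ebvApoptosisScale named scale (low/mid/high) weighting the
#'   apoptosis uplift by EBV class.
#' @param seed integer seed.
#' @return validated config (list).
#' @export
spatialSimConfig <- function(geometry = c("hex", "square"), extent = 40,
                             compartments = defaultCompartmentLayout(extent),
                             nGenes = 600, markersPerRole = 25,
                             foldChange = 8, dispersion = 2, depth = 5000,
                             libsizeSigma = 0.3, apoptosisFoldChange = 2,
                             ebvApoptosisScale = c(low = 1, mid = 1.25,
                                                   high = 1.5),
                             seed = 1) {
  geometry <- match.arg(geometry)
  stopifnot(extent >= 8, foldChange >= 1, dispersion > 0, depth > 0,
            libsizeSigma >= 0, nGenes >= 6 * markersPerRole)
  for (cp in compartments) {
    stopifnot(cp$region %in% c("TCA", "TLS", "stroma"),
              cp$ebv %in% c("high", "mid", "low", "none"),
              is.logical(cp$plasma), length(cp$centre) == 2L, cp$radius > 0)
    if (any(cp$centre - cp$radius < 0.5) ||
        any(cp$centre + cp$radius > extent + 0.5))
      stop("compartment disc extends outside the grid")
  }
  list(geometry = geometry, extent = extent, compartments = compartments,
       nGenes = nGenes, markersPerRole = markersPerRole,
       foldChange = foldChange, dispersion = dispersion, depth = depth,
       libsizeSigma = libsizeSigma,
       apoptosisFoldChange = apoptosisFoldChange,
       ebvApoptosisScale = ebvApoptosisScale, seed = seed)
}

# Build the spot lattice for a geometry: hex = offset rows, pitch 100 um;
# square = 49.72 um pitch.
.makeGrid <- function(geometry, extent) {
  idx <- expand.grid(col = seq_len(extent), row = seq_len(extent))
  if (geometry == "hex") {
    pitch <- 100
    x <- (idx$col + 0.5 * (idx$row %% 2)) * pitch
    y <- idx$row * pitch * sqrt(3) / 2
    platform <- "visium-hex"
  } else {
    pitch <- 49.72
    x <- idx$col * pitch
    y <- idx$row * pitch
    platform <- "square"
  }
  ids <- sprintf("spot_%03d_%03d", idx$row, idx$col)
  list(grid = SpotGrid(ids, x, y, platform = platform, pitch = pitch),
       row = idx$row, col = idx$col)
}

#' Simulate a spatial transcriptomic sample with planted compartments
#'
#' Generates negative-binomial spot counts on a hex or square lattice with
#' planted TLS/TCA/stroma discs. Marker genes of a region's role are
#' up-regulated by the fold-change inside that region; EBV-signature genes
#' are scaled by the planted EBV level (fold-change to the powers 0.5, 1,
#' 1.5 for low/mid/high); plasma-spot genes are up-regulated in
#' plasma-flagged discs, and apoptosis genes in plasma-flagged TCAs
#' (graded by EBV level). Identical config and seed give identical output.
#'
#' @param config from [spatialSimConfig()].
#' @return list with `counts` (sparse gene x spot), `grid`
#'   ([SpotGrid-class]), `signatures` ([SignatureSet-class] of the planted
#'   marker sets, named as [callCompartments()] expects) and `truth`
#'   (list: per-spot `region`, `component`, and per-component table
#'   `components` with `component`, `ebvClass`, `plasmaFlag`).
#' @export
generateSpatialSample <- function(config) {
  ge <- .makeGrid(config$geometry, config$extent)
  nSpot <- length(ge$grid)
  # planted disc membership in integer (row, col) index space
  discOf <- rep(NA_integer_, nSpot)
  for (i in seq_along(config$compartments)) {
    cp <- config$compartments[[i]]
    inDisc <- (ge$row - cp$centre[1L])^2 + (ge$col - cp$centre[2L])^2 <=
      cp$radius^2
    clash <- inDisc & !is.na(discOf)
    if (any(clash)) {
      other <- config$compartments[[discOf[which(clash)[1L]]]]
      if (!identical(other[c("region", "ebv", "plasma")],
                     cp[c("region", "ebv", "plasma")]))
        stop("overlapping compartment discs with conflicting labels")
    }
    discOf[inDisc & is.na(discOf)] <- i
  }
  region <- rep("stroma", nSpot)
  ebv <- rep("none", nSpot)
  plasma <- rep(FALSE, nSpot)
  for (i in seq_along(config$compartments)) {
    cp <- config$compartments[[i]]
    sel <- which(discOf == i)
    region[sel] <- cp$region
    ebv[sel] <- cp$ebv
    plasma[sel] <- cp$plasma
  }
  k <- config$markersPerRole
  roles <- c("malignant", "B", "T", "ebv", "plasma", "apoptosis")
  geneNames <- c(unlist(lapply(roles, function(r)
    sprintf("%s_g%03d", toupper(r), seq_len(k)))),
    sprintf("BG_g%04d", seq_len(config$nGenes - 6L * k)))
  roleOf <- c(rep(roles, each = k),
              rep("background", config$nGenes - 6L * k))
  fc <- config$foldChange
  ebvMult <- c(none = 1, low = fc^0.5, mid = fc, high = fc^1.5)
  apoScale <- config$ebvApoptosisScale
  out <- withSeed(config$seed, {
    base <- exp(rnorm(config$nGenes, 0, 1))
    mult <- matrix(1, nrow = config$nGenes, ncol = nSpot)
    isTCA <- region == "TCA"
    isTLS <- region == "TLS"
    mult[roleOf == "malignant", isTCA] <- fc
    mult[roleOf == "B", isTLS] <- fc
    mult[roleOf == "T", isTLS] <- fc
    mult[roleOf == "ebv", ] <- rep(ebvMult[ebv], each = k)
    mult[roleOf == "plasma", plasma] <- fc
    wp <- isTCA & plasma
    if (any(wp)) {
      sc <- apoScale[ebv[wp]]
      mult[roleOf == "apoptosis", wp] <-
        rep(config$apoptosisFoldChange * sc, each = k)
    }
    w <- base * mult
    depth <- config$depth *
      exp(rnorm(nSpot, -config$libsizeSigma^2 / 2, config$libsizeSigma))
    mu <- sweep(w, 2L, depth / colSums(w), "*")
    counts <- matrix(rnbinom(length(mu), mu = as.numeric(mu),
                             size = config$dispersion),
                     nrow = config$nGenes,
                     dimnames = list(geneNames, spotIds(ge$grid)))
    counts
  })
  sigs <- SignatureSet(
    setNames(lapply(roles, function(r) geneNames[roleOf == r]), roles),
    setNames(c("malignant", "B", "T", "EBV", "plasma", "apoptosis"), roles))
  tcaDiscs <- which(vapply(config$compartments,
                           function(cp) cp$region == "TCA", logical(1L)))
  compTab <- data.frame(
    component = tcaDiscs,
    ebvClass = vapply(config$compartments[tcaDiscs], `[[`, "", "ebv"),
    plasmaFlag = ifelse(vapply(config$compartments[tcaDiscs], `[[`,
                               logical(1L), "plasma"), "wP", "woP"),
    stringsAsFactors = FALSE)
  truthComponent <- ifelse(!is.na(discOf) & region == "TCA", discOf,
                           NA_integer_)
  list(counts = methods::as(out, "CsparseMatrix"), grid = ge$grid,
       signatures = sigs,
       truth = list(region = setNames(region, spotIds(ge$grid)),
                    component = setNames(truthComponent, spotIds(ge$grid)),
                    components = compTab))
}

#' Simulate cluster-labelled single cells
#'
#' Negative-binomial counts for cells from at least two clusters, each
#' cluster's marker genes up-regulated by the effect size.
#'
#' @param nCellsPerCluster named integer vector (names = cluster labels).
#' @param markerMap named list mapping each cluster to its marker genes
#'   (non-empty).
#' @param nBackground background gene count added to the marker universe.
#' @param effectSize fold-change of a cluster's markers in that cluster.
#' @param dispersion NB dispersion.
#' @param depth mean UMIs per cell.
#' @param seed integer seed.
#' @return list with `counts` (sparse gene x cell) and `truth` (named
#'   cluster factor per cell).
#' @export
generateSingleCells <- function(nCellsPerCluster, markerMap,
                                nBackground = 200, effectSize = 4,
                                dispersion = 2, depth = 2000, seed = 1) {
  clusters <- names(nCellsPerCluster)
  if (length(clusters) < 2L) stop("at least 2 clusters required")
  if (!all(clusters %in% names(markerMap)))
    stop("markerMap must cover every cluster")
  if (any(vapply(markerMap[clusters], length, integer(1L)) == 0L))
    stop("empty marker list for a cluster")
  genes <- c(unique(unlist(markerMap[clusters])),
             sprintf("BG_g%04d", seq_len(nBackground)))
  cellCluster <- rep(clusters, times = nCellsPerCluster)
  cellIds <- sprintf("cell_%05d", seq_along(cellCluster))
  withSeed(seed, {
    base <- exp(rnorm(length(genes), 0, 1))
    mult <- matrix(1, nrow = length(genes), ncol = length(cellCluster),
                   dimnames = list(genes, cellIds))
    for (cl in clusters) {
      mult[markerMap[[cl]], cellCluster == cl] <- effectSize
    }
    w <- base * mult
    dep <- depth * exp(rnorm(length(cellCluster), -0.045, 0.3))
    mu <- sweep(w, 2L, dep / colSums(w), "*")
    counts <- matrix(rnbinom(length(mu), mu = as.numeric(mu),
                             size = dispersion),
                     nrow = length(genes),
                     dimnames = dimnames(mult))
    list(counts = methods::as(counts, "CsparseMatrix"),
         truth = setNames(factor(cellCluster), cellIds))
  })
}

#' Simulate a BCR/TCR repertoire table
#'
#' Cells in each cluster draw clonotypes from a cluster-private pool with
#' power-law clone sizes. A sharing matrix plants clonotype sharing:
#' `sharing[A, B]` is the probability that a cell of cluster B carries a
#' clonotype drawn from cluster A's top-10 clonotypes. SHM frequencies are
#' zero with probability `shmZeroProb` and Beta otherwise; isotypes are
#' multinomial.
#'
#' @param nCellsPerCluster named integer vector.
#' @param sharing square numeric matrix in \[0,1\] with cluster names on
#'   both dimensions (diagonal ignored); off-diagonal column sums must
#'   not exceed 1.
#' @param powerLawExponent clone-size power-law exponent (default 1.5).
#' @param shmBeta length-2 Beta parameters of nonzero SHM frequencies.
#' @param shmZeroProb probability of SHM exactly 0 ("none" bin).
#' @param isotypeProportions named numeric summing to 1 (tolerance 1e-9).
#' @param seed integer seed.
#' @return data.frame with columns `cell`, `cluster`, `clonotype`,
#'   `isotype`, `shmFreq`, `sample`.
#' @export
generateRepertoire <- function(nCellsPerCluster,
                               sharing = NULL,
                               powerLawExponent = 1.5,
                               shmBeta = c(0.8, 40),
                               shmZeroProb = 0.2,
                               isotypeProportions = c(IGHA1 = 0.3,
                                                      IGHG1 = 0.3,
                                                      IGHM = 0.4),
                               seed = 1) {
  clusters <- names(nCellsPerCluster)
  if (is.null(sharing)) {
    sharing <- matrix(0, length(clusters), length(clusters),
                      dimnames = list(clusters, clusters))
  }
  stopifnot(all(sharing >= 0), all(sharing <= 1),
            identical(rownames(sharing), clusters),
            identical(colnames(sharing), clusters))
  offDiag <- sharing; diag(offDiag) <- 0
  if (any(colSums(offDiag) > 1))
    stop("total sharing into a cluster exceeds 1")
  if (abs(sum(isotypeProportions) - 1) > 1e-9)
    stop("isotype proportions must sum to 1")
  withSeed(seed, {
    pools <- lapply(clusters, function(cl) {
      k <- max(1L, round(nCellsPerCluster[[cl]] / 2))
      p <- (seq_len(k))^(-powerLawExponent)
      list(ids = sprintf("%s_cl%04d", cl, seq_len(k)), p = p / sum(p))
    })
    names(pools) <- clusters
    # donor draws weighted by clone size so the planted rate concentrates
    # on clonotypes that stay in the donor's observed top ranks
    top10 <- lapply(pools, function(pl) {
      ids <- utils::head(pl$ids, 10L)
      list(ids = ids, p = pl$p[seq_along(ids)] / sum(pl$p[seq_along(ids)]))
    })
    rows <- lapply(clusters, function(cl) {
      n <- nCellsPerCluster[[cl]]
      src <- offDiag[, cl]
      probs <- c(src[src > 0], own = 1 - sum(src))
      srcNames <- c(names(src)[src > 0], "own")
      pick <- sample(srcNames, n, replace = TRUE, prob = probs)
      clt <- character(n)
      ownN <- sum(pick == "own")
      clt[pick == "own"] <- sample(pools[[cl]]$ids, ownN, replace = TRUE,
                                   prob = pools[[cl]]$p)
      for (s in setdiff(unique(pick), "own")) {
        sel <- pick == s
        clt[sel] <- sample(top10[[s]]$ids, sum(sel), replace = TRUE,
                           prob = top10[[s]]$p)
      }
      data.frame(cluster = cl, clonotype = clt, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    n <- nrow(tab)
    shm <- ifelse(runif(n) < shmZeroProb, 0,
                  rbeta(n, shmBeta[1L], shmBeta[2L]))
    data.frame(cell = sprintf("cell_%05d", seq_len(n)),
               cluster = tab$cluster, clonotype = tab$clonotype,
               isotype = sample(names(isotypeProportions), n, replace = TRUE,
                                prob = isotypeProportions),
               shmFreq = pmin(shm, 1), sample = "sim",
               stringsAsFactors = FALSE)
  })
}

#' Simulate a phenotyped cell point pattern
#'
#' Anchors uniform in the field; a fraction `f` of targets is placed
#' uniformly inside radius `rAttract` of a randomly chosen anchor, the
#' remainder uniform in the field.
#'
#' @param nAnchors,nTargets point counts.
#' @param rAttract attraction radius (> 0).
#' @param f attraction fraction in \[0, 1\].
#' @param fieldSize length-2 field dimensions (or scalar for a square).
#' @param margin guard margin keeping points away from the field edge
#'   (default 0).
#' @param seed integer seed.
#' @return list with `anchors` and `targets` (data.frames with `x`, `y`)
#'   and `truth` (logical: target placed by attraction).
#' @export
generatePointPattern <- function(nAnchors, nTargets, rAttract, f,
                                 fieldSize = 1000, margin = 0, seed = 1) {
  if (rAttract <= 0) stop("attraction radius must be positive")
  stopifnot(f >= 0, f <= 1, all(fieldSize > 0), margin >= 0)
  if (length(fieldSize) == 1L) fieldSize <- rep(fieldSize, 2L)
  withSeed(seed, {
    runifIn <- function(n, lim) runif(n, margin, lim - margin)
    anchors <- data.frame(x = runifIn(nAnchors, fieldSize[1L]),
                          y = runifIn(nAnchors, fieldSize[2L]))
    attracted <- seq_len(nTargets) <= round(f * nTargets)
    x <- runifIn(nTargets, fieldSize[1L])
    y <- runifIn(nTargets, fieldSize[2L])
    if (any(attracted) && nAnchors > 0) {
      k <- sum(attracted)
      a <- sample.int(nAnchors, k, replace = TRUE)
      rad <- rAttract * sqrt(runif(k))
      ang <- runif(k, 0, 2 * pi)
      x[attracted] <- anchors$x[a] + rad * cos(ang)
      y[attracted] <- anchors$y[a] + rad * sin(ang)
    }
    list(anchors = anchors,
         targets = data.frame(x = x, y = y),
         truth = attracted)
  })
}

#' Simulate a survival cohort with a signature-dependent hazard
#'
#' Exponential event times with hazard `baselineHazard * exp(beta *
#' score)`, where the score is a balanced binary high-group indicator.
#' Censoring is independent uniform on (0, m), with m solved so the
#' expected censoring fraction matches `censoringRate`.
#'
#' @param n cohort size (>= 20).
#' @param beta log hazard ratio of the high group (e.g. `log(0.3)`).
#' @param baselineHazard events per time unit in the low group.
#' @param censoringRate target censoring fraction in \[0, 1).
#' @param seed integer seed.
#' @return list with `scores` (data.frame `sample`, `score`, `group`),
#'   `surv` (data.frame `sample`, `time`, `event`) and `truth` (the
#'   high-group indicator).
#' @export
generateSurvivalCohort <- function(n, beta, baselineHazard = 0.05,
                                   censoringRate = 0.3, seed = 1) {
  if (n < 20) stop("n must be at least 20")
  if (censoringRate < 0 || censoringRate >= 1)
    stop("censoring rate must lie in [0, 1)")
  withSeed(seed, {
    x <- rbinom(n, 1L, 0.5)
    h <- baselineHazard * exp(beta * x)
    tEvent <- rexp(n, rate = h)
    if (censoringRate > 0) {
      censFrac <- function(m) mean((1 - exp(-h * m)) / (h * m))
      m <- uniroot(function(m) censFrac(m) - censoringRate,
                   lower = 1e-6, upper = 1e6 / baselineHazard)$root
      cens <- runif(n, 0, m)
    } else cens <- rep(Inf, n)
    time <- pmin(tEvent, cens)
    event <- as.integer(tEvent <= cens)
    ids <- sprintf("s%04d", seq_len(n))
    list(scores = data.frame(sample = ids, score = x,
                             group = ifelse(x == 1, "high", "low"),
                             stringsAsFactors = FALSE),
         surv = data.frame(sample = ids, time = time, event = event,
                           stringsAsFactors = FALSE),
         truth = x)
  })
}

#' Simulate cells running a cyclic expression programme
#'
#' Each cell has a phase on the circle; each gene is a noisy sinusoid of
#' that phase with a random gene-specific phase shift and amplitude.
#' Used to exercise the germinal-centre polar embedding, whose angle
#' should recover the planted phases up to rotation and reflection.
#'
#' @param nCells,nGenes problem size.
#' @param noise Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return list with `expr` (gene x cell matrix) and `phase` (named
#'   planted phase per cell, radians).
#' @export
generateCyclicCells <- function(nCells = 500, nGenes = 40, noise = 0.3,
                                seed = 1) {
  withSeed(seed, {
    phase <- runif(nCells, 0, 2 * pi)
    genePhase <- runif(nGenes, 0, 2 * pi)
    amp <- runif(nGenes, 0.5, 1.5)
    expr <- amp * cos(outer(genePhase, phase, function(g, p) p - g)) +
      matrix(rnorm(nGenes * nCells, 0, noise), nGenes, nCells)
    dimnames(expr) <- list(sprintf("gene_%03d", seq_len(nGenes)),
                           sprintf("cell_%04d", seq_len(nCells)))
    list(expr = expr, phase = setNames(phase, colnames(expr)))
  })
}

#' Recovery metrics of a called compartment map against planted truth
#'
#' Spot-level region accuracy plus component-level EBV-class and plasma
#' recovery: every called TCA component is matched to the planted
#' component containing the majority of its spots, then classes are
#' compared.
#'
#' @param truth `truth` element from [generateSpatialSample()].
#' @param cmap called [CompartmentMap-class].
#' @return list with `regionAccuracy`, `componentTable` (one row per
#'   called component: truth match, truth and called classes),
#'   `ebvAccuracy`, `plasmaAccuracy` and `fourClassAccuracy` (joint
#'   EBV x plasma over components planted high or low).
#' @export
evaluateCompartmentRecovery <- function(truth, cmap) {
  called <- as.data.frame(cmap)
  regionAcc <- mean(called$region == truth$region[called$spot])
  comps <- componentClasses(cmap)
  rowsL <- lapply(comps$component, function(cp) {
    spots <- called$spot[!is.na(called$component) & called$component == cp]
    tr <- truth$component[spots]
    tr <- tr[!is.na(tr)]
    if (length(tr) == 0L) return(NULL)
    best <- as.integer(names(which.max(table(tr))))
    ti <- truth$components[truth$components$component == best, ]
    data.frame(called = cp, truthComponent = best,
               truthEbv = ti$ebvClass, truthPlasma = ti$plasmaFlag,
               calledEbv = comps$ebvClass[comps$component == cp],
               calledPlasma = comps$plasmaFlag[comps$component == cp],
               stringsAsFactors = FALSE)
  })
  ct <- do.call(rbind, rowsL)
  hl <- ct[ct$truthEbv %in% c("high", "low"), , drop = FALSE]
  list(regionAccuracy = regionAcc, componentTable = ct,
       ebvAccuracy = mean(ct$calledEbv == ct$truthEbv),
       plasmaAccuracy = mean(ct$calledPlasma == ct$truthPlasma),
       fourClassAccuracy = mean(hl$calledEbv == hl$truthEbv &
                                  hl$calledPlasma == hl$truthPlasma))
}
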