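#' Configuration for the synthetic tissue generator
#'
#' Defines a simulated tissue section: disk vessels surrounded by
#' perivascular membrane annuli, cuff-confined T cells placed uniformly
#' inside the annuli, stromal T cells from a Thomas cluster process, a
#' gemistocytic tumor cell (GTC) intensity that decays with distance to
#' cuff vessels, TAMs whose intensity is coupled to the local GTC
#' gradient, and homogeneous Poisson background phenotypes.
#'
#' Intensities are expected cells per mm^2. The annulus outer radius must
#' exceed the vessel radius.
#'
#' @param width,height domain size (micrometres).
#' @param nVessels number of vessels to place.
#' @param vesselRadius vessel (lumen) radius (micrometres).
#' @param annulusOuter outer radius of the perivascular annulus
#'   (micrometres); must exceed \code{vesselRadius}.
#' @param intensities named vector of homogeneous background intensities
#'   (cells per mm^2) for non-gradient phenotypes.
#' @param gtcIntensity GTC intensity at the vessel wall (cells per mm^2).
#' @param gtcDecay decay length (micrometres) of the GTC intensity with
#'   distance to the nearest cuff vessel; \code{Inf} gives a flat GTC
#'   field and disables TAM coupling.
#' @param cuffTPerVessel exact number of cuff T cells placed uniformly in
#'   each annulus.
#' @param tParentIntensity,tOffspringMean,tOffspringSigma Thomas-process
#'   parameters for stromal T cells: parent intensity (per mm^2), mean
#'   offspring per parent, offspring dispersion (micrometres).
#' @param tamIntensity baseline TAM intensity (cells per mm^2).
#' @param tamCoupling multiplier linking TAM intensity to the normalised
#'   local GTC intensity: lambda_TAM(x) = baseline * (1 + coupling * g(x)).
#' @param cd4Fraction probability a simulated T cell is CD4 (vs CD8).
#' @param seed master seed; each generator stage derives its own stream.
#' @return a validated \code{TissueConfig} list.
#' @export
tissueConfig <- function(width = 2000, height = 2000,
                         nVessels = 8, vesselRadius = 30,
                         annulusOuter = 90,
                         intensities = c(TumorCell = 350, Other = 80,
                                         BCell = 10),
                         gtcIntensity = 250, gtcDecay = 300,
                         cuffTPerVessel = 12,
                         tParentIntensity = 1.5, tOffspringMean = 6,
                         tOffspringSigma = 40,
                         tamIntensity = 120, tamCoupling = 1.5,
                         cd4Fraction = 0.6, seed = 1L) {
  cfg <- list(width = width, height = height, nVessels = nVessels,
              vesselRadius = vesselRadius, annulusOuter = annulusOuter,
              intensities = intensities, gtcIntensity = gtcIntensity,
              gtcDecay = gtcDecay, cuffTPerVessel = cuffTPerVessel,
              tParentIntensity = tParentIntensity,
              tOffspringMean = tOffspringMean,
              tOffspringSigma = tOffspringSigma,
              tamIntensity = tamIntensity, tamCoupling = tamCoupling,
              cd4Fraction = cd4Fraction, seed = as.integer(seed))
  if (width <= 0 || height <= 0) stop("config error: domain must be positive")
  if (annulusOuter <= vesselRadius)
    stop("config error: annulus outer radius must exceed vessel radius")
  ints <- c(intensities, gtcIntensity, tParentIntensity, tamIntensity)
  if (any(ints < 0)) stop("config error: intensities must be >= 0")
  if (cuffTPerVessel < 0 || nVessels < 0)
    stop("config error: counts must be >= 0")
  class(cfg) <- "TissueConfig"
  cfg
}

# Homogeneous Poisson points on [0,w] x [0,h]; intensity in cells/mm^2.
rPoissonPoints <- function(intensityPerMm2, w, h) {
  lam <- intensityPerMm2 * 1e-6 * w * h
  n <- rpois(1L, lam)
  cbind(runif(n, 0, w), runif(n, 0, h))
}

# Thomas cluster process: Poisson parents, Poisson offspring counts,
# Gaussian dispersion; offspring outside the domain are discarded.
rThomasPoints <- function(parentIntensityPerMm2, offspringMean, sigma,
                          w, h) {
  parents <- rPoissonPoints(parentIntensityPerMm2, w, h)
  if (nrow(parents) == 0L) return(cbind(numeric(0), numeric(0)))
  counts <- rpois(nrow(parents), offspringMean)
  tot <- sum(counts)
  if (tot == 0L) return(cbind(numeric(0), numeric(0)))
  px <- rep(parents[, 1], counts) + rnorm(tot, 0, sigma)
  py <- rep(parents[, 2], counts) + rnorm(tot, 0, sigma)
  keep <- px >= 0 & px <= w & py >= 0 & py <= h
  cbind(px[keep], py[keep])
}

# Normalised local GTC gradient around cuff vessels, in [0, 1].
gtcGradient <- function(pts, vesselCenters, vesselRadius, decay) {
  if (is.infinite(decay) || nrow(vesselCenters) == 0L)
    return(rep(0, nrow(pts)))
  d <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(vesselCenters))) {
    di <- sqrt((pts[, 1] - vesselCenters[i, 1])^2 +
               (pts[, 2] - vesselCenters[i, 2])^2) - vesselRadius
    d <- pmin(d, pmax(di, 0))
  }
  exp(-d / decay)
}

#' Simulate a tissue section with vessels, perivascular annuli and cells
#'
#' Generates the point pattern and geometry the downstream analyses
#' assume: vessels as disks, membranes as annuli around them, cuff T
#' cells uniform inside the annuli, stromal T cells from a Thomas
#' process, GTCs from an inhomogeneous Poisson process whose intensity
#' decays with distance to the cuff vessels (simulated by thinning), and
#' TAMs whose intensity is multiplied by \code{1 + coupling * g(x)} with
#' \code{g} the normalised GTC gradient. Identical config and seed give
#' identical output; every stage draws from its own named substream.
#'
#' @param cfg a \code{\link{tissueConfig}}.
#' @return list with \code{cells} (\code{CellMap}), \code{vessels} and
#'   \code{membranes} (lists of \code{MembraneHull}), and \code{truth}
#'   (character vector naming the generating process per cell:
#'   \code{cuff_t}, \code{stromal_t}, \code{gtc}, \code{tam},
#'   \code{background}).
#' @examples
#' sim <- simulateTissue(tissueConfig(width = 800, height = 800,
#'                                    nVessels = 2, seed = 7))
#' sim$cells
#' @export
simulateTissue <- function(cfg) {
  stopifnot(inherits(cfg, "TissueConfig"))
  w <- cfg$width; h <- cfg$height
  rv <- cfg$vesselRadius; ra <- cfg$annulusOuter

  centers <- withSeed(stageSeed(cfg$seed, "vessels"), {
    placed <- matrix(numeric(0), ncol = 2)
    margin <- min(ra, w / 2, h / 2)
    tries <- 0L
    while (nrow(placed) < cfg$nVessels && tries < 2000L) {
      tries <- tries + 1L
      cand <- c(runif(1, margin, w - margin), runif(1, margin, h - margin))
      if (nrow(placed) == 0L ||
          all(sqrt((placed[, 1] - cand[1])^2 +
                   (placed[, 2] - cand[2])^2) > 2.2 * ra))
        placed <- rbind(placed, cand)
    }
    placed
  })
  if (nrow(centers) < cfg$nVessels)
    warning(sprintf("placed %d of %d requested vessels", nrow(centers),
                    cfg$nVessels))
  vessels <- lapply(seq_len(nrow(centers)), function(i)
    MembraneHull(circleRing(centers[i, ], rv), marker = "CD31"))
  membranes <- lapply(seq_len(nrow(centers)), function(i)
    MembraneHull(circleRing(centers[i, ], ra),
                 holes = list(circleRing(centers[i, ], rv)),
                 marker = "LAMA2"))

  pts <- list(); truth <- list(); pheno <- list()

  # cuff T cells: exact count per vessel, uniform by area in the annulus
  # (radius capped at the annulus polygon's apothem so containment in the
  # polygonal ring is exact)
  if (nrow(centers) > 0L && cfg$cuffTPerVessel > 0L) {
    cuff <- withSeed(stageSeed(cfg$seed, "cuffT"), {
      raEff <- ra * cos(pi / 64) * (1 - 1e-9)
      do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
        n <- cfg$cuffTPerVessel
        r <- sqrt(runif(n, rv^2, raEff^2))
        th <- runif(n, 0, 2 * pi)
        cbind(centers[i, 1] + r * cos(th), centers[i, 2] + r * sin(th))
      }))
    })
    pts <- c(pts, list(cuff))
    truth <- c(truth, list(rep("cuff_t", nrow(cuff))))
    pheno <- c(pheno, list(rep(NA_character_, nrow(cuff))))
  }

  stromal <- withSeed(stageSeed(cfg$seed, "stromalT"),
                      rThomasPoints(cfg$tParentIntensity, cfg$tOffspringMean,
                                    cfg$tOffspringSigma, w, h))
  if (nrow(stromal) > 0L) {
    pts <- c(pts, list(stromal))
    truth <- c(truth, list(rep("stromal_t", nrow(stromal))))
    pheno <- c(pheno, list(rep(NA_character_, nrow(stromal))))
  }

  gtc <- withSeed(stageSeed(cfg$seed, "gtc"), {
    cand <- rPoissonPoints(cfg$gtcIntensity, w, h)
    if (nrow(cand) > 0L && is.finite(cfg$gtcDecay)) {
      keep <- runif(nrow(cand)) <
        gtcGradient(cand, centers, rv, cfg$gtcDecay)
      cand <- cand[keep, , drop = FALSE]
    }
    cand
  })
  if (nrow(gtc) > 0L) {
    pts <- c(pts, list(gtc))
    truth <- c(truth, list(rep("gtc", nrow(gtc))))
    pheno <- c(pheno, list(rep("GTC", nrow(gtc))))
  }

  tam <- withSeed(stageSeed(cfg$seed, "tam"), {
    cand <- rPoissonPoints(cfg$tamIntensity * (1 + cfg$tamCoupling), w, h)
    if (nrow(cand) > 0L) {
      g <- gtcGradient(cand, centers, rv, cfg$gtcDecay)
      keep <- runif(nrow(cand)) <
        (1 + cfg$tamCoupling * g) / (1 + cfg$tamCoupling)
      cand <- cand[keep, , drop = FALSE]
    }
    cand
  })
  if (nrow(tam) > 0L) {
    pts <- c(pts, list(tam))
    truth <- c(truth, list(rep("tam", nrow(tam))))
    pheno <- c(pheno, list(rep("TAM", nrow(tam))))
  }

  bg <- withSeed(stageSeed(cfg$seed, "background"), {
    lapply(names(cfg$intensities), function(ph)
      rPoissonPoints(cfg$intensities[[ph]], w, h))
  })
  for (i in seq_along(bg)) {
    if (nrow(bg[[i]]) > 0L) {
      pts <- c(pts, list(bg[[i]]))
      truth <- c(truth, list(rep("background", nrow(bg[[i]]))))
      pheno <- c(pheno, list(rep(names(cfg$intensities)[i], nrow(bg[[i]]))))
    }
  }

  xy <- if (length(pts)) do.call(rbind, pts) else cbind(numeric(0), numeric(0))
  truth <- unlist(truth, use.names = FALSE)
  pheno <- unlist(pheno, use.names = FALSE)
  if (is.null(truth)) truth <- character(0)
  if (is.null(pheno)) pheno <- character(0)

  isT <- is.na(pheno)
  if (any(isT)) {
    pheno[isT] <- withSeed(stageSeed(cfg$seed, "tSubtype"),
                           ifelse(runif(sum(isT)) < cfg$cd4Fraction,
                                  "CD4T", "CD8T"))
  }

  n <- length(truth)
  cells <- CellMap(data.frame(
    cell_id = if (n) sprintf("c%05d", seq_len(n)) else character(0),
    x = xy[, 1], y = xy[, 2], phenotype = pheno,
    sample_id = rep("sim", n), roi_id = rep(NA_character_, n)),
    provenance = list(source = "simulateTissue",
                      config_hash = objectHash(cfg)))
  list(cells = cells, vessels = vessels, membranes = membranes,
       truth = truth)
}

#' Simulate a single ROI of a declared tissue phenotype
#'
#' Produces a 670 x 502 um region of interest of one of the three tissue
#' phenotypes used to classify ROIs: \code{"cuff"} (at least one annulus
#' holding at least three T cells), \code{"stromal_T"} (T cells present
#' but none confined in an annulus) and \code{"absent"} (no T cells).
#'
#' @param cfg a \code{\link{tissueConfig}}; domain size is overridden by
#'   the ROI frame.
#' @param phenotype "cuff", "stromal_T" or "absent".
#' @param width,height ROI frame size (micrometres).
#' @return list with \code{cells}, \code{vessels}, \code{membranes},
#'   \code{truth} and \code{frame} (origin, size, declared phenotype).
#' @export
simulateROI <- function(cfg, phenotype = c("cuff", "stromal_T", "absent"),
                        width = 670, height = 502) {
  phenotype <- match.arg(phenotype)
  stopifnot(inherits(cfg, "TissueConfig"))
  base <- cfg
  base$width <- width; base$height <- height
  base$nVessels <- if (phenotype == "cuff") max(1L, min(cfg$nVessels, 2L)) else 1L
  base$cuffTPerVessel <- if (phenotype == "cuff")
    max(3L, cfg$cuffTPerVessel) else 0L
  if (phenotype == "absent") {
    base$tParentIntensity <- 0
    base$cuffTPerVessel <- 0L
  }
  class(base) <- "TissueConfig"
  sim <- simulateTissue(base)

  if (phenotype == "stromal_T") {
    # discard T cells confined in an annulus, then guarantee at least one
    # stromal T cell survives (deterministic fallback placement)
    ph <- phenotypes(sim$cells)
    isT <- ph %in% tCellLabels()
    inAnnulus <- rep(FALSE, nCells(sim$cells))
    if (any(isT) && length(sim$membranes)) {
      xy <- coords(sim$cells)[isT, , drop = FALSE]
      inside <- rep(FALSE, nrow(xy))
      for (m in sim$membranes) inside <- inside | hullContains(m, xy)
      inAnnulus[which(isT)[inside]] <- TRUE
    }
    keep <- !inAnnulus
    sim$cells <- sim$cells[keep]
    sim$truth <- sim$truth[keep]
    if (!any(phenotypes(sim$cells) %in% tCellLabels())) {
      far <- farthestCorner(sim$membranes, width, height)
      d <- cellData(sim$cells)
      d <- rbind(d, data.frame(cell_id = "t_fallback", x = far[1],
                               y = far[2], phenotype = "CD8T",
                               sample_id = "sim", roi_id = NA_character_))
      sim$cells <- CellMap(d, provenance = sim$cells@provenance)
      sim$truth <- c(sim$truth, "stromal_t")
    }
  }

  sim$frame <- list(origin = c(0, 0), width = width, height = height,
                    tissue_phenotype = phenotype)
  sim
}

# Frame corner farthest from every membrane annulus; inset from the edge.
farthestCorner <- function(membranes, w, h) {
  corners <- cbind(c(0.05, 0.95, 0.05, 0.95) * w,
                   c(0.05, 0.05, 0.95, 0.95) * h)
  if (length(membranes) == 0L) return(corners[1, ])
  d <- distanceToHulls(corners, membranes)
  corners[which.max(d), ]
}

#' Configuration for the synthetic expression generator
#'
#' Negative-binomial counts with a lognormal spread of per-gene baseline
#' means and a planted gene program whose mean is multiplied by
#' \code{2^log2Effect} in the affected units.
#'
#' @param nGenes,nUnits matrix dimensions.
#' @param baselineMean mean count of an average gene.
#' @param dispersion NB size parameter (variance = mu + mu^2/dispersion);
#'   \code{Inf} gives Poisson counts.
#' @param geneMeanSdLog sdlog of the lognormal per-gene mean multiplier
#'   (normalised to expectation 1); 0 makes all genes share
#'   \code{baselineMean}.
#' @param geneSetSize number of planted program genes.
#' @param log2Effect log2 fold change of planted genes in affected units.
#' @param affectedFraction fraction of units carrying the program.
#' @param seed master seed.
#' @return a validated \code{ExprConfig} list.
#' @export
exprConfig <- function(nGenes = 3000, nUnits = 200, baselineMean = 5,
                       dispersion = 2, geneMeanSdLog = 1,
                       geneSetSize = 50, log2Effect = 1,
                       affectedFraction = 0.5, seed = 1L) {
  cfg <- list(nGenes = as.integer(nGenes), nUnits = as.integer(nUnits),
              baselineMean = baselineMean, dispersion = dispersion,
              geneMeanSdLog = geneMeanSdLog,
              geneSetSize = as.integer(geneSetSize),
              log2Effect = log2Effect,
              affectedFraction = affectedFraction, seed = as.integer(seed))
  if (cfg$geneSetSize > cfg$nGenes)
    stop("config error: planted set larger than gene universe")
  if (!is.finite(cfg$log2Effect))
    stop("config error: effect size must be finite")
  if (cfg$baselineMean < 0 || cfg$dispersion <= 0)
    stop("config error: invalid NB parameters")
  if (cfg$affectedFraction < 0 || cfg$affectedFraction > 1)
    stop("config error: affectedFraction outside [0, 1]")
  class(cfg) <- "ExprConfig"
  cfg
}

#' Simulate an expression matrix with a planted program
#'
#' @param cfg an \code{\link{exprConfig}}.
#' @return list with \code{expr} (an \code{ExpressionMatrix} of raw
#'   counts), \code{plantedGenes} and \code{affectedUnits} (truth).
#' @examples
#' sim <- simulateExpression(exprConfig(nGenes = 100, nUnits = 20,
#'                                      seed = 3))
#' sim$expr
#' @export
simulateExpression <- function(cfg) {
  stopifnot(inherits(cfg, "ExprConfig"))
  geneMeans <- withSeed(stageSeed(cfg$seed, "geneMeans"), {
    if (cfg$geneMeanSdLog > 0) {
      m <- exp(rnorm(cfg$nGenes, 0, cfg$geneMeanSdLog) -
               cfg$geneMeanSdLog^2 / 2)
      cfg$baselineMean * m
    } else rep(cfg$baselineMean, cfg$nGenes)
  })
  planted <- withSeed(stageSeed(cfg$seed, "planted"),
                      sort(sample.int(cfg$nGenes, cfg$geneSetSize)))
  nAff <- round(cfg$affectedFraction * cfg$nUnits)
  affected <- withSeed(stageSeed(cfg$seed, "affected"),
                       sort(sample.int(cfg$nUnits, nAff)))
  mu <- matrix(geneMeans, nrow = cfg$nGenes, ncol = cfg$nUnits)
  if (length(planted) && length(affected))
    mu[planted, affected] <- mu[planted, affected] * 2^cfg$log2Effect
  counts <- withSeed(stageSeed(cfg$seed, "counts"), {
    if (is.infinite(cfg$dispersion)) rpois(length(mu), lambda = mu)
    else rnbinom(length(mu), mu = mu, size = cfg$dispersion)
  })
  m <- matrix(as.numeric(counts), nrow = cfg$nGenes, ncol = cfg$nUnits,
              dimnames = list(sprintf("g%04d", seq_len(cfg$nGenes)),
                              sprintf("u%04d", seq_len(cfg$nUnits))))
  list(expr = ExpressionMatrix(m, valueKind = "raw_count"),
       plantedGenes = rownames(m)[planted],
       affectedUnits = colnames(m)[affected])
}
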