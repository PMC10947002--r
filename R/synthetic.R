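#' Synthetic cohort configuration with study-anchored defaults
#'
#' Defaults emulate the study conditions: 29 OSB and 12 control subjects,
#' three timepoints with group gestational-age schedules (OSB means
#' 23+3 / 25+6 / 31+6 weeks, controls 23+1 / 28+6 / 32+6), 0.8 mm isotropic
#' voxels, linear per-structure growth, gyrification amplitude increasing
#' with GA, and group effects on ventricular growth (global medians
#' 2500.94 vs 708.21 mm^3/week with log-normal dispersion matched to the
#' reported IQRs) and on the folding trajectory (OSB folds faster in the
#' immediate period, slower long-term).
#'
#' @param nOSB,nControl subject counts.
#' @param seed master seed; every byte of the cohort is a deterministic
#'   function of (config, seed).
#' @param spacing voxel edge length, mm.
#' @param effect `"paper"` for the anchored group effects, `"null"` for a
#'   zero-effect cohort (both groups drawn from the control model).
#' @param structures which structures to generate (subset of
#'   `c("wm", "ventricles", "cerebellum")`); restricting speeds up large
#'   replicate studies that only need one structure.
#' @param nTheta,nPhi angular resolution of the generated surfaces.
#' @return a [CohortConfig-class].
#' @export
cohortConfig <- function(nOSB = 29L, nControl = 12L, seed = 1L,
                         spacing = 0.8, effect = c("paper", "null"),
                         structures = c("wm", "ventricles", "cerebellum"),
                         nTheta = 32L, nPhi = 64L) {
  effect <- match.arg(effect)
  structures <- match.arg(structures, several.ok = TRUE)
  ga <- list(
    OSB = list(mean = c(23.4286, 25.8571, 31.8571),
               sd = c(1.143, 0.714, 1.0)),
    control = list(mean = c(23.1429, 28.8571, 32.8571),
                   sd = c(1.286, 1.429, 1.714)))
  growth <- list(
    ventricles = list(
      # global weekly total-volume rate: log-normal median (mm^3/week) with
      # sigma from the reported IQRs; immediate rate = global * fImm
      OSB = list(median = 2500.94, sigma = 0.5567, fImm = 1.7300),
      control = list(median = 708.21, sigma = 0.4950, fImm = 0.9616),
      # ellipsoid axes (x, y, z) = (2.0, 1.0, 1.3) * b; atrial surrogate = 2b
      axesRatio = c(2.0, 1.0, 1.3),
      # baseline atrial diameter (mm) sampled per severity class
      baselineDiameter = list(
        OSB = list(classes = c(mild = 4, moderate = 8, severe = 17),
                   range = list(mild = c(10.5, 12.4), moderate = c(13, 15),
                                severe = c(15.6, 19))),
        control = list(classes = c(none = 1),
                       range = list(none = c(7, 9))))),
    wm = list(
      # base radius Rw (mm), linear in GA; ellipsoid axes = Rw * axes
      R0 = 26, Rslope = 0.7, gaRef = 21, axes = c(1.25, 1.05, 0.9),
      subjectSD = 0.8),
    cerebellum = list(R0 = 8, Rslope = 0.45, gaRef = 20,
                      axes = c(1.4, 1.1, 0.8), subjectSD = 0.4))
  folding <- list(
    ampBase = 0.03, gaRef = 20,
    ampSlope = list(OSB = c(immediate = 0.024, longterm = 0.008),
                    control = c(immediate = 0.012, longterm = 0.012)),
    nWaves = 10L, omegaRange = c(8, 16), fieldSeed = 104729L)
  effects <- list(
    enabled = effect == "paper",
    pACCmult = 1.4, HHmult = 1.3, severeVMmult = 1.35,
    pLesionMS = 7 / 29, pHH = 0.3, pCC = c(normal = 13, abnormal = 6,
                                           pACC = 10) / 29,
    pHT = 7 / 29)
  new("CohortConfig", nOSB = as.integer(nOSB), nControl = as.integer(nControl),
      seed = as.integer(seed), spacing = spacing, gaSchedule = ga,
      growth = growth, folding = folding, effects = effects,
      mesh = list(nTheta = as.integer(nTheta), nPhi = as.integer(nPhi),
                  structures = structures, effect = effect))
}

# fixed band-limited directional-cosine wave basis; per-subject phases vary
.foldBasis <- function(folding) {
  withr_seed <- folding$fieldSeed
  old <- .Random.seed_exists()
  set.seed(withr_seed)
  K <- folding$nWaves
  dirs <- matrix(stats::rnorm(3 * K), K, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  omega <- stats::runif(K, folding$omegaRange[1], folding$omegaRange[2])
  w <- 1 / sqrt(omega)
  w <- w / sum(w)  # |f| <= 1 for any phases
  .restore_seed(old)
  list(dirs = dirs, omega = omega, weights = w)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# evaluate the folding field at unit directions (n x 3)
.foldField <- function(dirs, basis, phases) {
  f <- numeric(nrow(dirs))
  for (j in seq_along(basis$omega))
    f <- f + basis$weights[j] *
      cos(basis$omega[j] * (dirs %*% basis$dirs[j, ]) + phases[j])
  as.vector(f)
}

# radial surface radius in direction d: ellipsoid base * (1 + amp * f)
.radialRadius <- function(dirs, axesMM, amp, basis, phases) {
  base <- 1 / sqrt((dirs[, 1] / axesMM[1])^2 + (dirs[, 2] / axesMM[2])^2 +
                     (dirs[, 3] / axesMM[3])^2)
  if (amp > 0) base * (1 + amp * .foldField(dirs, basis, phases)) else base
}

#' Generate a gyrified radial surface
#'
#' Radial cortical-surface model r(theta, phi) = R(direction) * (1 + a * f)
#' on a fixed latitude/longitude grid (plus the two poles): R is an
#' ellipsoid base radius, f a fixed band-limited sum of directional
#' sinusoids with the given phases, and a the folding amplitude. Because the
#' (theta, phi) grid is shared across gestational ages, vertices at
#' different timepoints correspond by index, which gives exact ground-truth
#' correspondence. Vertices carry lobe labels assigned by fixed angular
#' sectors (4 lobes x 2 hemispheres split at the mid-sagittal plane).
#'
#' @param ga gestational age, decimal weeks (20-37); only validated, the
#'   geometry is fully specified by `axesMM` and `amplitude`.
#' @param axesMM ellipsoid semi-axes (x anterior-posterior, y left-right,
#'   z superior-inferior), mm.
#' @param amplitude folding amplitude a (must satisfy a < 1: larger implies
#'   self-intersection of the radial model).
#' @param basis folding wave basis from the cohort config (dirs/omega/
#'   weights); defaults to the canonical basis.
#' @param phases per-wave phases (length `nWaves`); defaults to 0.
#' @param nTheta,nPhi grid resolution.
#' @param center surface centre, mm.
#' @param label structure code to attach.
#' @return a closed [SurfaceMesh-class]; `vertexData()` has columns `lobe`
#'   and `gridId`.
#' @export
generateSurface <- function(ga, axesMM, amplitude = 0, basis = NULL,
                            phases = NULL, nTheta = 32L, nPhi = 64L,
                            center = c(0, 0, 0), label = 1L) {
  if (ga < 20 || ga > 37) stop("ga must lie in [20, 37] weeks")
  if (is.null(basis)) basis <- .foldBasis(cohortConfig()@folding)
  if (is.null(phases)) phases <- rep(0, length(basis$omega))
  if (amplitude >= 1)
    stop("folding amplitude >= 1 implies self-intersection")
  th <- seq_len(nTheta - 1L) * pi / nTheta
  ph <- (seq_len(nPhi) - 1L) * 2 * pi / nPhi
  grid <- expand.grid(phi = ph, theta = th)
  dirs <- cbind(sin(grid$theta) * cos(grid$phi),
                sin(grid$theta) * sin(grid$phi),
                cos(grid$theta))
  dirs <- rbind(c(0, 0, 1), dirs, c(0, 0, -1))
  r <- .radialRadius(dirs, axesMM, amplitude, basis, phases)
  v <- dirs * r
  v <- sweep(v, 2, center, "+")
  n <- nrow(dirs)
  idx <- function(i, j) 1L + (i - 1L) * nPhi + ((j - 1L) %% nPhi) + 1L
  fl <- vector("list", nTheta)
  fl[[1]] <- cbind(1L, idx(1, seq_len(nPhi) + 1L), idx(1, seq_len(nPhi)))
  for (i in seq_len(nTheta - 2L)) {
    j <- seq_len(nPhi)
    fl[[i + 1L]] <- rbind(cbind(idx(i, j), idx(i, j + 1L), idx(i + 1L, j)),
                          cbind(idx(i, j + 1L), idx(i + 1L, j + 1L),
                                idx(i + 1L, j)))
  }
  fl[[nTheta]] <- cbind(n, idx(nTheta - 1L, seq_len(nPhi)),
                        idx(nTheta - 1L, seq_len(nPhi) + 1L))
  f <- do.call(rbind, fl)
  # lobe sectors in parameter space: angle from the anterior (+x) axis
  alpha <- acos(pmin(pmax(dirs[, 1], -1), 1))
  lobe <- ifelse(alpha < pi / 3, "frontal",
                 ifelse(alpha > 3 * pi / 4, "occipital",
                        ifelse(dirs[, 3] >= 0, "parietal", "temporal")))
  hemi <- ifelse(dirs[, 2] >= 0, "left", "right")
  vd <- data.frame(lobe = factor(paste(lobe, hemi, sep = "_"),
                                 levels = .LOBE_LEVELS),
                   gridId = seq_len(n))
  mesh <- surfaceMesh(v, f, structureLabel = label, vertexData = vd)
  .orientOutward(mesh)
}

#' Canonical atlas surface with lobe labels
#'
#' The labeled reference surface used for lobe parcellation: the generator's
#' radial surface at the requested gestational age with the canonical wave
#' basis and fixed phases, carrying exact sector-based lobe labels.
#'
#' @param ga gestational age, decimal weeks.
#' @param config a [CohortConfig-class] (defaults control the geometry).
#' @return a labeled [SurfaceMesh-class].
#' @export
atlasSurface <- function(ga, config = cohortConfig()) {
  wm <- config@growth$wm
  fold <- config@folding
  Rw <- wm$R0 + wm$Rslope * (ga - wm$gaRef)
  amp <- fold$ampBase + fold$ampSlope$control[["immediate"]] * (ga - fold$gaRef)
  basis <- .foldBasis(fold)
  generateSurface(ga, axesMM = Rw * wm$axes, amplitude = amp, basis = basis,
                  phases = rep(0.5, fold$nWaves),
                  nTheta = config@mesh$nTheta, nPhi = config@mesh$nPhi)
}

# numeric median of exp(N(0, sigma) + W) where W is the log-multiplier
# mixture implied by the covariate probabilities; used to renormalize the
# effect multipliers so the programmed group median is exact by construction
.lognormMixMedian <- function(sigma, logm, probs) {
  cdf <- function(t) sum(probs * stats::pnorm((t - logm) / sigma))
  exp(stats::uniroot(function(t) cdf(t) - 0.5, c(-10, 10))$root)
}

.sampleCovariates <- function(group, eff) {
  if (group != "OSB") {
    return(list(lesion_type = NA_character_, persistent_HH = FALSE,
                cc_status = "normal", heterotopia = FALSE,
                severity = "none", mult = 1))
  }
  sev <- sample(names(eff$sevProbs), 1, prob = eff$sevProbs)
  lesion <- sample(c("myeloschisis", "myelomeningocele"), 1,
                   prob = c(eff$pLesionMS, 1 - eff$pLesionMS))
  hh <- stats::runif(1) < eff$pHH
  cc <- sample(names(eff$pCC), 1, prob = eff$pCC)
  ht <- stats::runif(1) < eff$pHT
  mult <- 1
  if (eff$enabled) {
    if (sev == "severe") mult <- mult * eff$severeVMmult
    if (cc == "pACC") mult <- mult * eff$pACCmult
    if (hh) mult <- mult * eff$HHmult
  }
  list(lesion_type = lesion, persistent_HH = hh, cc_status = cc,
       heterotopia = ht, severity = sev, mult = mult)
}

# enumerate the multiplier distribution of the OSB group
.osbLogMultDist <- function(eff, sevProbs) {
  if (!eff$enabled) return(list(logm = 0, probs = 1))
  combos <- expand.grid(sev = c(TRUE, FALSE), pacc = c(TRUE, FALSE),
                        hh = c(TRUE, FALSE))
  pSev <- unname(sevProbs["severe"])
  if (is.na(pSev)) pSev <- 0
  pPACC <- unname(eff$pCC["pACC"])
  probs <- ifelse(combos$sev, pSev, 1 - pSev) *
    ifelse(combos$pacc, pPACC, 1 - pPACC) *
    ifelse(combos$hh, eff$pHH, 1 - eff$pHH)
  logm <- combos$sev * log(eff$severeVMmult) +
    combos$pacc * log(eff$pACCmult) + combos$hh * log(eff$HHmult)
  list(logm = logm, probs = probs)
}

#' Generate one synthetic subject
#'
#' Three timepoint label volumes plus full ground truth. The white matter is
#' a gyrified radial surface whose folding amplitude grows linearly in GA
#' (with group- and period-specific slopes); ventricles are two mirrored
#' ellipsoids (lateral bodies) whose total volume follows the programmed
#' weekly-rate trajectory; the cerebellum is a posterior-inferior ellipsoid.
#' Structures are voxelized onto a common isotropic grid (ventricles carved
#' out of the white-matter interior). Deterministic given (config, subject
#' index).
#'
#' @param group `"OSB"` or `"control"`.
#' @param config a [CohortConfig-class].
#' @param subjectIndex 1-based subject index (drives the per-subject seed).
#' @return list with `volumes` (3 [LabelVolume-class]), `meta` (covariates +
#'   GAs), and `truth` (programmed rates, true analytic volumes, folding
#'   amplitudes, fold phases).
#' @export
generateSubject <- function(group = c("OSB", "control"),
                            config = cohortConfig(), subjectIndex = 1L) {
  group <- match.arg(group)
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old))
  set.seed((config@seed + 7919L * subjectIndex +
              ifelse(group == "OSB", 0L, 499979L)) %% .Machine$integer.max)
  structures <- config@mesh$structures
  fold <- config@folding
  basis <- .foldBasis(fold)
  phases <- stats::runif(fold$nWaves, 0, 2 * pi)

  # gestational ages
  sch <- config@gaSchedule[[group]]
  ga <- NULL
  for (try in 1:100) {
    g <- stats::rnorm(3, sch$mean, sch$sd)
    if (all(diff(g) >= 0.5)) {
      ga <- g
      break
    }
  }
  if (is.null(ga)) ga <- sch$mean

  effGroup <- if (config@mesh$effect == "null") "control" else group
  eff <- config@effects
  bd <- config@growth$ventricles$baselineDiameter[[effGroup]]
  eff$sevProbs <- bd$classes / sum(bd$classes)
  cov <- .sampleCovariates(if (effGroup == "OSB") "OSB" else "control", eff)
  if (cov$severity == "none" && effGroup == "OSB") cov$severity <- "severe"
  sevRange <- bd$range[[if (effGroup == "OSB") cov$severity else "none"]]
  atrial <- stats::runif(1, sevRange[1], sevRange[2])

  # programmed ventricular volume trajectory (total over both bodies)
  gpar <- config@growth$ventricles[[effGroup]]
  dist <- .osbLogMultDist(eff, eff$sevProbs)
  norm <- if (effGroup == "OSB" && eff$enabled)
    .lognormMixMedian(gpar$sigma, dist$logm, dist$probs) else 1
  rawRate <- exp(stats::rnorm(1, 0, gpar$sigma)) * cov$mult / norm
  globalRate <- gpar$median * rawRate
  immRate <- globalRate * gpar$fImm
  ax <- config@growth$ventricles$axesRatio
  b1 <- atrial / 2
  ventV1 <- 2 * (4 / 3) * pi * prod(ax) * b1^3
  ventV <- c(ventV1,
             ventV1 + immRate * (ga[2] - ga[1]),
             ventV1 + globalRate * (ga[3] - ga[1]))
  if (any(diff(ventV) <= 0)) ventV <- cummax(ventV) + c(0, 1, 2)

  # white matter and cerebellum base radii
  wm <- config@growth$wm
  cb <- config@growth$cerebellum
  RwJit <- stats::rnorm(1, 0, wm$subjectSD)
  RcJit <- stats::rnorm(1, 0, cb$subjectSD)
  Rw <- wm$R0 + RwJit + wm$Rslope * (ga - wm$gaRef)
  Rc <- cb$R0 + RcJit + cb$Rslope * (ga - cb$gaRef)

  # Severe ventriculomegaly enlarges the head: widen the white-matter
  # envelope when the programmed ventricles would not fit inside it.
  if (all(c("wm", "ventricles") %in% structures)) {
    ax <- config@growth$ventricles$axesRatio
    for (t in 1:3) {
      bt <- (ventV[t] / 2 / ((4 / 3) * pi * prod(ax)))^(1 / 3)
      ext <- c(2 + bt * ax[1], 2 * bt * ax[2] + 2, bt * ax[3])
      ampT <- 0.25  # conservative folding allowance
      need <- max(ext / (wm$axes * (1 - ampT))) / 0.9
      Rw[t] <- max(Rw[t], need)
    }
    Rw <- cummax(Rw)
  }

  # folding amplitude: piecewise linear in GA with period-specific slopes
  slopes <- fold$ampSlope[[effGroup]]
  amp1 <- fold$ampBase + slopes[["immediate"]] * (ga[1] - fold$gaRef)
  amp <- c(amp1,
           amp1 + slopes[["immediate"]] * (ga[2] - ga[1]),
           amp1 + slopes[["immediate"]] * (ga[2] - ga[1]) +
             slopes[["longterm"]] * (ga[3] - ga[2]))

  volumes <- vector("list", 3)
  truthVol <- list()
  for (t in 1:3) {
    meshes <- list()
    if ("wm" %in% structures) {
      meshes$wm <- generateSurface(min(max(ga[t], 20), 37),
                                   axesMM = Rw[t] * wm$axes,
                                   amplitude = amp[t], basis = basis,
                                   phases = phases,
                                   nTheta = config@mesh$nTheta,
                                   nPhi = config@mesh$nPhi, label = 1L)
    }
    if ("ventricles" %in% structures) {
      bt <- (ventV[t] / 2 / ((4 / 3) * pi * prod(ax)))^(1 / 3)
      axv <- bt * ax
      yoff <- axv[2] + 2
      meshes$ventL <- .ellipsoidMesh(axv, center = c(-2, yoff, 0), label = 2L)
      meshes$ventR <- .ellipsoidMesh(axv, center = c(-2, -yoff, 0), label = 2L)
      if ("wm" %in% structures) {
        ok <- FALSE
        for (attempt in 1:5) {
          if (.containedInRadial(meshes$ventL, Rw[t] * wm$axes, amp[t], basis,
                                 phases) &&
              .containedInRadial(meshes$ventR, Rw[t] * wm$axes, amp[t], basis,
                                 phases)) {
            ok <- TRUE
            break
          }
          jit <- stats::rnorm(3, 0, 0.5)
          meshes$ventL@vertices <- sweep(meshes$ventL@vertices, 2, jit, "+")
          meshes$ventR@vertices <- sweep(meshes$ventR@vertices, 2, jit * c(1, -1, 1), "+")
        }
        if (!ok) stop("ventricles do not fit inside the white-matter surface")
      }
    }
    if ("cerebellum" %in% structures) {
      zc <- -(Rw[t] * wm$axes[3] * 0.5 + Rc[t] * cb$axes[3] + 6)
      meshes$cereb <- .ellipsoidMesh(Rc[t] * cb$axes,
                                     center = c(-Rw[t] * 0.6, 0, zc),
                                     label = 3L)
    }
    volumes[[t]] <- .assembleLabelVolume(meshes, config@spacing)
    truthVol[[t]] <- list(
      ventricles = if ("ventricles" %in% structures) ventV[t] else NA,
      wm_outer = if ("wm" %in% structures)
        .radialVolumeQuadrature(Rw[t] * wm$axes, amp[t], basis, phases)
      else NA,
      cerebellum = if ("cerebellum" %in% structures)
        (4 / 3) * pi * prod(Rc[t] * cb$axes) else NA)
  }

  meta <- data.frame(
    group = group, lesion_type = cov$lesion_type,
    persistent_HH = cov$persistent_HH, cc_status = cov$cc_status,
    heterotopia = cov$heterotopia, severity = cov$severity,
    atrial_diameter_mm = atrial,
    ga_t1 = ga[1], ga_t2 = ga[2], ga_t3 = ga[3])
  list(volumes = volumes, meta = meta,
       truth = list(ga = ga, ventricularGlobalRate = globalRate,
                    ventricularImmediateRate = immRate,
                    ventricularVolumes = ventV, foldAmplitude = amp,
                    foldPhases = phases, volumes = truthVol))
}

# UV-grid ellipsoid (a radial surface with zero folding)
.ellipsoidMesh <- function(axesMM, center = c(0, 0, 0), label = NA_integer_,
                           nTheta = 20L, nPhi = 40L) {
  generateSurface(28, axesMM = axesMM, amplitude = 0, nTheta = nTheta,
                  nPhi = nPhi, center = center, label = label)
}

# all mesh vertices strictly inside the radial WM surface (5% margin)
.containedInRadial <- function(mesh, axesMM, amp, basis, phases) {
  v <- vertices(mesh)
  rr <- sqrt(rowSums(v^2))
  dirs <- v / pmax(rr, 1e-12)
  rWM <- .radialRadius(dirs, axesMM, amp, basis, phases)
  all(rr < 0.95 * rWM)
}

# enclosed volume of the radial surface by spherical quadrature
.radialVolumeQuadrature <- function(axesMM, amp, basis, phases, n = 200L) {
  th <- (seq_len(n) - 0.5) * pi / n
  ph <- (seq_len(2L * n) - 0.5) * pi / n
  g <- expand.grid(theta = th, phi = ph)
  dirs <- cbind(sin(g$theta) * cos(g$phi), sin(g$theta) * sin(g$phi),
                cos(g$theta))
  r <- .radialRadius(dirs, axesMM, amp, basis, phases)
  sum(r^3 / 3 * sin(g$theta)) * (pi / n) * (pi / n)
}

# voxelize a set of structure meshes onto one grid; ventricles overwrite the
# white-matter interior (nested anatomy), cerebellum sits outside
.assembleLabelVolume <- function(meshes, spacing, padding = 3L) {
  allv <- do.call(rbind, lapply(meshes, vertices))
  lo <- apply(allv, 2, min) - padding * spacing
  hi <- apply(allv, 2, max) + padding * spacing
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  lab <- array(0L, dims)
  for (m in meshes) {
    inside <- .voxelize_mesh(vertices(m), faces(m), dims, rep(spacing, 3), lo)
    lab[inside == 1L] <- structureLabel(m)
  }
  labelVolume(lab, spacing = spacing, origin = lo)
}

#' Generate a synthetic longitudinal cohort
#'
#' Runs [generateSubject()] for every subject, assembles the cohort manifest
#' and the ground-truth bundle, and (optionally) writes NIfTI volumes, a
#' manifest CSV and a truth JSON to `dir`.
#'
#' @param config a [CohortConfig-class].
#' @param dir optional output directory; when NULL everything stays in
#'   memory.
#' @return list with `manifest` (data.frame), `subjects` (per-subject lists
#'   from [generateSubject()]), and `config`.
#' @export
generateCohort <- function(config = cohortConfig(), dir = NULL) {
  ids <- c(sprintf("osb%02d", seq_len(config@nOSB)),
           sprintf("ctl%02d", seq_len(config@nControl)))
  groups <- rep(c("OSB", "control"), c(config@nOSB, config@nControl))
  subjects <- vector("list", length(ids))
  names(subjects) <- ids
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    s <- generateSubject(groups[i], config, subjectIndex = i)
    subjects[[i]] <- s
    rows[[i]] <- cbind(subject_id = ids[i], s$meta)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- matrix("", length(ids), 3)
    for (i in seq_along(ids)) {
      for (t in 1:3) {
        p <- file.path(dir, sprintf("%s_t%d.nii.gz", ids[i], t))
        writeLabelVolume(subjects[[i]]$volumes[[t]], p)
        paths[i, t] <- p
      }
    }
    manifest$path_t1 <- paths[, 1]
    manifest$path_t2 <- paths[, 2]
    manifest$path_t3 <- paths[, 3]
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    truth <- lapply(subjects, function(s) s$truth)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(manifest = manifest, subjects = subjects, config = config)
}
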