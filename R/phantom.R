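# Parametric digital head phantom.
#
# A spherical head (scalp, skull, brain shells) holding a corpus callosum
# modelled as an elliptical-arch slab in the midsagittal plane: the arch runs
# from the rostrum (anterior-inferior recurve, arc parameter t = 0) over the
# genu and body to the splenium (t = 1). Cingulate subregions are bands
# wrapping the arch a few mm outside the callosal surface, partitioned at
# configurable arc-length fractions; the five entry gyri are angular cortical
# patches; the vessel tree carries the paired pericallosal arteries on the
# dorsal callosal surface (the principal hazard forcing trajectories off the
# midline), a dorsal midline sinus and cortical bridging vessels.
# World coordinates are RAS with the origin at the head centre.

#' PhantomConfig: parameters of the digital head phantom
#'
#' Defaults give a 96^3, 1 mm isotropic head that every stage of the
#' pipeline can run on. The same config and seed always yield a
#' voxel-identical phantom.
#'
#' @slot dim integer(3) grid shape.
#' @slot spacing numeric(3) voxel spacing, mm.
#' @slot arch named numeric: `apSemi`, `heightSemi` (ellipse semi-axes, mm),
#'   `centreY`, `centreZ` (arch centre, mm), `phiStartDeg`, `phiEndDeg`
#'   (parametric angle range; the start below 0 deg gives the rostral
#'   recurve), `radius` (half-thickness of the callosal slab, mm),
#'   `halfWidth` (lateral half-width, mm).
#' @slot band named numeric: `gap` (mm between callosal surface and band),
#'   `width` (band thickness, mm), `halfWidth` (lateral half-width, mm).
#' @slot fractions numeric(3), strictly increasing arc-length fractions
#'   dividing subcallosal / anterior / middle / posterior cingulate.
#' @slot head named numeric: `scalpOuter`, `skullOuter`, `skullInner`,
#'   `gyrusInner` radii, mm.
#' @slot vessels named numeric: pericallosal radius/lateral offset/surface
#'   offset, sinus radius and radial position, bridging-vessel radius and
#'   count.
#' @slot nStreamlines default streamline count.
#' @slot seed random seed for the stochastic parts (streamlines).
#' @slot dominance `"left"` (default) or `"right"`; flips all laterality
#'   roles.
#' @slot rightFrontalVesselWall add a curtain of cortical vessels sealing
#'   the non-dominant frontal approach (the adversarial variant).
#' @export
setClass("PhantomConfig",
         representation(dim = "integer", spacing = "numeric",
                        arch = "numeric", band = "numeric",
                        fractions = "numeric", head = "numeric",
                        vessels = "numeric", nStreamlines = "integer",
                        seed = "integer", dominance = "character",
                        rightFrontalVesselWall = "logical"))

setValidity("PhantomConfig", function(object) {
  if (any(object@spacing <= 0)) return("spacing must be positive")
  pos <- c(object@arch[c("apSemi", "heightSemi", "radius", "halfWidth")],
           object@band[c("width", "halfWidth")], object@head)
  if (any(pos <= 0)) return("all phantom lengths must be > 0")
  f <- object@fractions
  if (length(f) != 3L || any(diff(f) <= 0) || f[1] <= 0 || f[3] >= 1)
    return("division fractions must be strictly increasing within (0, 1)")
  if (!object@dominance %in% c("left", "right"))
    return("dominance must be 'left' or 'right'")
  h <- object@head
  if (!(h[["gyrusInner"]] < h[["skullInner"]] &&
        h[["skullInner"]] < h[["skullOuter"]] &&
        h[["skullOuter"]] < h[["scalpOuter"]]))
    return("need gyrusInner < skullInner < skullOuter < scalpOuter")
  TRUE
})

#' @param dim,spacing,arch,band,fractions,head,vessels,nStreamlines,seed,dominance,rightFrontalVesselWall
#'   see slots; any named element supplied for the vector parameters
#'   overrides the default of that element.
#' @rdname PhantomConfig-class
#' @export
phantomConfig <- function(dim = c(96L, 96L, 96L), spacing = c(1, 1, 1),
                          arch = numeric(), band = numeric(),
                          fractions = c(0.12, 0.30, 0.72),
                          head = numeric(), vessels = numeric(),
                          nStreamlines = 5000L, seed = 7L,
                          dominance = "left",
                          rightFrontalVesselWall = FALSE) {
  merge <- function(def, got) { def[names(got)] <- got; def }
  arch <- merge(c(apSemi = 20, heightSemi = 13, centreY = 0, centreZ = 6,
                  phiStartDeg = -20, phiEndDeg = 170, radius = 3,
                  halfWidth = 3, exponent = 2.2), arch)
  band <- merge(c(gap = 3, width = 7, halfWidth = 6), band)
  head <- merge(c(scalpOuter = 45, skullOuter = 43, skullInner = 40,
                  gyrusInner = 35), head)
  vessels <- merge(c(pericallosalRadius = 1, pericallosalLateral = 2,
                     pericallosalOffset = 1, sinusRadius = 2.5,
                     sinusPosRadius = 41, bridgeRadius = 0.8, nBridges = 6),
                   vessels)
  if (length(dim) == 1L) dim <- rep(dim, 3L)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("PhantomConfig", dim = as.integer(dim), spacing = as.numeric(spacing),
      arch = arch, band = band, fractions = fractions, head = head,
      vessels = vessels, nStreamlines = as.integer(nStreamlines),
      seed = as.integer(seed), dominance = dominance,
      rightFrontalVesselWall = rightFrontalVesselWall)
}

# label ids of the phantom parcellation; gyrus role names follow the
# dominance convention (ids stay fixed, names mirror)
phantomLabelSchema <- function(dominance = "left") {
  base <- c(scalp = 1L, skull = 2L, brain = 3L, ventricles = 4L,
            corpus_callosum = 5L, subcallosal_gyrus = 6L,
            anterior_cingulate = 7L, middle_cingulate = 8L,
            posterior_cingulate = 9L)
  gyri <- structure(10:14, names = names(.gyrusPatches(dominance)))
  c(base, gyri)
}

#' Sample the callosal arch curve
#'
#' Returns the arch centreline in the midsagittal (y, z) plane sampled at
#' `n` points, with the normalised arc-length parameter `t` (0 = rostrum,
#' 1 = splenium) and outward 2D normals. Used internally to build the
#' phantom and by callers wanting arch-sector geometry.
#'
#' @param config a [PhantomConfig].
#' @param n number of samples.
#' @return list with `yz` (n x 2), `t`, `normal` (n x 2).
#' @export
phantomArch <- function(config, n = 512L) {
  a <- config@arch
  ex <- if ("exponent" %in% names(a)) a[["exponent"]] else 2.5
  phi <- seq(a[["phiStartDeg"]], a[["phiEndDeg"]], length.out = n) * pi / 180
  # superellipse: flat dorsal body and near-straight genu face with a
  # rounded bend, like the real callosum (exponent 2 recovers an ellipse)
  sp <- function(u, p) sign(u) * abs(u)^p
  yz <- cbind(a[["centreY"]] + a[["apSemi"]] * sp(cos(phi), 2 / ex),
              a[["centreZ"]] + a[["heightSemi"]] * sp(sin(phi), 2 / ex))
  seg <- sqrt(rowSums(diff(yz)^2))
  t <- c(0, cumsum(seg)) / sum(seg)
  # outward normal = gradient of (|y/a|^ex + |z/b|^ex)
  nrm <- cbind(sp(cos(phi), 2 / ex * (ex - 1)) / a[["apSemi"]],
               sp(sin(phi), 2 / ex * (ex - 1)) / a[["heightSemi"]])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  list(yz = yz, t = t, normal = nrm)
}

#' Arch sector of an arc-length parameter
#'
#' Sector boundaries (rostrum < 0.2, genu 0.2--0.55, posterior body
#' 0.55--0.85, splenium >= 0.85) are the phantom's own convention for the
#' classical callosal subdivisions, chosen so the three generated targets
#' fall at rostrum, genu and posterior body.
#'
#' @param t numeric vector of arc-length fractions in `[0, 1]`.
#' @return character vector of sector names.
#' @export
archSector <- function(t) {
  cut(t, breaks = c(-Inf, 0.2, 0.55, 0.85, Inf),
      labels = c("rostrum", "genu", "posterior_body", "splenium")) |>
    as.character()
}

# entry gyrus patches: unit direction + angular radius (deg), left-dominant
.gyrusPatches <- function(dominance) {
  # directions follow the real gyral topography: superior frontal
  # anterior-superior near the midline, superior parietal lobule and angular
  # gyrus posterior (angular lower and more lateral), middle frontal
  # anterior-lateral -- so trajectories to the deep callosal targets run
  # obliquely along the arch rather than dropping onto it from overhead
  p <- list(
    right_superior_frontal = list(dir = c(0.15, 0.90, 0.41), theta = 24),
    right_superior_parietal = list(dir = c(0.22, -0.72, 0.66), theta = 16),
    right_angular = list(dir = c(0.55, -0.70, 0.45), theta = 16),
    left_superior_frontal = list(dir = c(-0.15, 0.70, 0.70), theta = 20),
    left_middle_frontal = list(dir = c(-0.55, 0.72, 0.42), theta = 16))
  if (dominance == "right") {
    nm <- names(p)
    nm <- ifelse(startsWith(nm, "right_"), sub("^right_", "left_", nm),
                 sub("^left_", "right_", nm))
    names(p) <- nm
    p <- lapply(p, function(g) { g$dir[1] <- -g$dir[1]; g })
  }
  lapply(p, function(g) { g$dir <- g$dir / sqrt(sum(g$dir^2)); g })
}

#' Generate the digital head phantom
#'
#' Builds the labelled parcellation (scalp, skull, brain, ventricles,
#' corpus callosum, subcallosal gyrus, three cingulate bands, five entry
#' gyri -- pairwise disjoint) and the vessel tree (two pericallosal
#' arteries on the dorsal callosal surface ~2 mm lateral to the midline, a
#' dorsal midline sinus, and cortical bridging vessels). Deterministic given
#' the config.
#'
#' @param config a [PhantomConfig].
#' @return list with `volume` (a [LabelVolume]) and `vessels`
#'   (a [VesselTree]; adversarial wall vessels, when enabled, have names
#'   starting `"wall"`).
#' @export
makeHeadPhantom <- function(config = phantomConfig()) {
  validObject(config)
  grid <- VoxelGrid(config@dim, spacing = config@spacing)
  hd <- config@head
  halfExtent <- min((config@dim - 1) * config@spacing / 2)
  if (hd[["scalpOuter"]] > halfExtent)
    stop("phantom geometry: structure 'scalp' (radius ",
         hd[["scalpOuter"]], " mm) does not fit inside the grid (half ",
         "extent ", halfExtent, " mm)", call. = FALSE)
  a <- config@arch
  archProbe <- phantomArch(config, n = 256L)
  archReach <- max(sqrt(rowSums(archProbe$yz^2))) + a[["radius"]]
  if (archReach > hd[["gyrusInner"]])
    stop("phantom geometry: structure 'corpus_callosum' (arch reach ",
         signif(archReach, 4),
         " mm) collides with the cortical shell at ", hd[["gyrusInner"]],
         " mm", call. = FALSE)

  # world coordinate vectors along each axis (affine is diagonal, centred)
  wx <- voxelToWorld(grid, cbind(seq_len(config@dim[1]) - 1, 0, 0))[, 1]
  wy <- voxelToWorld(grid, cbind(0, seq_len(config@dim[2]) - 1, 0))[, 2]
  wz <- voxelToWorld(grid, cbind(0, 0, seq_len(config@dim[3]) - 1))[, 3]
  r2 <- outer(outer(wx^2, wy^2, "+"), wz^2, "+")
  sch <- phantomLabelSchema(config@dominance)
  labels <- array(0L, config@dim)
  labels[r2 <= hd[["scalpOuter"]]^2] <- sch[["scalp"]]
  labels[r2 <= hd[["skullOuter"]]^2] <- sch[["skull"]]
  labels[r2 <= hd[["skullInner"]]^2] <- sch[["brain"]]

  # midsagittal-plane distance to the arch centreline and arc parameter
  arch <- phantomArch(config, n = 1024L)
  d2yz <- matrix(Inf, config@dim[2], config@dim[3])
  tyz <- matrix(0, config@dim[2], config@dim[3])
  YY <- matrix(wy, config@dim[2], config@dim[3])
  ZZ <- matrix(wz, config@dim[2], config@dim[3], byrow = TRUE)
  for (i in seq_len(nrow(arch$yz))) {
    d2 <- (YY - arch$yz[i, 1])^2 + (ZZ - arch$yz[i, 2])^2
    upd <- d2 < d2yz
    d2yz[upd] <- d2[upd]
    tyz[upd] <- arch$t[i]
  }
  dyz <- sqrt(d2yz)

  # lateral ventricles: paired curved bodies hugging the callosal underside
  # (the callosal body is the ventricular roof), frontal horns flanking the
  # genu -- they seal the sub-callosal lateral corridor as in vivo
  ex <- if ("exponent" %in% names(a)) a[["exponent"]] else 2.5
  ell2 <- abs((YY - a[["centreY"]]) / a[["apSemi"]])^ex +
    abs((ZZ - a[["centreZ"]]) / a[["heightSemi"]])^ex
  vent2d <- ell2 < 1 & dyz > a[["radius"]] + 0.5 &
    dyz <= a[["radius"]] + 6 & tyz >= 0.10 & tyz <= 0.97
  lateralVent <- abs(wx) >= 1.5 & abs(wx) <= 8
  for (k in seq_len(config@dim[3])) {
    cols <- which(vent2d[, k])
    for (j in cols) {
      sel <- lateralVent & labels[, j, k] == sch[["brain"]]
      labels[sel, j, k] <- sch[["ventricles"]]
    }
  }

  # cingulate band (outside the callosal surface), partitioned by arc length
  bd <- config@band
  inBand2d <- dyz >= a[["radius"]] + bd[["gap"]] &
    dyz <= a[["radius"]] + bd[["gap"]] + bd[["width"]]
  f <- config@fractions
  bandRole <- matrix(NA_integer_, config@dim[2], config@dim[3])
  bandRole[inBand2d & tyz < f[1]] <- sch[["subcallosal_gyrus"]]
  bandRole[inBand2d & tyz >= f[1] & tyz < f[2]] <- sch[["anterior_cingulate"]]
  bandRole[inBand2d & tyz >= f[2] & tyz < f[3]] <- sch[["middle_cingulate"]]
  bandRole[inBand2d & tyz >= f[3]] <- sch[["posterior_cingulate"]]
  lateralBand <- abs(wx) <= bd[["halfWidth"]]
  # bands stay below the cortical shell so the entry gyri keep their caps
  bandRMax2 <- hd[["gyrusInner"]]^2
  for (k in seq_len(config@dim[3])) {
    rolesK <- bandRole[, k]
    cols <- which(!is.na(rolesK))
    for (j in cols) {
      sel <- lateralBand & labels[, j, k] == sch[["brain"]] &
        r2[, j, k] < bandRMax2
      labels[sel, j, k] <- rolesK[j]
    }
  }

  # the callosal slab itself (painted after the bands; disjoint by distance)
  inCC2d <- dyz <= a[["radius"]]
  lateralCC <- abs(wx) <= a[["halfWidth"]]
  for (k in seq_len(config@dim[3])) {
    cols <- which(inCC2d[, k])
    for (j in cols) {
      sel <- lateralCC & labels[, j, k] %in%
        c(sch[["brain"]], sch[["ventricles"]])
      labels[sel, j, k] <- sch[["corpus_callosum"]]
    }
  }

  # entry gyrus patches: angular caps of the outer cortical shell
  patches <- .gyrusPatches(config@dominance)
  shell <- r2 >= hd[["gyrusInner"]]^2 & r2 <= hd[["skullInner"]]^2
  idxShell <- which(shell & labels == sch[["brain"]])
  co <- voxelToWorld(grid, arrayInd(idxShell, config@dim) - 1)
  rad <- sqrt(rowSums(co^2))
  for (role in names(patches)) {
    g <- patches[[role]]
    cosang <- (co %*% g$dir) / rad
    sel <- cosang >= cos(g$theta * pi / 180)
    if (!any(sel))
      stop("phantom geometry: structure '", role, "' is empty", call. = FALSE)
    labels[idxShell[sel]] <- sch[[role]]
  }

  vol <- LabelVolume(labels, grid = grid, table = sch)
  for (role in names(sch))
    if (!any(labels == sch[[role]]))
      stop("phantom geometry: structure '", role, "' is empty", call. = FALSE)

  vessels <- .phantomVessels(config, arch)
  reach <- vapply(vessels@centrelines,
                  function(p) sqrt(max(rowSums(p^2))), 1)
  if (any(reach + vessels@radii > hd[["scalpOuter"]]))
    stop("phantom geometry: structure 'vessel tree' leaves the head volume",
         call. = FALSE)
  list(volume = vol, vessels = vessels)
}

.phantomVessels <- function(config, arch) {
  vs <- config@vessels
  a <- config@arch
  keep <- arch$t >= 0.04 & arch$t <= 0.96
  surf <- arch$yz[keep, ] + arch$normal[keep, ] *
    (a[["radius"]] + vs[["pericallosalOffset"]])
  centrelines <- list(
    pericallosal_left = cbind(-vs[["pericallosalLateral"]], surf),
    pericallosal_right = cbind(vs[["pericallosalLateral"]], surf))
  radii <- rep(vs[["pericallosalRadius"]], 2)

  # anterior cerebral artery segments ascending in front of the rostrum to
  # join the pericallosal trunks
  tip <- arch$yz[1, ] + arch$normal[1, ] *
    (a[["radius"]] + vs[["pericallosalOffset"]])
  for (s in c(-1, 1)) {
    centrelines[[if (s < 0) "aca_left" else "aca_right"]] <-
      rbind(c(s * 1.5, 12, -16), c(s * 1.5, tip))
    radii <- c(radii, vs[["pericallosalRadius"]])
  }

  ys <- seq(-33, 33, by = 2)
  rs <- vs[["sinusPosRadius"]]
  centrelines$sinus <- cbind(0, ys, sqrt(pmax(0, rs^2 - ys^2)))
  radii <- c(radii, vs[["sinusRadius"]])

  # pericallosal branches ascending to the medial cortex: they fan over the
  # dorsal callosal surface along the whole arch, so the only corridors with
  # real clearance run inside the callosal slab, as in vivo
  tb <- seq(0.05, 0.95, by = 0.05)
  archAt <- function(tv) {
    i <- which.min(abs(arch$t - tv))
    list(p = arch$yz[i, ], n = arch$normal[i, ])
  }
  k <- 0
  for (ti in tb) for (s in c(-1, 1)) {
    k <- k + 1
    at <- archAt(ti)
    p0 <- c(s * vs[["pericallosalLateral"]],
            at$p + at$n * (a[["radius"]] + vs[["pericallosalOffset"]]))
    p1 <- c(s * 9, at$p + at$n * (a[["radius"]] + 9))
    centrelines[[paste0("pericallosal_branch", k)]] <- rbind(p0, p1)
    radii <- c(radii, 0.6)
  }

  yb <- seq(-28, 28, length.out = vs[["nBridges"]])
  for (i in seq_along(yb)) {
    s <- if (i %% 2 == 0) 1 else -1
    zc <- sqrt(max(0, (config@head[["skullInner"]] - 3)^2 - 64 - yb[i]^2))
    zs <- sqrt(max(0, rs^2 - yb[i]^2))
    centrelines[[paste0("bridge", i)]] <-
      rbind(c(s * 8, yb[i], zc), c(0, yb[i], zs))
    radii <- c(radii, vs[["bridgeRadius"]])
  }

  if (config@rightFrontalVesselWall) {
    # curtain of cortical vessels over the non-dominant frontal entry patch
    patch <- .gyrusPatches(config@dominance)[[1]]
    u <- patch$dir
    # orthonormal frame of the patch
    e1 <- c(-u[2], u[1], 0); e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    rWall <- config@head[["gyrusInner"]] - 2
    for (i in seq(-4, 4)) {
      pts <- t(vapply(seq(-4, 4), function(j) {
        v <- u + (i / 10) * e1 + (j / 10) * e2
        rWall * v / sqrt(sum(v^2))
      }, numeric(3)))
      centrelines[[paste0("wall", i + 5)]] <- pts
      radii <- c(radii, 1.5)
    }
  }
  VesselTree(centrelines, radii)
}

#' Rasterise a vessel tree into a binary volume
#'
#' A voxel is set iff its centre lies within the vessel radius of some
#' centreline segment (capsule rasterisation). An empty tree gives an
#' all-zero mask.
#'
#' @param tree a [VesselTree].
#' @param grid the target [VoxelGrid].
#' @return a binary [LabelVolume] (role `vessel` = 1).
#' @export
rasteriseVessels <- function(tree, grid) {
  g <- .gridOf(grid)
  if (length(tree@centrelines) == 0) {
    mask <- array(FALSE, g@dim)
  } else {
    mask <- .capsule_mask_cpp(unname(tree@centrelines), tree@radii, g@dim,
                              g@affine, solve(g@affine))
  }
  LabelVolume(array(as.integer(mask), g@dim), grid = g,
              table = c(vessel = 1L))
}

#' Generate synthetic interhemispheric streamlines
#'
#' Noisy arcs crossing the corpus callosum: each streamline starts in the
#' left hemisphere, ends in the right, and passes through at least one
#' callosal voxel. Crossing points are sampled uniformly over the midline
#' callosal voxels, covering rostrum to splenium. No diffusion physics is
#' simulated.
#'
#' @param phantom the phantom [LabelVolume] (roles `corpus_callosum` and
#'   `brain` required).
#' @param n number of streamlines (default 5000).
#' @param seed random seed; the same seed yields identical point arrays.
#' @return a [StreamlineSet].
#' @export
makeInterhemisphericStreamlines <- function(phantom, n = 5000L, seed = 7L) {
  if (n < 0) stop("streamline count must be >= 0", call. = FALSE)
  cc <- roleMask(phantom, "corpus_callosum")
  roleMask(phantom, "brain")  # loud failure when the role is missing
  grid <- phantom@grid
  if (n == 0L)
    return(StreamlineSet(list(), provenance = "phantom"))
  co <- maskWorldCoords(cc, grid)
  mid <- co[abs(co[, 1]) <= spacing(grid)[1] / 2 + 1e-9, , drop = FALSE]
  if (!nrow(mid)) mid <- co
  brainR <- sqrt(max(rowSums(maskWorldCoords(phantom@labels != 0L &
                                               phantom@labels != 1L &
                                               phantom@labels != 2L,
                                             grid)^2)))
  withr::with_seed(seed, {
    pick <- sample.int(nrow(mid), n, replace = TRUE)
    lapply(seq_len(n), function(i) {
      cpt <- mid[pick[i], ]
      X <- runif(1, 12, 25)
      D <- runif(1, 5, 15)
      m <- -cpt / sqrt(sum(cpt^2))
      s <- seq(-1, 1, length.out = 21)
      pts <- cbind(cpt[1] + s * X, cpt[2], cpt[3]) +
        outer(s^2 * D, m)
      noise <- matrix(rnorm(length(pts), sd = 0.4), ncol = 3)
      noise[s == 0, ] <- 0  # keep the callosal crossing point exact
      pts <- pts + noise
      # keep points intracranial
      rr <- sqrt(rowSums(pts^2))
      over <- rr > brainR - 1
      pts[over, ] <- pts[over, ] * (brainR - 1) / rr[over]
      pts
    }) |> StreamlineSet(provenance = "phantom")
  })
}

setMethod("show", "PhantomConfig", function(object) {
  cat("PhantomConfig:", paste(object@dim, collapse = "x"), "voxels at",
      paste(object@spacing, collapse = "x"), "mm;",
      object@nStreamlines, "streamlines; seed", object@seed, ";",
      object@dominance, "dominant\n")
})
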