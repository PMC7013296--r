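#' Parameters of the synthetic left-ventricular shell phantom
#'
#' The phantom is a truncated half-ellipsoid shell: an outer ellipsoid with
#' the given semi-axes, minus an inner ellipsoid offset inward by the wall
#' thickness, cut at a base plane. The truncation fraction is the fraction
#' of the full ellipsoid height retained, measured from the apex: the base
#' plane sits at `z = c * (2 * truncation - 1)` for outer semi-axis `c`
#' along z. Defaults give a shell volume near 150 ml at 1 mm isotropic
#' spacing, a plausible adult LV myocardial volume.
#'
#' @param semi_axes Outer semi-axes `(a, b, c)`, mm.
#' @param wall_mm Wall thickness, mm (< smallest semi-axis).
#' @param truncation Fraction of ellipsoid height retained, in `(0, 1]`.
#' @param spacing_mm Voxel spacing, mm (scalar or length 3).
#' @return List of class `lv_shell_params`.
#' @export
lv_shell_params <- function(semi_axes = c(35, 35, 55), wall_mm = 10,
                            truncation = 0.85, spacing_mm = 1) {
  semi_axes <- as.numeric(semi_axes)
  spacing_mm <- rep(as.numeric(spacing_mm), length.out = 3)
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0),
            wall_mm > 0, wall_mm < min(semi_axes),
            truncation > 0, truncation <= 1, all(spacing_mm > 0))
  structure(list(semi_axes = semi_axes, wall_mm = wall_mm,
                 truncation = truncation, spacing_mm = spacing_mm),
            class = "lv_shell_params")
}

#' Generate the voxelized LV shell phantom
#'
#' Deterministic: a voxel is myocardium when its center lies inside the
#' outer ellipsoid, outside the inner ellipsoid, and below the base plane.
#'
#' @param params An [lv_shell_params()].
#' @return A [myocardium_mask()] carrying `params` as attribute
#'   `shell_params`.
#' @export
generate_lv_shell <- function(params = lv_shell_params()) {
  stopifnot(inherits(params, "lv_shell_params"))
  ax <- params$semi_axes
  sp <- params$spacing_mm
  h <- ax[3] * (2 * params$truncation - 1)
  lo <- c(-ax[1], -ax[2], -ax[3])
  hi <- c(ax[1], ax[2], h)
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / sp)))
  origin <- lo + sp / 2
  cx <- origin[1] + (seq_len(dims[1]) - 1) * sp[1]
  cy <- origin[2] + (seq_len(dims[2]) - 1) * sp[2]
  cz <- origin[3] + (seq_len(dims[3]) - 1) * sp[3]
  inner <- ax - params$wall_mm
  q_out <- outer(outer((cx / ax[1])^2, (cy / ax[2])^2, "+"),
                 (cz / ax[3])^2, "+")
  q_in <- outer(outer((cx / inner[1])^2, (cy / inner[2])^2, "+"),
                (cz / inner[3])^2, "+")
  below <- rep(cz <= h, each = dims[1] * dims[2])
  grid <- array(q_out <= 1 & q_in > 1 & below, dim = dims)
  if (!any(grid)) stop("shell parameters produce an empty mask")
  mask <- myocardium_mask(grid, spacing = sp, origin = origin)
  attr(mask, "shell_params") <- params
  mask
}

#' Analytic volume of the truncated ellipsoid shell
#'
#' Closed-form reference for the voxelized phantom: the volume of the outer
#' ellipsoid below the base plane minus that of the inner ellipsoid below
#' the same plane, in ml.
#'
#' @param params An [lv_shell_params()].
#' @return Volume in ml.
#' @export
analytic_shell_volume_ml <- function(params) {
  stopifnot(inherits(params, "lv_shell_params"))
  cap <- function(a, b, c, h) {
    # volume of {x^2/a^2 + y^2/b^2 + z^2/c^2 <= 1, z <= h}
    h <- max(-c, min(c, h))
    pi * a * b * (h - h^3 / (3 * c^2) + 2 * c / 3)
  }
  ax <- params$semi_axes
  inn <- ax - params$wall_mm
  h <- ax[3] * (2 * params$truncation - 1)
  (cap(ax[1], ax[2], ax[3], h) - cap(inn[1], inn[2], inn[3], h)) / 1000
}

#' Parameters of the synthetic coronary tree generator
#'
#' Three arteries (RCA, LAD, LCx) run from base toward apex along the outer
#' (epicardial) ellipsoid surface at separated azimuths, each with a number
#' of side branches that leave the main branch and descend toward the
#' apex/lateral wall, also on the surface.
#'
#' @param azimuth_deg Named vector: starting azimuth of each main branch,
#'   degrees in the xy plane.
#' @param drift_deg Azimuthal drift of each main branch from base to apex,
#'   degrees.
#' @param side_branches Named integer vector: side-branch count per artery.
#' @param main_nodes Nodes per main branch.
#' @param side_nodes Nodes per side branch.
#' @param seed Optional integer; when non-`NULL` the generator seeds its own
#'   draws (side-branch placement, direction, extent), making the tree
#'   reproducible in isolation. Leave `NULL` to draw from the ambient RNG
#'   stream (as [generate_cohort()] does under its run seed).
#' @return List of class `tree_params`.
#' @export
tree_params <- function(azimuth_deg = c(RCA = 340, LAD = 90, LCx = 200),
                        drift_deg = c(RCA = -30, LAD = -25, LCx = 35),
                        side_branches = c(RCA = 2, LAD = 3, LCx = 2),
                        main_nodes = 24, side_nodes = 8, seed = NULL) {
  stopifnot(all(side_branches >= 0), main_nodes >= 2, side_nodes >= 2)
  structure(list(azimuth_deg = azimuth_deg, drift_deg = drift_deg,
                 side_branches = side_branches, main_nodes = main_nodes,
                 side_nodes = side_nodes, seed = seed),
            class = "tree_params")
}

# Point on the outer ellipsoid surface at polar angle phi (0 = base pole,
# pi = apex pole) and azimuth theta.
ellipsoid_point <- function(ax, phi, theta) {
  cbind(ax[1] * sin(phi) * cos(theta),
        ax[2] * sin(phi) * sin(theta),
        ax[3] * cos(phi))
}

#' Generate a synthetic three-artery epicardial centerline tree
#'
#' @param shell A [generate_lv_shell()] mask (its `shell_params` attribute
#'   supplies the surface), or an [lv_shell_params()] directly.
#' @param params A [tree_params()].
#' @return A validated [centerline_tree()]; every node lies exactly on the
#'   outer ellipsoid surface.
#' @export
generate_coronary_tree <- function(shell, params = tree_params()) {
  sp <- if (inherits(shell, "lv_shell_params")) shell else
    attr(shell, "shell_params")
  if (is.null(sp)) stop("`shell` must carry lv_shell_params")
  stopifnot(inherits(params, "tree_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  ax <- sp$semi_axes
  h <- ax[3] * (2 * sp$truncation - 1)
  phi_base <- acos(min(1, h / ax[3])) + 0.03
  phi_apex <- 0.93 * pi

  rows <- list()
  next_id <- 0L
  add_node <- function(xyz, parent, artery, branch) {
    next_id <<- next_id + 1L
    rows[[next_id]] <<- data.frame(
      id = next_id, x = xyz[1], y = xyz[2], z = xyz[3],
      parent = parent, artery = artery, branch = branch
    )
    next_id
  }

  for (artery in c("RCA", "LAD", "LCx")) {
    th0 <- params$azimuth_deg[[artery]] * pi / 180
    dth <- params$drift_deg[[artery]] * pi / 180
    nm <- params$main_nodes
    phis <- seq(phi_base, phi_apex, length.out = nm)
    thetas <- th0 + dth * (phis - phi_base) / (phi_apex - phi_base)
    pts <- ellipsoid_point(ax, phis, thetas)
    main_ids <- integer(nm)
    parent <- NA_integer_
    for (i in seq_len(nm)) {
      parent <- add_node(pts[i, ], parent, artery, "main")
      main_ids[i] <- parent
    }
    k <- params$side_branches[[artery]]
    if (k > 0) {
      attach_frac <- (seq_len(k)) / (k + 1)
      for (b in seq_len(k)) {
        ai <- max(2L, min(nm - 2L,
                          round(attach_frac[b] * nm) +
                            sample(c(-1L, 0L, 1L), 1)))
        phi_a <- phis[ai]
        th_a <- thetas[ai]
        side_sign <- if (runif(1) < 0.5) -1 else 1
        offset <- side_sign * (30 + runif(1) * 25) * pi / 180
        dphi <- runif(1, 0.35, 0.6) * (phi_apex - phi_a)
        ns <- params$side_nodes
        phi_s <- phi_a + seq_len(ns) / ns * dphi
        th_s <- th_a + seq_len(ns) / ns * offset
        spts <- ellipsoid_point(ax, phi_s, th_s)
        parent <- main_ids[ai]
        for (i in seq_len(ns)) {
          parent <- add_node(spts[i, ], parent, artery, paste0("side", b))
        }
      }
    }
  }
  centerline_tree(do.call(rbind, rows))
}

#' Parameters of the synthetic FFR pressure-loss model
#'
#' Hyperemic flow scales with the subtended myocardial volume,
#' `Q = q * MMAR` (ml/min). The trans-stenotic pressure gradient follows
#' classic stenosis fluid mechanics — a viscous term linear in flow and an
#' expansion (inertial) term quadratic in flow:
#' `dP = k_viscous * (length / MLD^4) * Q +
#'  k_expansion * (1/MLD^2 - 1/RD^2)^2 * Q^2`,
#' and `FFR = (Pa - dP) / Pa` plus optional Gaussian measurement noise,
#' clamped to `(0, 1]`. A lesion subtending a large mass therefore drops
#' FFR more than an anatomically identical lesion subtending a small mass,
#' which is the mechanism the MMAR/MLD index exploits.
#'
#' @param pa_mmHg Hyperemic aortic pressure, mmHg.
#' @param q_flow Hyperemic flow per unit subtended volume, ml/min per ml.
#' @param k_viscous Viscous loss coefficient (mmHg per (mm^-3 * ml/min)).
#' @param k_expansion Expansion loss coefficient (mmHg per (mm^-4 *
#'   (ml/min)^2)).
#' @param noise_sd SD of additive FFR measurement noise (0 = noiseless).
#' @param floor Lower clamp for FFR, keeping it in `(0, 1]`.
#' @return List of class `ffr_model_params`.
#' @export
ffr_model_params <- function(pa_mmHg = 90, q_flow = 2.5,
                             k_viscous = 0.031, k_expansion = 0.0073,
                             noise_sd = 0.04, floor = 0.01) {
  stopifnot(pa_mmHg > 0, q_flow >= 0, k_viscous >= 0, k_expansion >= 0,
            noise_sd >= 0, floor > 0, floor < 1)
  structure(list(pa_mmHg = pa_mmHg, q_flow = q_flow, k_viscous = k_viscous,
                 k_expansion = k_expansion, noise_sd = noise_sd,
                 floor = floor),
            class = "ffr_model_params")
}

#' Simulate FFR for lesion geometry and subtended mass
#'
#' Vectorized over lesions. With `noise_sd = 0` the result is a
#' deterministic, strictly decreasing function of MMAR and strictly
#' increasing function of MLD (at fixed RD, length).
#'
#' @param mmar_ml Subtended myocardial volume, ml (>= 0).
#' @param mld,rd Minimal lumen and reference diameters, mm
#'   (`0 < mld <= rd`).
#' @param length_mm Lesion length, mm (> 0).
#' @param params An [ffr_model_params()].
#' @return FFR values in `(0, 1]`.
#' @export
simulate_ffr <- function(mmar_ml, mld, rd, length_mm,
                         params = ffr_model_params()) {
  stopifnot(inherits(params, "ffr_model_params"))
  n <- max(length(mmar_ml), length(mld), length(rd), length(length_mm))
  mmar_ml <- rep_len(mmar_ml, n); mld <- rep_len(mld, n)
  rd <- rep_len(rd, n); length_mm <- rep_len(length_mm, n)
  if (any(mmar_ml < 0)) stop("`mmar_ml` must be non-negative")
  if (any(mld <= 0 | rd <= 0 | mld > rd)) {
    stop("lesion geometry must satisfy 0 < mld <= rd")
  }
  if (any(length_mm <= 0)) stop("`length_mm` must be positive")
  q <- params$q_flow * mmar_ml
  dp <- params$k_viscous * (length_mm / mld^4) * q +
    params$k_expansion * (1 / mld^2 - 1 / rd^2)^2 * q^2
  ffr <- (params$pa_mmHg - dp) / params$pa_mmHg
  if (params$noise_sd > 0) ffr <- ffr + rnorm(n, 0, params$noise_sd)
  pmin(1, pmax(params$floor, ffr))
}

#' Parameters of the synthetic lesion cohort
#'
#' Geometry marginals are log-normal with medians and spreads targeting a
#' representative intermediate-stenosis cohort: MLD median 1.39 mm, RD
#' median 2.65 mm, length median 12 mm; log-scale MLD--RD correlation 0.78
#' reproduces the observed diameter-stenosis spread (median near 47%,
#' interquartile range near 40--56%). Arteries are drawn with the observed
#' study mix (RCA 18%, LAD 60%, LCx 21%) and lesions sit at a mildly
#' proximal-weighted arc-length fraction of their branch.
#'
#' @param artery_prob Named sampling probabilities for RCA/LAD/LCx.
#' @param p_side Probability that a lesion sits on a side branch rather
#'   than the main branch.
#' @param arc_shape Beta shape parameters for the arc-length fraction.
#' @param arc_range Range the Beta fraction is mapped into.
#' @param mld_meanlog,mld_sdlog,rd_meanlog,rd_sdlog,len_meanlog,len_sdlog
#'   Log-normal geometry parameters (mm).
#' @param log_cor Correlation of log-MLD and log-RD.
#' @param proximal_frac Main-branch arc fraction at or below which a lesion
#'   is labeled proximal.
#' @return List of class `lesion_params`.
#' @export
lesion_params <- function(artery_prob = c(RCA = 27, LAD = 90, LCx = 32) / 149,
                          p_side = 0.12,
                          arc_shape = c(1.0, 3.2),
                          arc_range = c(0.02, 0.9),
                          mld_meanlog = log(1.39), mld_sdlog = 0.360,
                          rd_meanlog = log(2.65), rd_sdlog = 0.235,
                          log_cor = 0.78,
                          len_meanlog = log(12), len_sdlog = 0.542,
                          proximal_frac = 0.15) {
  stopifnot(all(artery_prob >= 0), sum(artery_prob) > 0,
            p_side >= 0, p_side <= 1, all(arc_shape > 0),
            arc_range[1] >= 0, arc_range[2] <= 1,
            arc_range[1] < arc_range[2],
            mld_sdlog > 0, rd_sdlog > 0, len_sdlog > 0,
            abs(log_cor) < 1, proximal_frac > 0, proximal_frac < 1)
  structure(as.list(environment()), class = "lesion_params")
}

# Correlated log-normal (MLD, RD) pairs with rejection of MLD >= RD.
draw_lesion_geometry <- function(n, lp) {
  mld <- numeric(n); rd <- numeric(n)
  todo <- seq_len(n)
  for (iter in 1:200) {
    m <- length(todo)
    if (m == 0L) break
    z1 <- rnorm(m)
    z2 <- lp$log_cor * z1 + sqrt(1 - lp$log_cor^2) * rnorm(m)
    mld_i <- exp(lp$mld_meanlog + lp$mld_sdlog * z1)
    rd_i <- exp(lp$rd_meanlog + lp$rd_sdlog * z2)
    ok <- mld_i < rd_i
    mld[todo[ok]] <- mld_i[ok]
    rd[todo[ok]] <- rd_i[ok]
    todo <- todo[!ok]
  }
  if (length(todo)) stop("geometry rejection sampling failed to converge")
  list(mld = mld, rd = rd, length = rlnorm(n, lp$len_meanlog, lp$len_sdlog))
}

#' Generate a synthetic lesion cohort
#'
#' Places `n` lesions at random arc-length positions on random branches of
#' the tree, draws lesion geometry from the log-normal model, computes each
#' lesion's MMAR geometrically through the Voronoi territory machinery
#' (one tessellation, shared by all lesions), and simulates FFR from the
#' pressure-loss model. All randomness is drawn from a single generator
#' seeded with `seed`, in a fixed documented order (arteries, branch
#' choices, arc fractions, geometry, FFR noise), so cohorts are
#' bit-reproducible.
#'
#' @param n Number of lesions (>= 0).
#' @param mask A [generate_lv_shell()] mask (or any [myocardium_mask()]).
#' @param tree A [centerline_tree()] on that geometry.
#' @param lp A [lesion_params()].
#' @param fp An [ffr_model_params()].
#' @param seed Integer run seed.
#' @param threshold FFR significance threshold.
#' @param max_spacing Densification step for the tessellation; default half
#'   the smallest voxel spacing.
#' @return Validated lesion table (see [read_lesion_table()] for columns);
#'   `n = 0` yields an empty table with the same columns.
#' @export
generate_cohort <- function(n, mask, tree, lp = lesion_params(),
                            fp = ffr_model_params(), seed = 1,
                            threshold = 0.8, max_spacing = NULL) {
  stopifnot(n >= 0, inherits(mask, "myocardium_mask"),
            inherits(tree, "centerline_tree"))
  empty <- data.frame(
    lesion_id = integer(0), artery = character(0), proximal = logical(0),
    mld_mm = numeric(0), rd_mm = numeric(0), length_mm = numeric(0),
    ds_pct = numeric(0), mmar_ml = numeric(0), pct_mmar = numeric(0),
    ffr = numeric(0), mmar_mld = numeric(0), significant = logical(0)
  )
  if (n == 0L) return(empty)
  set.seed(seed)
  if (is.null(max_spacing)) max_spacing <- 0.5 * min(mask$spacing)
  stree <- densify_centerline(tree, max_spacing)
  labels <- assign_voxels(mask, stree)
  fg_labels <- labels[mask$grid]
  n_total <- length(fg_labels)
  vox_ml <- voxel_volume_ml(mask)
  counts <- tabulate(fg_labels, nbins = nrow(stree$samples))

  s <- stree$samples
  branch_len <- tapply(s$arc, interaction(s$artery, s$branch, drop = TRUE),
                       max)
  side_branches <- lapply(split(s$branch, s$artery), function(b) {
    sort(setdiff(unique(b), "main"))
  })

  # documented draw order: arteries, side usage, branch picks, arc
  # fractions, geometry, FFR noise (inside simulate_ffr)
  arteries <- sample(names(lp$artery_prob), n, replace = TRUE,
                     prob = lp$artery_prob)
  on_side <- runif(n) < lp$p_side
  branch <- rep("main", n)
  for (i in which(on_side)) {
    sb <- side_branches[[arteries[i]]]
    branch[i] <- if (length(sb)) sb[sample.int(length(sb), 1)] else "main"
  }
  frac <- lp$arc_range[1] +
    (lp$arc_range[2] - lp$arc_range[1]) * rbeta(n, lp$arc_shape[1],
                                                lp$arc_shape[2])
  geom <- draw_lesion_geometry(n, lp)

  mmar <- numeric(n)
  for (i in seq_len(n)) {
    len_key <- paste(arteries[i], branch[i], sep = ".")
    arc <- frac[i] * branch_len[[len_key]]
    distal <- distal_sample_set(
      stree, lesion_point(arteries[i], branch = branch[i], arc_mm = arc))
    mmar[i] <- sum(counts[distal]) * vox_ml
  }

  ffr <- simulate_ffr(mmar, geom$mld, geom$rd, geom$length, fp)
  df <- data.frame(
    lesion_id = seq_len(n),
    artery = arteries,
    proximal = branch == "main" & frac <= lp$proximal_frac,
    mld_mm = geom$mld, rd_mm = geom$rd, length_mm = geom$length,
    ds_pct = diameter_stenosis(geom$mld, geom$rd),
    mmar_ml = mmar,
    pct_mmar = 100 * mmar / (n_total * vox_ml),
    ffr = ffr
  )
  validate_lesion_table(df, threshold = threshold)
}
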