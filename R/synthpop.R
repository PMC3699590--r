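#' Parameters for the synthetic labeled population
#'
#' Describes the phantom anatomy and the population it generates: an
#' ellipsoidal brain composed of a cortical shell, a white-matter shell, a
#' deep shell and interior nuclei, one region per spec row, with per-region
#' relative T1 intensity, FA and relative MD targets; inter-subject
#' variability enters as smooth random deformations plus fresh additive
#' noise. Defaults reproduce the reference rabbit-like statistics
#' ([default_region_specs()]) with 10 subjects.
#'
#' @param grid_shape Integer length-3 grid (default 48^3).
#' @param region_specs Data frame as returned by [default_region_specs()].
#' @param deform_amplitude Max voxel displacement of the per-subject random
#'   deformations (voxels).
#' @param deform_smoothness Gaussian sigma of the deformations (voxels);
#'   keeping it well above the amplitude prevents folding.
#' @param n_subjects Population size (default 10).
#' @param noise_sd_frac Per-subject additive Gaussian noise, as a fraction
#'   of the intensity range (default 0.05).
#' @param intensity_scale Global T1 scale: voxel intensity is
#'   `intensity_scale * (relative T1 + region noise)`.
#' @param seed Integer master seed; all randomness derives from it.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(grid_shape = c(48L, 48L, 48L),
                         region_specs = default_region_specs(),
                         deform_amplitude = 2, deform_smoothness = 6,
                         n_subjects = 10L, noise_sd_frac = 0.05,
                         intensity_scale = 100, seed = 1L) {
  if (sum(region_specs$vol_frac) >= 1)
    stop("region volume fractions must sum to < 1 (the rest is background)")
  if (deform_amplitude < 0) stop("deform_amplitude must be >= 0")
  if (deform_smoothness <= 0) stop("deform_smoothness must be > 0")
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  structure(list(grid_shape = as.integer(grid_shape),
                 region_specs = region_specs,
                 deform_amplitude = deform_amplitude,
                 deform_smoothness = deform_smoothness,
                 n_subjects = as.integer(n_subjects),
                 noise_sd_frac = noise_sd_frac,
                 intensity_scale = intensity_scale,
                 seed = as.integer(seed)),
            class = "synth_params")
}

# Normalized coordinates of every voxel: the brain is the unit ball of
# u = (index - center) / semi_axes, so azimuthal sectors and radial shells
# have exactly proportional volumes.
phantom_coords <- function(dims) {
  center <- (dims - 1) / 2
  semi <- c(0.40, 0.34, 0.30) * dims
  u1 <- (seq_len(dims[1]) - 1 - center[1]) / semi[1]
  u2 <- (seq_len(dims[2]) - 1 - center[2]) / semi[2]
  u3 <- (seq_len(dims[3]) - 1 - center[3]) / semi[3]
  U1 <- array(u1, dims)
  U2 <- array(rep(u2, each = dims[1]), dims)
  U3 <- array(rep(u3, each = dims[1] * dims[2]), dims)
  list(U1 = U1, U2 = U2, U3 = U3,
       rho = sqrt(U1^2 + U2^2 + U3^2),
       phi = atan2(U2, U1))
}

# Interior nuclei slots: centers and semi-axis shape ratios in normalized
# coordinates; blob k gets slot k, scaled so its volume fraction is met.
blob_slots <- function() {
  list(
    list(center = c(0, -0.38, 0), ratios = c(2.2, 0.9, 1.2)),
    list(center = c(0, 0.35, 0), ratios = c(2.0, 1.26, 1.0)),
    list(center = c(0, 0, 0.58), ratios = c(1, 1, 1)),
    list(center = c(0, 0, -0.58), ratios = c(1, 1, 1)),
    list(center = c(0.55, 0, 0), ratios = c(1, 1, 1)),
    list(center = c(-0.55, 0, 0), ratios = c(1, 1, 1)))
}

# Assign azimuthal sectors of a radial shell to regions, angular width
# proportional to the volume fractions.
assign_sectors <- function(lab, in_shell, phi, ids, fracs) {
  if (!length(ids)) return(lab)
  shares <- fracs / sum(fracs)
  edges <- -pi + 2 * pi * cumsum(c(0, shares))
  for (k in seq_along(ids)) {
    sel <- in_shell & phi >= edges[k] & (phi < edges[k + 1] | k == length(ids))
    lab[sel] <- ids[k]
  }
  lab
}

#' Generate the base labeled phantom
#'
#' Deterministic given the seed. The brain is an ellipsoid filling ~80% of
#' the grid extent; cortical regions tile the outer shell as azimuthal
#' sectors, white-matter and "other"-group regions share the next band as
#' sectors (so each remains at least a voxel or two thick at desk-scale
#' grids), and deep-gray regions become interior nuclei (ellipsoidal blobs
#' clipped to the core). Shell radii are chosen so each layer's volume
#' equals its regions' summed target fractions; sector angles are
#' proportional to the individual fractions. Voxel intensity is
#' `intensity_scale * (relative T1 + N(0, t1_sd))` per region and 0 in the
#' background (including the unassigned central core).
#'
#' @param p A [synth_params()].
#' @param noise Add the per-region T1 noise (disable for a clean base).
#' @return List with `volume` ([volume()]) and `labels` ([label_map()]).
#' @export
make_phantom <- function(p, noise = TRUE) {
  stopifnot(inherits(p, "synth_params"))
  dims <- p$grid_shape
  rs <- p$region_specs
  co <- phantom_coords(dims)
  lab <- array(0L, dims)
  f_cx <- sum(rs$vol_frac[rs$group == "cortical"])
  f_band <- sum(rs$vol_frac[rs$group %in% c("white_matter", "other")])
  r1 <- (1 - f_cx)^(1 / 3)
  r3 <- (r1^3 - f_band)^(1 / 3)
  cx <- rs$group == "cortical"
  lab <- assign_sectors(lab, co$rho <= 1 & co$rho > r1, co$phi,
                        rs$region_id[cx], rs$vol_frac[cx])
  # white-matter and "other" structures share one sub-cortical band: every
  # sector is then at least a voxel or two thick at desk-scale grids, which
  # keeps all regions representable (and radiologically meaningful) on the
  # grid instead of producing sub-voxel full shells
  bd <- rs$group %in% c("white_matter", "other")
  bd_order <- c(which(rs$group == "white_matter"), which(rs$group == "other"))
  lab <- assign_sectors(lab, co$rho <= r1 & co$rho > r3, co$phi,
                        rs$region_id[bd_order], rs$vol_frac[bd_order])
  dg <- which(rs$group == "deep_gray")
  slots <- blob_slots()
  if (length(dg) > length(slots))
    stop("cannot pack more than ", length(slots), " deep_gray nuclei: ",
         paste(rs$name[dg[-seq_along(slots)]], collapse = ", "))
  brain_n <- sum(co$rho <= 1)
  bad <- character(0)
  for (k in seq_along(dg)) {
    i <- dg[k]
    slot <- slots[[k]]
    t3 <- (rs$vol_frac[i] / prod(slot$ratios))^(1 / 3)
    semi <- slot$ratios * t3
    m <- ((co$U1 - slot$center[1]) / semi[1])^2 +
         ((co$U2 - slot$center[2]) / semi[2])^2 +
         ((co$U3 - slot$center[3]) / semi[3])^2 <= 1
    claim <- m & co$rho <= r3 & lab == 0L
    realized <- sum(claim) / brain_n
    if (realized < 0.8 * rs$vol_frac[i])
      bad <- c(bad, rs$name[i])
    lab[claim] <- rs$region_id[i]
  }
  if (length(bad))
    stop("region specs cannot be packed into the grid (realized volume ",
         "more than 20% short of target): ", paste(bad, collapse = ", "))
  rt <- region_table(rs[, c("region_id", "name", "group", "hemisphere")])
  intens <- array(0, dims)
  if (noise) set.seed(p$seed)
  for (i in seq_len(nrow(rs))) {
    sel <- lab == rs$region_id[i]
    n <- sum(sel)
    if (!n) next
    val <- rs$t1[i]
    intens[sel] <- p$intensity_scale *
      (val + if (noise && rs$t1_sd[i] > 0) stats::rnorm(n, 0, rs$t1_sd[i])
             else 0)
  }
  out <- list(volume = volume(intens), labels = label_map(lab, rt))
  attr(out, "brain_voxels") <- brain_n
  out
}

#' Smooth random deformation field
#'
#' Gaussian-smoothed white-noise vector field rescaled so the maximum voxel
#' displacement equals `amplitude` exactly. Reproducible given the seed;
#' amplitude well below the smoothness keeps the Jacobian positive (no
#' folding) in practice.
#'
#' @param shape Integer length-3 grid.
#' @param amplitude Maximum displacement norm in voxels (>= 0).
#' @param smoothness Gaussian sigma in voxels.
#' @param seed Integer seed.
#' @return A `displacement_field`.
#' @export
random_deformation <- function(shape, amplitude, smoothness, seed) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  shape <- as.integer(shape)
  if (amplitude == 0) return(zero_field(shape))
  set.seed(as.integer(seed))
  d <- array(stats::rnorm(prod(shape) * 3), c(shape, 3L))
  for (k in 1:3) d[, , , k] <- gauss_smooth(d[, , , k], smoothness)
  nmax <- sqrt(max(d[, , , 1]^2 + d[, , , 2]^2 + d[, , , 3]^2))
  displacement_field(d * (amplitude / nmax))
}

#' Generate a synthetic population
#'
#' Subject `i` is the clean base phantom warped by its own smooth random
#' deformation, with fresh per-region T1 noise and global additive noise;
#' its label map is the nearest-neighbour warp of the base labels. The
#' generating fields are returned so registration accuracy can be scored
#' against ground truth.
#'
#' @param p A [synth_params()].
#' @return List with `base` (clean phantom, see [make_phantom()]) and
#'   `subjects`: a list of `list(volume, labels, field, seed)` of length
#'   `n_subjects`.
#' @export
synth_population <- function(p) {
  stopifnot(inherits(p, "synth_params"))
  base <- make_phantom(p, noise = FALSE)
  rng <- max(base$volume$data) - min(base$volume$data)
  subjects <- vector("list", p$n_subjects)
  for (i in seq_len(p$n_subjects)) {
    sub_seed <- (p$seed + 7919L * i) %% .Machine$integer.max
    f <- random_deformation(p$grid_shape, p$deform_amplitude,
                            p$deform_smoothness, sub_seed)
    vol <- warp_volume(base$volume, f)
    labs <- warp_volume(base$labels, f)
    set.seed(sub_seed + 1L)
    rs <- p$region_specs
    for (j in seq_len(nrow(rs))) {
      sel <- labs$labels == rs$region_id[j]
      n <- sum(sel)
      if (n && rs$t1_sd[j] > 0)
        vol$data[sel] <- vol$data[sel] +
          p$intensity_scale * stats::rnorm(n, 0, rs$t1_sd[j])
    }
    if (p$noise_sd_frac > 0)
      vol$data <- vol$data +
        stats::rnorm(length(vol$data), 0, p$noise_sd_frac * rng)
    subjects[[i]] <- list(volume = volume(vol$data), labels = labs,
                          field = f, seed = sub_seed)
  }
  list(base = base, subjects = subjects)
}

#' Deterministic well-spread gradient directions
#'
#' Fibonacci-sphere unit vectors, adequate as a synthetic diffusion
#' encoding scheme (any >= 6 non-collinear set identifies the tensor).
#'
#' @param n Number of directions (default 12).
#' @return 3 x n matrix of unit vectors.
#' @export
gradient_directions <- function(n = 12L) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  th <- golden * (seq_len(n) - 1)
  m <- rbind(r * cos(th), r * sin(th), z)
  dimnames(m) <- NULL
  m
}

# Closed-form eigenvalues of a cylindrically symmetric tensor with mean
# diffusivity m and fractional anisotropy fa_t (lambda2 = lambda3).
cylindrical_eigenvalues <- function(m, fa_t) {
  if (fa_t >= 1) stop("FA target must be < 1 for a cylindrical tensor")
  delta <- fa_t / sqrt(3 - 2 * fa_t^2)
  c(m * (1 + 2 * delta), m * (1 - delta), m * (1 - delta))
}

#' Synthesize a diffusion-weighted set from a parcellation
#'
#' Each region gets a cylindrically symmetric tensor whose trace is three
#' times its (relative) MD target scaled by `md_scale` and whose FA matches
#' the region target, principal axis fixed per region; background is
#' isotropic with the mean tissue diffusivity. Signals follow the
#' monoexponential model with optional additive Gaussian noise.
#'
#' @param labels A [label_map()].
#' @param p A [synth_params()] providing per-region `fa` and `md` targets.
#' @param bvecs 3 x n unit directions (default [gradient_directions()]).
#' @param bval b-value in s/mm^2 applied to all weighted volumes.
#' @param s0 Baseline signal.
#' @param noise_sd Additive signal noise SD (0 = noiseless).
#' @param seed Seed for the noise.
#' @param md_scale Absolute diffusivity (mm^2/s) corresponding to a
#'   relative MD of 1.
#' @return A [dwi_set()], with attribute `true_tensors` (region id ->
#'   6-component tensor) for validation.
#' @export
synth_dwi <- function(labels, p, bvecs = gradient_directions(12L),
                      bval = 3000, s0 = 100, noise_sd = 0, seed = 1L,
                      md_scale = 2e-4) {
  stopifnot(inherits(labels, "label_map"), inherits(p, "synth_params"))
  if (ncol(bvecs) < 6L) stop("need >= 6 gradient directions")
  rs <- p$region_specs
  dims <- dim(labels$labels)
  nvox <- prod(dims)
  lab <- as.vector(labels$labels)
  # per-voxel tensor components Dxx Dyy Dzz Dxy Dxz Dyz
  Dv <- matrix(0, nvox, 6)
  axes <- gradient_directions(max(nrow(rs), 6L))
  true_tensors <- matrix(0, nrow(rs), 6,
                         dimnames = list(as.character(rs$region_id), NULL))
  for (i in seq_len(nrow(rs))) {
    lam <- cylindrical_eigenvalues(rs$md[i] * md_scale, rs$fa[i])
    a <- axes[, i]
    D <- lam[2] * diag(3) + (lam[1] - lam[2]) * (a %*% t(a))
    comp <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
    true_tensors[i, ] <- comp
    sel <- lab == rs$region_id[i]
    if (any(sel)) Dv[sel, ] <- matrix(comp, sum(sel), 6, byrow = TRUE)
  }
  bg <- lab == 0L
  if (any(bg)) {
    m_bg <- mean(rs$md) * md_scale
    Dv[bg, c(1, 2, 3)] <- m_bg
  }
  if (noise_sd > 0) set.seed(as.integer(seed))
  weighted <- vector("list", ncol(bvecs))
  for (j in seq_len(ncol(bvecs))) {
    g <- bvecs[, j]
    q <- c(g[1]^2, g[2]^2, g[3]^2, 2 * g[1] * g[2], 2 * g[1] * g[3],
           2 * g[2] * g[3])
    S <- s0 * exp(-bval * as.vector(Dv %*% q))
    if (noise_sd > 0) S <- S + stats::rnorm(nvox, 0, noise_sd)
    weighted[[j]] <- volume(array(S, dims), labels$spacing, labels$origin)
  }
  out <- dwi_set(volume(array(s0, dims), labels$spacing, labels$origin),
                 weighted, rep(bval, ncol(bvecs)), bvecs)
  attr(out, "true_tensors") <- true_tensors
  out
}

#' Write a synthetic population to a directory
#'
#' Emits `subject_XX_t1.nii.gz`, `subject_XX_labels.nii.gz`,
#' `subject_XX_field.nii.gz` per subject plus `base_t1.nii.gz`,
#' `base_labels.nii.gz`, `regions.tsv` and `params.json`.
#'
#' @param pop Result of [synth_population()].
#' @param dir Output directory.
#' @param p The [synth_params()] used (recorded in `params.json`).
#' @return `dir`, invisibly.
#' @export
write_population <- function(pop, dir, p) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(pop$base$volume, file.path(dir, "base_t1.nii.gz"))
  write_label_map(pop$base$labels, file.path(dir, "base_labels.nii.gz"),
                  file.path(dir, "regions.tsv"))
  for (i in seq_along(pop$subjects)) {
    s <- pop$subjects[[i]]
    write_volume(s$volume, file.path(dir, sprintf("subject_%02d_t1.nii.gz", i)))
    write_label_map(s$labels,
                    file.path(dir, sprintf("subject_%02d_labels.nii.gz", i)),
                    file.path(dir, "regions.tsv"))
    write_field(s$field, file.path(dir, sprintf("subject_%02d_field.nii.gz", i)))
  }
  pl <- unclass(p)
  pl$region_specs <- NULL
  jsonlite::write_json(pl, file.path(dir, "params.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
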