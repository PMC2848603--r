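#' Specification of a synthetic microscope field
#'
#' Defines the statistical and optical structure of a rendered field of
#' subconfluent adherent cells: irregular star-convex cell bodies (truncated
#' Fourier perturbation of a disk), one nucleus per cell, a requested
#' fraction of cells placed so their bodies touch, a non-uniform background
#' (level plus linear gradient) with additive Gaussian noise, lognormal
#' per-cell antigen totals split between nucleus and cytoplasm, a G2
#' subpopulation with doubled DNA signal, and an optional integer chromatic
#' shift of the cell channel.
#'
#' Defaults emulate a 10x field: radius-14 px cells (about a third of the
#' area occupied by the nucleus), 20% of cells touching, background 100 with
#' a gentle gradient and SD-5 noise, stains well above the 3-SD detection
#' threshold, and 30% G2 cells.
#'
#' @param field_size_px Square field side (default 512).
#' @param n_cells Number of cells (default 50).
#' @param touching_fraction Fraction of cells placed as touching pairs
#'   (default 0.2).
#' @param cell_radius_mean,cell_radius_sd Cell body radius distribution in
#'   px (defaults 14, 2).
#' @param nucleus_area_ratio Nucleus/cell area ratio (default 0.35).
#' @param contour_irregularity Relative amplitude of the radial contour
#'   perturbation (default 0.12; nuclei use half).
#' @param background_level Background intensity (default 100).
#' @param background_gradient Background slope per pixel along x
#'   (default 0.05).
#' @param noise_sd Additive Gaussian noise SD, all channels (default 5).
#' @param nuclear_stain_level Nuclear stain above background for G1 cells;
#'   G2 cells get twice this (default 500).
#' @param cell_stain_level Cell stain above background at the nucleus;
#'   intensity falls off linearly to 65% at the cell edge, mimicking cell
#'   thickness (default 180).
#' @param antigen_log_mean,antigen_log_sd Lognormal parameters of per-cell
#'   antigen totals (defaults `log(5e4)`, 0.5).
#' @param nuclear_fraction_of_antigen Fraction of each cell's antigen placed
#'   in the nucleus (default 0.5).
#' @param g2_fraction Fraction of cells in G2 (default 0.3).
#' @param chromatic_shift_px Integer (row, col) shift applied to the cell
#'   channel only (default `c(0, 0)`).
#' @param antigen_names Names of the antigen channels (default `"pERK"`).
#' @param seed Mandatory RNG seed; generation is fully deterministic.
#' @return A list of class `"synthetic_field_spec"`.
#' @export
synthetic_field_spec <- function(field_size_px = 512L, n_cells = 50L,
                                 touching_fraction = 0.2,
                                 cell_radius_mean = 14, cell_radius_sd = 2,
                                 nucleus_area_ratio = 0.35,
                                 contour_irregularity = 0.12,
                                 background_level = 100,
                                 background_gradient = 0.05,
                                 noise_sd = 5,
                                 nuclear_stain_level = 500,
                                 cell_stain_level = 180,
                                 antigen_log_mean = log(5e4),
                                 antigen_log_sd = 0.5,
                                 nuclear_fraction_of_antigen = 0.5,
                                 g2_fraction = 0.3,
                                 chromatic_shift_px = c(0L, 0L),
                                 antigen_names = "pERK",
                                 seed) {
  if (missing(seed) || is.null(seed))
    stop("a seed is mandatory for reproducible generation", call. = FALSE)
  for (f in c(touching_fraction, nucleus_area_ratio,
              nuclear_fraction_of_antigen, g2_fraction))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (background_level < 0 || noise_sd < 0 || nuclear_stain_level < 0 ||
      cell_stain_level < 0)
    stop("levels must be >= 0", call. = FALSE)
  structure(list(field_size_px = as.integer(field_size_px),
                 n_cells = as.integer(n_cells),
                 touching_fraction = touching_fraction,
                 cell_radius_mean = cell_radius_mean,
                 cell_radius_sd = cell_radius_sd,
                 nucleus_area_ratio = nucleus_area_ratio,
                 contour_irregularity = contour_irregularity,
                 background_level = background_level,
                 background_gradient = background_gradient,
                 noise_sd = noise_sd,
                 nuclear_stain_level = nuclear_stain_level,
                 cell_stain_level = cell_stain_level,
                 antigen_log_mean = antigen_log_mean,
                 antigen_log_sd = antigen_log_sd,
                 nuclear_fraction_of_antigen = nuclear_fraction_of_antigen,
                 g2_fraction = g2_fraction,
                 chromatic_shift_px = as.integer(chromatic_shift_px),
                 antigen_names = antigen_names,
                 seed = as.integer(seed)),
            class = "synthetic_field_spec")
}

# Evaluate a star-convex radial contour r(theta) = R * (1 + sum_k a_k
# cos(k theta + phi_k)), k = 2..4. Amplitudes are scaled so the total
# perturbation never exceeds `irregularity`.
.radial_shape <- function(irregularity) {
  k <- 2:4
  u <- runif(3)
  a <- if (sum(u) > 0) irregularity * u / sum(u) else u
  phi <- runif(3, 0, 2 * pi)
  list(k = k, a = a, phi = phi)
}

.radial_eval <- function(shape, theta) {
  out <- rep(1, length(theta))
  for (i in seq_along(shape$k))
    out <- out + shape$a[i] * cos(shape$k[i] * theta + shape$phi[i])
  out
}

#' Render a synthetic field with exact ground truth
#'
#' Places the requested cells (singles kept apart, the touching fraction
#' placed as overlapping-body pairs whose contact pixels go to the nearer
#' cell in units of normalized radius), renders the nuclear, cell and
#' antigen channels, adds background plane, gradient and noise, applies the
#' chromatic shift to the cell channel, and returns both the
#' [field_image_set()] and the exact ground truth.
#'
#' @param spec A [synthetic_field_spec()].
#' @param antigen_totals Optional matrix (n_cells x n_antigen) of per-cell
#'   antigen totals, overriding the lognormal draw (used to plant known
#'   population structure).
#' @param well_id,field_index,time_min,treatment,experiment_id Metadata for
#'   the generated field.
#' @return A list with `field` (the [field_image_set()]) and `truth`: exact
#'   `nuclear_mask` and `cell_mask` [label_mask()]s, plus a `cells` data
#'   frame (centre, radius, DNA class, true antigen totals and nuclear
#'   fractions, areas).
#' @export
generate_field <- function(spec, antigen_totals = NULL, well_id = "A01",
                           field_index = 1L, time_min = NA_real_,
                           treatment = NA_character_, experiment_id = "exp1") {
  stopifnot(inherits(spec, "synthetic_field_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed)

  n <- spec$n_cells
  sz <- spec$field_size_px
  n_pairs <- round(spec$touching_fraction * n / 2)
  radii <- pmax(6, rnorm(n, spec$cell_radius_mean, spec$cell_radius_sd))
  margin <- max(radii) * (1 + spec$contour_irregularity) + 3
  if (2 * margin >= sz)
    stop("field too small for the requested cell size", call. = FALSE)

  centers <- matrix(NA_real_, n, 2)
  is_pair_member <- rep(FALSE, n)
  placed <- 0L
  clearance <- function(i, cx, cy, extra = 6) {
    if (placed == 0L) return(TRUE)
    d <- sqrt((centers[seq_len(placed), 1] - cx)^2 +
                (centers[seq_len(placed), 2] - cy)^2)
    all(d > radii[seq_len(placed)] + radii[i] + extra)
  }
  place_one <- function(i, extra = 6) {
    for (try in 1:4000) {
      cx <- runif(1, margin, sz - margin)
      cy <- runif(1, margin, sz - margin)
      if (clearance(i, cx, cy, extra)) return(c(cx, cy))
    }
    stop("could not place all cells without overlap; reduce n_cells",
         call. = FALSE)
  }
  i <- 1L
  for (p in seq_len(n_pairs)) {
    j <- i + 1L
    repeat {
      anchor <- place_one(i, extra = 6 + 2 * radii[j])
      ang <- runif(1, 0, 2 * pi)
      d <- 0.92 * (radii[i] + radii[j])
      partner <- anchor + d * c(cos(ang), sin(ang))
      if (partner[1] > margin && partner[1] < sz - margin &&
          partner[2] > margin && partner[2] < sz - margin) break
    }
    centers[i, ] <- anchor
    placed <- placed + 1L
    centers[j, ] <- partner
    placed <- placed + 1L
    is_pair_member[c(i, j)] <- TRUE
    i <- j + 1L
  }
  while (i <= n) {
    centers[i, ] <- place_one(i)
    placed <- placed + 1L
    i <- i + 1L
  }

  shapes <- lapply(seq_len(n), function(i) .radial_shape(spec$contour_irregularity))
  nshapes <- lapply(seq_len(n), function(i) .radial_shape(spec$contour_irregularity / 2))
  nuc_radii <- radii * sqrt(spec$nucleus_area_ratio)

  cell_mask <- matrix(0L, sz, sz)
  norm_dist <- matrix(Inf, sz, sz)  # ownership: smaller rho / r(theta) wins
  nuc_mask <- matrix(0L, sz, sz)
  for (i in seq_len(n)) {
    R <- radii[i] * (1 + spec$contour_irregularity)
    r1 <- max(1L, floor(centers[i, 1] - R)); r2 <- min(sz, ceiling(centers[i, 1] + R))
    c1 <- max(1L, floor(centers[i, 2] - R)); c2 <- min(sz, ceiling(centers[i, 2] + R))
    rr <- r1:r2; cc <- c1:c2
    dx <- rr - centers[i, 1]
    dy <- cc - centers[i, 2]
    DX <- matrix(dx, length(rr), length(cc))
    DY <- matrix(dy, length(rr), length(cc), byrow = TRUE)
    rho <- sqrt(DX^2 + DY^2)
    theta <- atan2(DY, DX)
    rmax <- radii[i] * .radial_eval(shapes[[i]], theta)
    nd <- rho / rmax
    inside <- nd <= 1
    sub_lin <- outer(rr, (cc - 1L) * sz, `+`)
    win <- inside & nd < norm_dist[sub_lin]
    idx <- sub_lin[win]
    cell_mask[idx] <- i
    norm_dist[idx] <- nd[win]
    # nucleus: same centre, smaller star shape; clipped to own cell later
    nrmax <- nuc_radii[i] * .radial_eval(nshapes[[i]], theta)
    nin <- rho <= nrmax
    nuc_mask[sub_lin[nin]] <- i
  }
  nuc_mask[nuc_mask != cell_mask] <- 0L

  dna_class <- ifelse(runif(n) < spec$g2_fraction, "G2", "G1")
  n_ant <- length(spec$antigen_names)
  if (is.null(antigen_totals)) {
    antigen_totals <- matrix(rlnorm(n * n_ant, spec$antigen_log_mean,
                                    spec$antigen_log_sd), n, n_ant)
  } else {
    antigen_totals <- as.matrix(antigen_totals)
    stopifnot(nrow(antigen_totals) == n, ncol(antigen_totals) == n_ant)
  }

  cols_plane <- matrix(seq_len(sz) - 1L, sz, sz, byrow = TRUE)
  bg_plane <- spec$background_level + spec$background_gradient * cols_plane

  cell_areas <- tabulate(cell_mask[cell_mask > 0L], nbins = n)
  nuc_areas <- tabulate(nuc_mask[nuc_mask > 0L], nbins = n)

  # Nuclear channel. DNA content per cell is ploidy-determined, not
  # nucleus-size-determined: every G1 cell carries the same total (2x for
  # G2) up to a 5% staining jitter, so the per-pixel level scales inversely
  # with the rendered nuclear area. `nuclear_stain_level` is the per-pixel
  # level of a nominal (mean-geometry) G1 nucleus.
  nominal_nuc_area <- pi * spec$cell_radius_mean^2 * spec$nucleus_area_ratio
  dna_jitter <- pmax(0.5, rnorm(n, 1, 0.05))
  lev <- ifelse(dna_class == "G2", 2, 1) * spec$nuclear_stain_level *
    dna_jitter * nominal_nuc_area / pmax(nuc_areas, 1)
  nuc_stain <- matrix(0, sz, sz)
  sel <- nuc_mask > 0L
  nuc_stain[sel] <- lev[nuc_mask[sel]]

  # cell channel: thickness profile falling to 65% at the contour
  cel_stain <- matrix(0, sz, sz)
  sel <- cell_mask > 0L
  cel_stain[sel] <- spec$cell_stain_level * (1 - 0.35 * norm_dist[sel])
  if (any(spec$chromatic_shift_px != 0L))
    cel_stain <- .shift_matrix(cel_stain, spec$chromatic_shift_px)

  # antigen channels: per-cell total split between nucleus and cytoplasm;
  # nuclear_fraction_of_antigen may be per-channel (recycled), e.g. a
  # cytoplasmic kinase alongside a nuclear-translocating substrate
  fs <- rep_len(spec$nuclear_fraction_of_antigen, n_ant)
  cyto_areas <- cell_areas - nuc_areas
  ant_stains <- lapply(seq_len(n_ant), function(k) {
    f <- fs[k]
    st <- matrix(0, sz, sz)
    nuc_px <- ifelse(nuc_areas > 0, f * antigen_totals[, k] / pmax(nuc_areas, 1), 0)
    cyt_px <- ifelse(cyto_areas > 0,
                     (1 - f) * antigen_totals[, k] / pmax(cyto_areas, 1), 0)
    st[sel] <- cyt_px[cell_mask[sel]]
    nsel <- nuc_mask > 0L
    st[nsel] <- nuc_px[nuc_mask[nsel]]
    st
  })

  noisy <- function(stain) {
    pmax(stain + bg_plane + rnorm(sz * sz, 0, spec$noise_sd), 0)
  }
  nuclear_img <- noisy(nuc_stain)
  cell_img <- noisy(cel_stain)
  antigen_imgs <- lapply(ant_stains, noisy)
  names(antigen_imgs) <- spec$antigen_names

  field <- field_image_set(nuclear_img, cell_img, antigen_imgs,
                           well_id = well_id, field_index = field_index,
                           time_min = time_min, treatment = treatment,
                           experiment_id = experiment_id)
  truth_cells <- data.frame(cell_id = seq_len(n),
                            center_row = centers[, 1],
                            center_col = centers[, 2],
                            radius_px = radii,
                            dna_class = dna_class,
                            dna_total = lev * nuc_areas,
                            area_px = cell_areas,
                            nuclear_area_px = nuc_areas,
                            touching = is_pair_member,
                            stringsAsFactors = FALSE)
  for (k in seq_len(n_ant)) {
    truth_cells[[paste0("total_", spec$antigen_names[k])]] <- antigen_totals[, k]
    truth_cells[[paste0("nuclear_fraction_", spec$antigen_names[k])]] <- fs[k]
  }
  list(field = field,
       truth = list(nuclear_mask = label_mask(nuc_mask, "nuclear"),
                    cell_mask = label_mask(cell_mask, "cellular"),
                    cells = truth_cells,
                    noiseless_antigen = setNames(ant_stains, spec$antigen_names)))
}

# Integer translation with zero fill; shift = c(rows down, cols right).
.shift_matrix <- function(m, shift) {
  out <- matrix(0, nrow(m), ncol(m))
  sr <- shift[1]; sc <- shift[2]
  r_src <- seq_len(nrow(m)) - sr
  c_src <- seq_len(ncol(m)) - sc
  rok <- r_src >= 1 & r_src <= nrow(m)
  cok <- c_src >= 1 & c_src <= ncol(m)
  out[which(rok), which(cok)] <- m[r_src[rok], c_src[cok]]
  out
}

#' Synthetic per-cell MEK/ERK population with a planted noise schedule
#'
#' Generates per-cell measurements from the kinase-cascade mechanism the
#' correlation and SD trajectories probe: at each time point
#' \deqn{\log MEK \sim N(\mu_t, \sigma_{MEK}^2), \quad
#'       \log ERK = c \cdot \log MEK + \epsilon_t, \quad
#'       \epsilon_t \sim N(0, \sigma_\epsilon(t)^2)}
#' so the true log-Pearson correlation at time t is
#' \eqn{c\,\sigma_{MEK} / \sqrt{c^2 \sigma_{MEK}^2 + \sigma_\epsilon(t)^2}}:
#' a dephosphorylation noise term whose variance rises and falls produces a
#' falling-then-rising correlation trajectory with the ERK log-SD its mirror
#' image.
#'
#' @param n_cells Cells per time point.
#' @param time_grid Time points (minutes).
#' @param mek_log_mean Scalar or per-time vector \eqn{\mu_t}.
#' @param mek_log_sd \eqn{\sigma_{MEK}} (scalar).
#' @param coupling Coupling coefficient c (default 1).
#' @param noise_schedule Scalar or per-time vector \eqn{\sigma_\epsilon(t)}.
#' @param erk_log_offset Additive offset for log ERK (sets its scale).
#' @param channels Channel names (default `c("pMEK", "pERK")`).
#' @param seed Mandatory RNG seed.
#' @return A per-cell data frame (`cell_id`, `well_id`, `time_min`,
#'   `total_<ch>` columns) with attribute `true_params` holding the planted
#'   parameters and the closed-form correlation trajectory.
#' @export
generate_population <- function(n_cells, time_grid, mek_log_mean = log(1000),
                                mek_log_sd = 0.4, coupling = 1,
                                noise_schedule = 0, erk_log_offset = 0,
                                channels = c("pMEK", "pERK"), seed) {
  if (missing(seed) || is.null(seed))
    stop("a seed is mandatory for reproducible generation", call. = FALSE)
  stopifnot(mek_log_sd > 0, coupling >= 0, all(noise_schedule >= 0))
  nt <- length(time_grid)
  mu <- rep_len(mek_log_mean, nt)
  sig_eps <- rep_len(noise_schedule, nt)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  rows <- lapply(seq_len(nt), function(t) {
    lm <- rnorm(n_cells, mu[t], mek_log_sd)
    le <- coupling * lm + erk_log_offset + rnorm(n_cells, 0, sig_eps[t])
    out <- data.frame(cell_id = seq_len(n_cells),
                      well_id = sprintf("T%02d", t),
                      time_min = time_grid[t])
    out[[paste0("total_", channels[1])]] <- exp(lm)
    out[[paste0("total_", channels[2])]] <- exp(le)
    out
  })
  tab <- do.call(rbind, rows)
  true_cor <- coupling * mek_log_sd /
    sqrt(coupling^2 * mek_log_sd^2 + sig_eps^2)
  attr(tab, "true_params") <- list(mek_log_mean = mu, mek_log_sd = mek_log_sd,
                                   coupling = coupling,
                                   noise_schedule = sig_eps,
                                   log_pearson = true_cor,
                                   erk_log_sd = sqrt(coupling^2 * mek_log_sd^2 +
                                                       sig_eps^2))
  tab
}
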