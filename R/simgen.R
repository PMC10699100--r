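#' Antibody model for simulation
#'
#' Describes one primary antibody entering the simulator: its true relative
#' binding efficiency `rho` (the dimensionless quantity the downstream
#' regression estimates), the Langmuir half-saturation concentration `K_p`
#' of its binding to the epitope, and whether it is an irrelevant control.
#' Controls bind nothing specific, so their efficiency is forced to zero.
#'
#' @param antibody_id Character label, e.g. `"ref"` or `"ctrl"`.
#' @param rho True relative binding efficiency, dimensionless, `>= 0`.
#' @param K_p Half-saturation concentration of the primary antibody in
#'   ng/mL, `> 0`. The default 76.9 ng/mL makes a 100-fold dilution from
#'   5000 to 50 ng/mL lose 60% of the specific signal.
#' @param is_control Logical; an irrelevant antibody. Forces `rho = 0`.
#'
#' @return An object of class `antibody_model`.
#' @export
antibody_model <- function(antibody_id, rho, K_p = 76.9, is_control = FALSE) {
  stopifnot(is.character(antibody_id), length(antibody_id) == 1L, nzchar(antibody_id))
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || rho < 0)
    stop("'rho' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(K_p) || length(K_p) != 1L || is.na(K_p) || K_p <= 0)
    stop("'K_p' must be a single positive number (ng/mL)", call. = FALSE)
  if (isTRUE(is_control) && rho != 0) {
    warning("control antibody: forcing rho = 0", call. = FALSE)
    rho <- 0
  }
  structure(
    list(antibody_id = antibody_id, rho = rho, K_p = K_p,
         is_control = isTRUE(is_control)),
    class = "antibody_model"
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic two-channel immunofluorescence image
#' generator. Cells are elliptical membrane annuli (the fusion protein is
#' surface-localized); per-cell expression is log-normal (transient
#' transfection is heterogeneous); each channel's expected membrane
#' intensity is `background + gain * expression * detection`, where
#' detection combines Langmuir primary-antibody occupancy with a
#' proportional secondary-antibody factor; noise is Gaussian with variance
#' proportional to the expected mean (shot-noise approximation), then
#' rounded and clipped to the bit-depth ceiling.
#'
#' @param width,height Image size in pixels.
#' @param bit_depth Bits per pixel; intensities live in `[0, 2^bit_depth - 1]`.
#' @param n_cells Number of cells placed per image.
#' @param transfected_fraction Fraction of cells expressing the fusion
#'   protein; the rest render background only in both channels.
#' @param expression_mu,expression_sigma Log-normal parameters (meanlog,
#'   sdlog) of per-cell expression.
#' @param ring_radius_range Length-2 numeric, pixels; ellipse semi-axes are
#'   drawn uniformly from this range.
#' @param ring_thickness Membrane annulus thickness, pixels.
#' @param gain_ref,gain_tag Intensity counts per expression unit per channel.
#' @param background_ref,background_tag Additive per-pixel offsets.
#' @param noise_factor Variance-to-mean ratio of the noise; 0 disables noise.
#' @param primary_conc Anti-tag primary antibody concentration, ng/mL.
#' @param secondary_scale Fraction of the recommended secondary-antibody
#'   concentration, in `[0, 1]`; the secondary is the limiting reagent, so
#'   detection scales proportionally with it.
#' @param ref_primary_conc,ref_K_p Concentration and half-saturation of the
#'   reference-channel (anti-carrier) antibody, held fixed across conditions.
#' @param s_max Plateau signal, arbitrary units, used by
#'   [simulate_dilution_series()].
#' @param seed Integer RNG seed, or `NULL` to leave the RNG stream alone.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
simulation_config <- function(width = 512L, height = 512L, bit_depth = 16L,
                              n_cells = 30L, transfected_fraction = 0.7,
                              expression_mu = 0, expression_sigma = 0.6,
                              ring_radius_range = c(18, 30), ring_thickness = 4,
                              gain_ref = 3000, gain_tag = 3000,
                              background_ref = 150, background_tag = 120,
                              noise_factor = 4,
                              primary_conc = 5000, secondary_scale = 1,
                              ref_primary_conc = 5000, ref_K_p = 76.9,
                              s_max = 100, seed = NULL) {
  cfg <- list(width = as.integer(width), height = as.integer(height),
              bit_depth = as.integer(bit_depth), n_cells = as.integer(n_cells),
              transfected_fraction = transfected_fraction,
              expression_mu = expression_mu, expression_sigma = expression_sigma,
              ring_radius_range = as.numeric(ring_radius_range),
              ring_thickness = ring_thickness,
              gain_ref = gain_ref, gain_tag = gain_tag,
              background_ref = background_ref, background_tag = background_tag,
              noise_factor = noise_factor,
              primary_conc = primary_conc, secondary_scale = secondary_scale,
              ref_primary_conc = ref_primary_conc, ref_K_p = ref_K_p,
              s_max = s_max,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (width < 1L || height < 1L) stop("image dimensions must be positive", call. = FALSE)
    if (bit_depth < 1L || bit_depth > 16L) stop("bit_depth must be in 1..16", call. = FALSE)
    if (n_cells < 0L) stop("n_cells must be >= 0", call. = FALSE)
    if (transfected_fraction < 0 || transfected_fraction > 1)
      stop("transfected_fraction must lie in [0, 1]", call. = FALSE)
    if (any(c(gain_ref, gain_tag, background_ref, background_tag, noise_factor) < 0))
      stop("gains, backgrounds and noise_factor must be >= 0", call. = FALSE)
    if (length(ring_radius_range) != 2L || any(ring_radius_range <= 0) ||
        ring_radius_range[1] > ring_radius_range[2])
      stop("ring_radius_range must be an increasing positive pair", call. = FALSE)
    if (ring_thickness <= 0) stop("ring_thickness must be > 0", call. = FALSE)
    if (expression_sigma < 0) stop("expression_sigma must be >= 0", call. = FALSE)
    if (primary_conc < 0 || ref_primary_conc < 0)
      stop("antibody concentrations must be >= 0", call. = FALSE)
    if (ref_K_p <= 0) stop("ref_K_p must be > 0", call. = FALSE)
    if (secondary_scale < 0 || secondary_scale > 1)
      stop("secondary_scale must lie in [0, 1]", call. = FALSE)
    if (s_max < 0) stop("s_max must be >= 0", call. = FALSE)
  })
  invisible(cfg)
}

#' Langmuir primary-antibody occupancy
#'
#' Equilibrium bound fraction of epitopes at primary-antibody concentration
#' `conc`: `theta(c) = c / (c + K_p)`. Strictly increasing in `conc`,
#' strictly decreasing in `K_p`, with range in `[0, 1)`.
#'
#' @param conc Concentration in ng/mL, `>= 0`. Vectorized.
#' @param K_p Half-saturation concentration in ng/mL, `> 0`.
#' @return Bound fraction(s) in `[0, 1)`.
#' @examples
#' primary_occupancy(76.9, 76.9)          # 0.5 at half-saturation
#' 100 * (1 - primary_occupancy(50, 76.9) / primary_occupancy(5000, 76.9))
#' @export
primary_occupancy <- function(conc, K_p) {
  if (!is.numeric(conc) || any(is.na(conc)) || any(conc < 0))
    stop("'conc' must be non-negative (ng/mL)", call. = FALSE)
  if (!is.numeric(K_p) || any(is.na(K_p)) || any(K_p <= 0))
    stop("'K_p' must be positive (ng/mL)", call. = FALSE)
  conc / (conc + K_p)
}

#' Secondary-antibody detection factor
#'
#' The fluorescent secondary antibody is the limiting reagent: diluting it
#' reduces the observed signal approximately proportionally. Detection is
#' therefore a pure multiplicative factor equal to `secondary_scale` for
#' scales in `[0, 1]` (no super-saturation regime is modeled).
#'
#' @param secondary_scale Fraction of the recommended secondary
#'   concentration, in `[0, 1]`. Vectorized.
#' @return Multiplicative detection factor(s), equal to `secondary_scale`.
#' @export
secondary_response <- function(secondary_scale) {
  if (!is.numeric(secondary_scale) || any(is.na(secondary_scale)) ||
      any(secondary_scale < 0) || any(secondary_scale > 1))
    stop("'secondary_scale' must lie in [0, 1]", call. = FALSE)
  secondary_scale
}

# Combined detection factors for the two channels under a config/antibody.
detection_factors <- function(config, antibody) {
  d_tag <- primary_occupancy(config$primary_conc, antibody$K_p) *
    secondary_response(config$secondary_scale)
  d_ref <- primary_occupancy(config$ref_primary_conc, config$ref_K_p)
  list(d_ref = d_ref, d_tag = d_tag)
}

# Pixel mask (linear indices into a height x width matrix) of an elliptical
# annulus centered at (cx, cy) with semi-axes (a, b) and thickness t.
annulus_mask <- function(cx, cy, a, b, t, width, height) {
  x0 <- max(1L, floor(cx - a)); x1 <- min(width,  ceiling(cx + a))
  y0 <- max(1L, floor(cy - b)); y1 <- min(height, ceiling(cy + b))
  xs <- x0:x1; ys <- y0:y1
  dx <- matrix((xs - cx) / a, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  dy <- matrix((ys - cy) / b, nrow = length(ys), ncol = length(xs))
  inside_outer <- dx^2 + dy^2 <= 1
  ai <- a - t; bi <- b - t
  if (ai > 0 && bi > 0) {
    dxi <- matrix((xs - cx) / ai, nrow = length(ys), ncol = length(xs), byrow = TRUE)
    dyi <- matrix((ys - cy) / bi, nrow = length(ys), ncol = length(xs))
    ring <- inside_outer & (dxi^2 + dyi^2 > 1)
  } else {
    ring <- inside_outer
  }
  idx <- which(ring)
  row_in_box <- (idx - 1L) %% length(ys) + 1L
  col_in_box <- (idx - 1L) %/% length(ys) + 1L
  (x0 + col_in_box - 2L) * height + (y0 + row_in_box - 1L)
}

#' Simulate a co-registered two-channel immunofluorescence image pair
#'
#' Places `n_cells` elliptical membrane annuli at rejection-sampled
#' positions (perimeter overlap with previously placed cells is held at or
#' below 20% where possible), draws per-cell log-normal expression, renders
#' both channels as `background + gain * expression * detection` on the
#' membrane pixels, adds mean-proportional Gaussian noise, and rounds and
#' clips to the bit-depth ceiling.
#'
#' @param config A [simulation_config()].
#' @param antibody An [antibody_model()] for the tag channel.
#' @param image_id Character label stored on the returned pair.
#' @return A list with elements `pair` (class `image_pair`: integer matrices
#'   `ref` and `tag`, `bit_depth`, `image_id`) and `truth` (class
#'   `ground_truth`: per-cell table, membrane masks, true `rho`, effective
#'   gains/backgrounds/detection factors, seed) — everything needed to
#'   predict the expected regression slope, see [expected_slope()].
#' @export
simulate_image_pair <- function(config, antibody, image_id = "sim") {
  stopifnot(inherits(config, "sim_config"), inherits(antibody, "antibody_model"))
  if (!is.null(config$seed)) set.seed(config$seed)

  w <- config$width; h <- config$height
  ceiling_val <- 2^config$bit_depth - 1
  rmax <- config$ring_radius_range[2]
  if (2 * rmax + 2 > min(w, h) && config$n_cells > 0L)
    stop("configuration error: a cell of maximum radius ", rmax,
         " cannot fit in a ", w, "x", h, " image", call. = FALSE)

  occupied <- logical(w * h)
  n <- config$n_cells
  cells <- data.frame(cx = numeric(n), cy = numeric(n), a = numeric(n),
                      b = numeric(n), transfected = logical(n),
                      expression = numeric(n), overlapping = logical(n))
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(200L)) {
      a <- stats::runif(1, config$ring_radius_range[1], config$ring_radius_range[2])
      b <- stats::runif(1, config$ring_radius_range[1], config$ring_radius_range[2])
      cx <- stats::runif(1, a + 1, w - a)
      cy <- stats::runif(1, b + 1, h - b)
      m <- annulus_mask(cx, cy, a, b, config$ring_thickness, w, h)
      overlap <- mean(occupied[m])
      if (overlap <= 0.2) { placed <- TRUE; break }
    }
    # after 200 draws accept the last proposal but flag it
    cells$cx[i] <- cx; cells$cy[i] <- cy; cells$a[i] <- a; cells$b[i] <- b
    cells$overlapping[i] <- !placed || overlap > 0
    masks[[i]] <- m
    occupied[m] <- TRUE
  }
  cells$transfected <- stats::runif(n) < config$transfected_fraction
  expr <- stats::rlnorm(n, config$expression_mu, config$expression_sigma)
  cells$expression <- ifelse(cells$transfected, expr, 0)

  d <- detection_factors(config, antibody)
  mu_ref <- matrix(config$background_ref, nrow = h, ncol = w)
  mu_tag <- matrix(config$background_tag, nrow = h, ncol = w)
  for (i in seq_len(n)) {
    if (!cells$transfected[i]) next
    e <- cells$expression[i]
    mu_ref[masks[[i]]] <- mu_ref[masks[[i]]] + config$gain_ref * e * d$d_ref
    mu_tag[masks[[i]]] <- mu_tag[masks[[i]]] + config$gain_tag * antibody$rho * e * d$d_tag
  }

  render <- function(mu) {
    if (config$noise_factor > 0)
      mu <- mu + stats::rnorm(length(mu), sd = sqrt(config$noise_factor * mu))
    m <- matrix(as.integer(pmin(pmax(round(mu), 0), ceiling_val)),
                nrow = nrow(mu), ncol = ncol(mu))
    m
  }
  pair <- structure(
    list(ref = render(mu_ref), tag = render(mu_tag),
         bit_depth = config$bit_depth, image_id = image_id),
    class = "image_pair"
  )
  truth <- structure(
    list(image_id = image_id, cells = cells, masks = masks,
         rho = antibody$rho, antibody_id = antibody$antibody_id,
         gain_ref = config$gain_ref, gain_tag = config$gain_tag,
         background_ref = config$background_ref,
         background_tag = config$background_tag,
         d_ref = d$d_ref, d_tag = d$d_tag,
         noise_factor = config$noise_factor,
         seed = config$seed),
    class = "ground_truth"
  )
  list(pair = pair, truth = truth)
}

#' Expected regression slope implied by the ground truth
#'
#' Closed form for the slope the ROI regression should recover: with both
#' channels affine in per-cell expression over membrane pixels, tag-vs-ref
#' intensity has slope `rho * (gain_tag * d_tag) / (gain_ref * d_ref)`.
#'
#' @param truth A `ground_truth` object from [simulate_image_pair()].
#' @return Expected slope (dimensionless).
#' @export
expected_slope <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  truth$rho * (truth$gain_tag * truth$d_tag) / (truth$gain_ref * truth$d_ref)
}

# Noise-free expected-mean images reconstructed from ground truth; used to
# verify the pixelwise affine relation between channels.
expected_mean_images <- function(truth, width, height) {
  mu_ref <- matrix(truth$background_ref, nrow = height, ncol = width)
  mu_tag <- matrix(truth$background_tag, nrow = height, ncol = width)
  for (i in seq_len(nrow(truth$cells))) {
    if (!truth$cells$transfected[i]) next
    e <- truth$cells$expression[i]
    m <- truth$masks[[i]]
    mu_ref[m] <- mu_ref[m] + truth$gain_ref * e * truth$d_ref
    mu_tag[m] <- mu_tag[m] + truth$gain_tag * truth$rho * e * truth$d_tag
  }
  list(ref = mu_ref, tag = mu_tag)
}

#' Forward model of a primary/secondary dilution series
#'
#' Expected specific signal for every combination of primary-antibody
#' concentration and secondary-antibody dilution:
#' `signal = s_max * theta(conc, K_p) * secondary_scale`. Diluting the
#' secondary scales the signal proportionally (it is the limiting reagent);
#' diluting the primary follows Langmuir occupancy, so a 100-fold dilution
#' from 5000 ng/mL costs far less than 100-fold in signal.
#'
#' @param antibody An [antibody_model()].
#' @param primary_concs Numeric vector of primary concentrations, ng/mL.
#' @param secondary_scales Numeric vector of secondary dilutions in `[0, 1]`.
#' @param config A [simulation_config()]; supplies the plateau `s_max`.
#' @return A data frame with one row per condition: `primary_conc`,
#'   `secondary_scale`, `occupancy`, `secondary_factor`, `signal`.
#' @export
simulate_dilution_series <- function(antibody, primary_concs, secondary_scales,
                                     config = simulation_config()) {
  stopifnot(inherits(antibody, "antibody_model"), inherits(config, "sim_config"))
  if (length(primary_concs) == 0L || length(secondary_scales) == 0L)
    stop("concentration and dilution lists must be non-empty", call. = FALSE)
  grid <- expand.grid(primary_conc = primary_concs,
                      secondary_scale = secondary_scales,
                      KEEP.OUT.ATTRS = FALSE)
  grid$occupancy <- primary_occupancy(grid$primary_conc, antibody$K_p)
  grid$secondary_factor <- secondary_response(grid$secondary_scale)
  grid$signal <- config$s_max * grid$occupancy * grid$secondary_factor
  grid
}
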