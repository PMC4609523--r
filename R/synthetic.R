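#' Simulated observer profile
#'
#' An observer is characterized by how their error grows with cutout
#' difficulty and by how they resolve uncertainty. At difficulty d the
#' observer is "unsure" with probability `d^uncertainty_slope`; when sure
#' they report the true label (with probability `sensitivity`, default
#' 1), when unsure a neutral observer guesses a fair coin while a
#' conservative observer always reports "no CTC" — the
#' false-positive-avoiding bias seen in real annotation panels.
#'
#' @param observer_id Identifier string.
#' @param sensitivity Probability of a correct call when sure (default
#'   1; at difficulty 0 every profile reproduces the truth).
#' @param uncertainty_slope Positive exponent coupling difficulty to the
#'   probability of being unsure.
#' @param conservative Logical; resolve uncertainty to "no CTC"?
#' @return A list of class `observer_profile`.
#' @export
observer_profile <- function(observer_id, sensitivity = 1,
                             uncertainty_slope = 1, conservative = FALSE) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, uncertainty_slope > 0)
  structure(list(observer_id = as.character(observer_id),
                 sensitivity = sensitivity,
                 uncertainty_slope = uncertainty_slope,
                 conservative = isTRUE(conservative)),
            class = "observer_profile")
}

#' Default simulated observer panel
#'
#' Nine neutral plus two conservative profiles, mirroring the structure
#' of the eleven-observer study the generator emulates.
#'
#' @param n_neutral,n_conservative Panel composition.
#' @param uncertainty_slope Shared slope parameter.
#' @return List of [observer_profile()] objects.
#' @export
default_observer_panel <- function(n_neutral = 9, n_conservative = 2,
                                   uncertainty_slope = 1) {
  c(
    lapply(seq_len(n_neutral), function(i)
      observer_profile(sprintf("N%02d", i),
                       uncertainty_slope = uncertainty_slope)),
    lapply(seq_len(n_conservative), function(i)
      observer_profile(sprintf("C%02d", i),
                       uncertainty_slope = uncertainty_slope,
                       conservative = TRUE))
  )
}

#' Two-component difficulty mixture
#'
#' Cutout difficulty is drawn from a mixture of a "clear" Beta component
#' concentrated near 0 and an "ambiguous" Beta component at intermediate
#' difficulty. The disagreement probability across cutouts is therefore
#' not uniform — most cutouts are easy, a minority is genuinely hard —
#' and the ambiguous mass is the main calibration knob.
#'
#' @param ambiguous_mass Mixture weight of the ambiguous component in
#'   \[0, 1\].
#' @param clear_shape,ambiguous_shape Length-2 Beta shape parameters.
#' @return A list of class `difficulty_mixture`.
#' @export
difficulty_mixture <- function(ambiguous_mass = 0.5,
                               clear_shape = c(1, 24),
                               ambiguous_shape = c(4, 3)) {
  stopifnot(ambiguous_mass >= 0, ambiguous_mass <= 1,
            length(clear_shape) == 2, length(ambiguous_shape) == 2)
  structure(list(ambiguous_mass = ambiguous_mass,
                 clear_shape = clear_shape,
                 ambiguous_shape = ambiguous_shape),
            class = "difficulty_mixture")
}

# Draw n difficulties from the mixture (uses the current RNG stream).
sample_difficulties <- function(n, mix) {
  amb <- stats::rbinom(n, 1, mix$ambiguous_mass) == 1
  d <- numeric(n)
  d[!amb] <- stats::rbeta(sum(!amb), mix$clear_shape[1], mix$clear_shape[2])
  d[amb] <- stats::rbeta(sum(amb), mix$ambiguous_shape[1],
                         mix$ambiguous_shape[2])
  d
}

#' Scene specification for one synthetic cutout
#'
#' Decision-relevant appearance follows the annotation rules: a CTC has
#' an intact blue nucleus plus structured green EpCAM/cytokeratin
#' staining and no red CD45 signal; a non-CTC is either red-positive
#' (a leukocyte) or lacks convincing green staining. Difficulty
#' monotonically lowers staining intensity and structure, so hard scenes
#' are faint and ambiguous like real low-intensity cutouts.
#'
#' @param truth_label 1 (CTC) or 0.
#' @param difficulty Real in \[0, 1\]; 0 is unambiguous.
#' @param pixel_area um^2 per pixel, one of 1.0, 0.5, 0.25.
#' @param seed Integer seed; the raster is a deterministic function of
#'   the spec.
#' @param noise_level Amplitude of the uniform background noise.
#' @param background_level Dark background offset (camera black level
#'   plus autofluorescence) added to all channels, with a faint green
#'   tint as in real fluorescence frames; keeps background pixels nearly
#'   stable in hue/saturation rather than chromatically random.
#' @param non_ctc_mode How a non-CTC scene is realized: `"leukocyte"`
#'   (red-positive) or `"weak_green"` (no red, faint unstructured green).
#' @param nucleus_radius_um Nucleus radius in um.
#' @param n_flanking Number of flanking debris objects.
#' @param lean Perceptual lean of the scene in \[0, 1\]: the probability
#'   with which an unsure neutral observer calls the scene a CTC. All
#'   observers view the same stimulus, so this bias is a scene property
#'   shared by the whole panel; 0.5 means no shared lean.
#' @param appearance Rendered CTC evidence in \[0, 1\]: how CTC-like the
#'   staining pattern actually looks (1 = textbook CTC, 0 = clearly
#'   negative). For ambiguous scenes this is deliberately distinct from
#'   both the latent truth and the panel's lean: staining quality and
#'   human judgment each track the truth imperfectly and not through the
#'   same noise. `NULL` (default) uses
#'   `(1 - difficulty) * truth_label + difficulty * 0.5`.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(truth_label, difficulty, pixel_area = 1.0, seed = 1,
                       noise_level = 0.02, background_level = 0.05,
                       non_ctc_mode = c("leukocyte", "weak_green"),
                       nucleus_radius_um = 6, n_flanking = 0, lean = 0.5,
                       appearance = NULL) {
  non_ctc_mode <- match.arg(non_ctc_mode)
  if (is.null(appearance))
    appearance <- (1 - difficulty) * truth_label + difficulty * 0.5
  stopifnot(truth_label %in% c(0, 1), difficulty >= 0, difficulty <= 1,
            pixel_area > 0, noise_level >= 0, background_level >= 0,
            nucleus_radius_um > 0, n_flanking >= 0, lean >= 0, lean <= 1,
            appearance >= 0, appearance <= 1)
  structure(list(truth_label = as.integer(truth_label),
                 difficulty = difficulty, pixel_area = pixel_area,
                 seed = as.integer(seed), noise_level = noise_level,
                 background_level = background_level,
                 non_ctc_mode = non_ctc_mode,
                 nucleus_radius_um = nucleus_radius_um,
                 n_flanking = as.integer(n_flanking), lean = lean,
                 appearance = appearance),
            class = "scene_spec")
}

# Isotropic Gaussian blob on an n x n grid, peak value `intensity`.
gaussian_blob <- function(n, cx, cy, sigma, intensity) {
  xs <- seq_len(n)
  dx2 <- outer((xs - cx)^2, (xs - cy)^2, `+`)
  intensity * exp(-dx2 / (2 * sigma^2))
}

# Patchy texture field in [0,1]: smoothed uniform noise, renormalized.
texture_field <- function(n, grain_sigma = 1.5) {
  raw <- matrix(stats::runif(n * n), n, n)
  k <- gaussian_kernel(grain_sigma)
  sm <- EBImage::filter2(raw, k, boundary = "replicate")
  rng <- range(sm)
  if (diff(rng) < .Machine$double.eps) return(matrix(0.5, n, n))
  (sm - rng[1]) / diff(rng)
}

#' Generate a synthetic cutout image
#'
#' Renders a stylized three-channel raster for a [scene_spec()]: a
#' central Gaussian-profile nucleus (blue), an overlapping green blob
#' whose texture contrast encodes staining structure, an optional red
#' CD45 blob for leukocyte scenes, optional flanking debris, and
#' additive uniform background noise. The raster side is the physical
#' 2500 um^2 crop side plus a 10-pixel margin so [crop_to_region()]
#' always succeeds. Bit-identical under the same spec.
#'
#' @param spec A [scene_spec()].
#' @return A [cutout()].
#' @export
generate_cutout <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  side <- crop_side(2500, spec$pixel_area) + 10L
  ctr <- (side + 1) / 2
  px_per_um <- 1 / sqrt(spec$pixel_area)
  sigma_n <- spec$nucleus_radius_um * px_per_um / 2
  d <- spec$difficulty
  withr::with_seed(spec$seed, {
    blue <- green <- red <- matrix(0, side, side)
    # the rendered staining pattern follows the scene's apparent CTC
    # evidence: clear scenes show their class unambiguously, ambiguous
    # scenes sit between the two class prototypes in color space
    e <- spec$appearance
    # per-scene morphology: cells and staining vary in size, placement
    # and texture grain, as cutouts pooled from many source images do
    sigma_n <- sigma_n * stats::runif(1, 0.85, 1.3)
    g_ratio <- stats::runif(1, 1.3, 2.0)
    grain <- 1.2 * px_per_um * stats::runif(1, 0.7, 1.6)
    # nucleus: always present (cutouts are nucleus-triggered ROIs)
    blue <- gaussian_blob(side, ctr, ctr, sigma_n, 0.9 + 0.05 * e)
    gx <- ctr + stats::rnorm(1, 0, 0.06 * side)
    gy <- ctr + stats::rnorm(1, 0, 0.06 * side)
    # green EpCAM/cytokeratin: intensity and punctate structure track
    # the apparent evidence; e = 0 leaves a faint diffuse haze
    structure_level <- 0.8 * e
    tex <- texture_field(side, grain_sigma = grain)
    mult <- (1 - structure_level) + structure_level * (0.5 + tex)
    green <- clip01(
      gaussian_blob(side, gx, gy, g_ratio * sigma_n, 0.1 + 0.8 * e) * mult)
    if (spec$truth_label == 0L && spec$non_ctc_mode == "leukocyte") {
      # red CD45 counterstain, attenuated when the scene looks CTC-like
      red <- gaussian_blob(side, gx, gy, 1.3 * sigma_n,
                           0.85 * (1 - 0.8 * e))
    }
    # flanking debris: faint blue/green blobs away from the center
    if (spec$n_flanking > 0L) {
      for (k in seq_len(spec$n_flanking)) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(1, 0.3, 0.45) * side
        fx <- ctr + rad * cos(ang)
        fy <- ctr + rad * sin(ang)
        amp <- stats::runif(1, 0.3, 0.8)
        blue <- blue + gaussian_blob(side, fx, fy, 0.6 * sigma_n, amp)
        green <- green + gaussian_blob(side, fx, fy, 0.7 * sigma_n, 0.7 * amp)
      }
    }
    # spectral bleed-through between the dye channels (filter crosstalk),
    # varying from scene to scene with staining and exposure
    ct_rg <- stats::runif(1, 0.05, 0.35)
    ct_gr <- stats::runif(1, 0.05, 0.35)
    ct_gb <- stats::runif(1, 0.05, 0.25)
    red_m <- red + ct_rg * green
    green_m <- green + ct_gr * red + ct_gb * blue
    noise <- function() matrix(stats::runif(side * side, 0, nl_eff),
                               side, side)
    # dark offset with a faint green autofluorescence tint; the whole
    # frame then fades with difficulty. The fade is a pure intensity
    # (V-channel) effect: hue and saturation are invariant to it, so the
    # classifier features deliberately do not see how faint a scene is —
    # the stated reason the V dimension is dropped.
    # illumination and camera state differ between source images
    b0 <- spec$background_level * stats::runif(1, 0.75, 1.4)
    nl_eff <- spec$noise_level * stats::runif(1, 0.7, 1.6)
    fade <- 1 - 0.55 * d
    px <- array(0, dim = c(side, side, 3))
    px[, , 1] <- clip01(fade * (red_m + 1.0 * b0 + noise()))
    px[, , 2] <- clip01(fade * (green_m + 1.4 * b0 + noise()))
    px[, , 3] <- clip01(fade * (blue + 1.1 * b0 + noise()))
    cutout(px, spec$pixel_area,
           sprintf("synth_t%d_d%03d_s%d", spec$truth_label,
                   round(1000 * d), spec$seed))
  })
}

#' Simulate one observer's label for a scene
#'
#' With probability `difficulty^uncertainty_slope` the observer is
#' unsure: a conservative profile then reports 0, a neutral profile
#' votes 1 with probability equal to the scene's shared perceptual
#' `lean` (a fair coin at the default `lean = 0.5`). Otherwise the true
#' label is reported (with probability `sensitivity`).
#'
#' @param profile An [observer_profile()].
#' @param spec A [scene_spec()].
#' @param seed Integer seed.
#' @return Integer label 0/1.
#' @export
simulate_observer <- function(profile, spec, seed) {
  stopifnot(inherits(profile, "observer_profile"),
            inherits(spec, "scene_spec"))
  withr::with_seed(seed, {
    u <- spec$difficulty^profile$uncertainty_slope
    if (stats::runif(1) < u) {
      if (profile$conservative) 0L else stats::rbinom(1, 1, spec$lean)
    } else {
      if (stats::runif(1) < profile$sensitivity) spec$truth_label
      else 1L - spec$truth_label
    }
  })
}

# Per-scene perceptual lean: weakly informative of the truth, so unsure
# neutral votes correlate across the panel (shared stimulus) and lean,
# on average, toward the correct call.
sample_leans <- function(truth) {
  stats::rbeta(length(truth), 0.5 + 0.5 * truth, 0.5 + 0.5 * (1 - truth))
}

# Vectorized panel annotation under the current RNG stream; same
# per-observer model as simulate_observer().
simulate_annotations <- function(truth, difficulty, lean, profiles) {
  n <- length(truth)
  labs <- matrix(0L, n, length(profiles))
  for (j in seq_along(profiles)) {
    pr <- profiles[[j]]
    u <- difficulty^pr$uncertainty_slope
    unsure <- stats::runif(n) < u
    sure_lab <- ifelse(stats::runif(n) < pr$sensitivity, truth, 1L - truth)
    guess <- if (pr$conservative) rep(0L, n) else stats::rbinom(n, 1, lean)
    labs[, j] <- ifelse(unsure, guess, sure_lab)
  }
  colnames(labs) <- vapply(profiles, `[[`, character(1), "observer_id")
  labs
}

# Mean pairwise agreement and consensus fraction of a label matrix,
# computed from per-row vote counts.
panel_statistics <- function(labs, c_limit) {
  M <- ncol(labs)
  v <- rowSums(labs)
  agree_pairs <- choose(v, 2) + choose(M - v, 2)
  list(mean_agreement = mean(agree_pairs) / choose(M, 2),
       consensus_fraction = mean(v >= c_limit | (M - v) >= c_limit))
}

#' Generate a full synthetic panel
#'
#' Draws i.i.d. scenes (latent truth at the given prevalence,
#' difficulties from the mixture), applies every observer profile
#' independently, and optionally renders the cutout images. The latent
#' truth is returned for oracle testing only; no analysis stage uses it.
#'
#' @param n_points Number of cutouts.
#' @param profiles List of [observer_profile()] objects (>= 2).
#' @param difficulty_distribution A [difficulty_mixture()].
#' @param seed Master seed; images get per-scene derived seeds.
#' @param prevalence Probability that a scene truly contains a CTC
#'   (default 0.5).
#' @param pixel_area Either a single pixel area used for all scenes or a
#'   vector to sample from uniformly.
#' @param images Render cutout images? (Annotation-only panels are much
#'   faster and sufficient for agreement statistics.)
#' @param noise_level,n_flanking_mean Scene rendering parameters;
#'   flanking-object counts are Poisson with the given mean.
#' @return A list with `ann` (an [annotation_matrix()]), `truth`,
#'   `difficulty`, `scenes` (list of [scene_spec()]), and `cutouts`
#'   (list of [cutout()] or `NULL`).
#' @export
generate_panel <- function(n_points, profiles,
                           difficulty_distribution = difficulty_mixture(),
                           seed = 1, prevalence = 0.5, pixel_area = 1.0,
                           images = TRUE, noise_level = 0.02,
                           n_flanking_mean = 1.0) {
  stopifnot(n_points >= 1, length(profiles) >= 2,
            inherits(difficulty_distribution, "difficulty_mixture"))
  sim <- withr::with_seed(seed, {
    truth <- stats::rbinom(n_points, 1, prevalence)
    difficulty <- sample_difficulties(n_points, difficulty_distribution)
    lean <- sample_leans(truth)
    labs <- simulate_annotations(truth, difficulty, lean, profiles)
    # staining quality jitter, drawn independently of the lean: what a
    # scene shows and what the panel reads into it track the truth
    # through different noise. Appearance degrades faster than the
    # panel's uncertainty — observers also exploit intensity and context
    # cues that the hue/saturation representation discards, so there are
    # unanimously annotated cutouts whose color pattern is borderline.
    jitter <- stats::rbeta(n_points, 1 + truth, 2 - truth)
    appearance <- (1 - difficulty) * truth + difficulty * jitter
    mode <- ifelse(stats::runif(n_points) < 0.6, "leukocyte", "weak_green")
    pa <- if (length(pixel_area) == 1L) rep(pixel_area, n_points)
          else sample(pixel_area, n_points, replace = TRUE)
    nf <- stats::rpois(n_points, n_flanking_mean)
    list(truth = truth, difficulty = difficulty, lean = lean,
         appearance = appearance, labs = labs, mode = mode, pa = pa, nf = nf)
  })
  scenes <- lapply(seq_len(n_points), function(i)
    scene_spec(sim$truth[i], sim$difficulty[i], pixel_area = sim$pa[i],
               seed = derive_seed(seed, 7000, i),
               noise_level = noise_level, non_ctc_mode = sim$mode[i],
               n_flanking = sim$nf[i], lean = sim$lean[i],
               appearance = sim$appearance[i]))
  cutouts <- if (images) lapply(scenes, generate_cutout) else NULL
  ann <- annotation_matrix(sim$labs,
                           cutout_ids = sprintf("cutout_%04d",
                                                seq_len(n_points)))
  list(ann = ann, truth = sim$truth, difficulty = sim$difficulty,
       scenes = scenes, cutouts = cutouts)
}

#' Calibrate the difficulty mixture to target agreement statistics
#'
#' Searches the generator's ambiguous-mass fraction (and, over a small
#' grid, the uncertainty slope) so that simulated panels reproduce the
#' target mean pairwise agreement and consensus fraction. Mean agreement
#' is monotonically decreasing in the ambiguous mass, so a coarse
#' bracketing grid followed by bisection on the ambiguous mass pins it
#' down; the slope grid then selects the member of the family whose
#' consensus fraction comes closest.
#'
#' @param target_agreement Target mean pairwise agreement in (0, 1).
#' @param target_consensus_fraction Target fraction of cutouts reaching
#'   the [consensus_limit()] threshold, in (0, 1).
#' @param profiles Observer panel (slope is overridden by the grid).
#' @param tolerance Named vector with elements `agreement` and
#'   `consensus`.
#' @param n_points,n_replicates Simulated panel size and number of
#'   replicate panels averaged per evaluation.
#' @param seed Master seed for the calibration simulations.
#' @param slope_grid Candidate uncertainty slopes.
#' @param alpha Consensus significance level.
#' @return A list with `mixture` (calibrated [difficulty_mixture()]),
#'   `profiles` (slope-adjusted), `uncertainty_slope`,
#'   `achieved_agreement`, `achieved_consensus_fraction`, and the
#'   targets. Errors with condition class `calibration_failure`
#'   (carrying the best parameters found in field `best`) if no grid
#'   member meets both tolerances.
#' @export
calibrate_difficulty <- function(target_agreement = 0.85,
                                 target_consensus_fraction = 0.81,
                                 profiles = default_observer_panel(),
                                 tolerance = c(agreement = 0.02,
                                               consensus = 0.03),
                                 n_points = 617, n_replicates = 3,
                                 seed = 1, slope_grid = c(0.7, 1, 1.5),
                                 alpha = 0.05) {
  stopifnot(target_agreement > 0, target_agreement <= 1,
            target_consensus_fraction > 0, target_consensus_fraction <= 1)
  M <- length(profiles)
  c_limit <- consensus_limit(M, alpha)
  if (is.na(c_limit))
    stop("no consensus limit exists for this panel size", call. = FALSE)

  set_slope <- function(slope) lapply(profiles, function(p) {
    p$uncertainty_slope <- slope
    p
  })
  eval_point <- function(w, prof, k) {
    stats_r <- vapply(seq_len(n_replicates), function(r) {
      labs <- withr::with_seed(derive_seed(seed, k, r), {
        truth <- stats::rbinom(n_points, 1, 0.5)
        diff <- sample_difficulties(n_points, difficulty_mixture(w))
        simulate_annotations(truth, diff, sample_leans(truth), prof)
      })
      s <- panel_statistics(labs, c_limit)
      c(s$mean_agreement, s$consensus_fraction)
    }, numeric(2))
    rowMeans(stats_r)
  }

  best <- NULL
  eval_counter <- 0L
  for (slope in slope_grid) {
    prof <- set_slope(slope)
    # coarse grid to bracket the agreement target
    grid_w <- seq(0, 1, by = 0.2)
    grid_a <- vapply(grid_w, function(w) {
      eval_counter <<- eval_counter + 1L
      eval_point(w, prof, eval_counter)[1]
    }, numeric(1))
    if (all(grid_a < target_agreement)) {
      w_hat <- 0
    } else if (all(grid_a > target_agreement)) {
      w_hat <- 1
    } else {
      hi_i <- max(which(grid_a >= target_agreement))  # agreement decreasing in w
      lo <- grid_w[hi_i]
      hi <- grid_w[min(hi_i + 1L, length(grid_w))]
      for (it in 1:12) {
        mid <- (lo + hi) / 2
        eval_counter <- eval_counter + 1L
        a_mid <- eval_point(mid, prof, eval_counter)[1]
        if (a_mid >= target_agreement) lo <- mid else hi <- mid
      }
      w_hat <- (lo + hi) / 2
    }
    eval_counter <- eval_counter + 1L
    achieved <- eval_point(w_hat, prof, eval_counter)
    cand <- list(mixture = difficulty_mixture(w_hat),
                 profiles = prof, uncertainty_slope = slope,
                 achieved_agreement = achieved[1],
                 achieved_consensus_fraction = achieved[2],
                 target_agreement = target_agreement,
                 target_consensus_fraction = target_consensus_fraction)
    score <- abs(achieved[1] - target_agreement) / tolerance[["agreement"]] +
      abs(achieved[2] - target_consensus_fraction) / tolerance[["consensus"]]
    if (is.null(best) || score < best$score) {
      best <- cand
      best$score <- score
    }
  }
  ok <- abs(best$achieved_agreement - target_agreement) <=
          tolerance[["agreement"]] &&
        abs(best$achieved_consensus_fraction - target_consensus_fraction) <=
          tolerance[["consensus"]]
  if (!ok) {
    cond <- structure(
      list(message = sprintf(
        "calibration failed: best achieved agreement %.3f / consensus %.3f for targets %.3f / %.3f",
        best$achieved_agreement, best$achieved_consensus_fraction,
        target_agreement, target_consensus_fraction),
        call = NULL, best = best),
      class = c("calibration_failure", "error", "condition"))
    stop(cond)
  }
  best$score <- NULL
  best
}
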