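## Synthetic heme-O2 conformations and multi-spin ground-truth charges.
## The generator stands in for the (non-deposited) trajectory dataset: it
## samples the O2 binding coordinate widely and attaches smooth, spin-
## dependent charges so the full featurize -> train -> predict pipeline can
## be exercised end to end.

HEME_LABELS <- c("Fe", "N1", "N2", "N3", "N4", "C5", "C6", "C7", "C8", "C9",
                 "C10", "N11", "O12", "O13")
HEME_ELEMENTS <- c("Fe", rep("N", 4L), rep("C", 6L), "N", "O", "O")

#' Heavy-atom label table of the heme-O2 model
#'
#' Fixed mapping between the chemical labels (Fe, N1..N4, C5..C10, N11, O12,
#' O13) and the 0-based atom indices used in charge tables. Atom positions in
#' generated structures are `atom_index + 1`.
#'
#' @return Data frame with columns `atom_index`, `label`, `element`.
#' @export
heme_atom_table <- function() {
  data.frame(atom_index = seq_along(HEME_LABELS) - 1L,
             label = HEME_LABELS, element = HEME_ELEMENTS)
}

#' Idealized template geometry of the heme-O2 model
#'
#' Fe at the origin; four pyrrole-like nitrogens N1-N4 in a square plane at
#' 2.0 Angstrom; two planar C3N2 chelate rings (N1-C10-C6-C5-N2 and
#' N3-C7-C8-C9-N4); an axial ammonia nitrogen N11 at 2.1 Angstrom below the
#' plane; O12 axially above Fe with O13 at 1.25 Angstrom from O12. The 14
#' heavy atoms come first in [heme_atom_table()] order, followed by 9
#' hydrogens (one per ring carbon, three on the ammonia).
#'
#' @param d_feo Fe-O12 distance (Angstrom, default 2.0).
#' @param feoo_angle Fe-O12-O13 angle (degrees, default 120).
#' @return A [structure3d()] with 23 atoms and an `atom_labels` attribute.
#' @export
heme_template <- function(d_feo = 2.0, feoo_angle = 120) {
  heavy <- rbind(
    Fe  = c(0.0,  0.0,  0.0),
    N1  = c(2.0,  0.0,  0.0),
    N2  = c(0.0,  2.0,  0.0),
    N3  = c(-2.0, 0.0,  0.0),
    N4  = c(0.0, -2.0,  0.0),
    C5  = c(1.1,  2.8,  0.0),
    C6  = c(2.3,  2.3,  0.0),
    C7  = c(-2.8, -1.1, 0.0),
    C8  = c(-2.3, -2.3, 0.0),
    C9  = c(-1.1, -2.8, 0.0),
    C10 = c(2.8,  1.1,  0.0),
    N11 = c(0.0,  0.0, -2.1),
    O12 = c(0.0,  0.0,  d_feo),
    O13 = c(0.0,  0.0,  d_feo) + o13_offset(feoo_angle)
  )
  ## ring hydrogens point radially outward from Fe, 1.08 A from their carbon
  ring_c <- heavy[c("C5", "C6", "C7", "C8", "C9", "C10"), ]
  hring <- ring_c + 1.08 * ring_c / sqrt(rowSums(ring_c^2))
  ## ammonia hydrogens below N11
  phi <- c(0, 2, 4) * pi / 3
  hnh3 <- cbind(0.96 * cos(phi), 0.96 * sin(phi), rep(-0.34, 3L))
  hnh3 <- sweep(1.02 * hnh3 / sqrt(rowSums(hnh3^2)), 2L,
                heavy["N11", ], "+")
  coords <- rbind(heavy, hring, hnh3)
  s <- structure3d(c(HEME_ELEMENTS, rep("H", 9L)), coords, frame_id = 0L)
  attr(s, "atom_labels") <- c(HEME_LABELS, paste0("H", 15:23))
  s
}

## Unit placement of O13 relative to O12 so the Fe-O12-O13 angle is `theta`:
## Fe sits along -z from O12, so the O12->O13 direction (sin t, 0, -cos t)
## has cos(angle) = cos(theta).
o13_offset <- function(theta_deg, bond = 1.25) {
  t <- theta_deg * pi / 180
  bond * c(sin(t), 0, -cos(t))
}

#' Generator parameters for synthetic conformations
#'
#' Each frame draws the Fe-O12 distance and the Fe-O12-O13 angle uniformly
#' from their ranges, places O2 accordingly on the template, then jitters
#' every Cartesian coordinate with independent Gaussian noise.
#'
#' @param n_frames Number of frames (>= 1).
#' @param seed Master seed for the generator.
#' @param feo_range Fe-O12 distance range (Angstrom), default `c(1.8, 4.0)` --
#'   spans bound to essentially dissociated O2.
#' @param feoo_angle_range Fe-O12-O13 angle range (degrees), default
#'   `c(100, 180)` (bent end-on binding through linear).
#' @param geom_jitter_sigma Per-coordinate Gaussian jitter (Angstrom),
#'   default 0.05 -- thermal-scale distortion of the whole scaffold.
#' @param charge_noise_sigma Per-charge Gaussian noise (e), default 0.01.
#' @param total_charge Total charge of the 14 heavy atoms (e), default 0.
#' @return A validated `cac_generator_params` list.
#' @export
generator_params <- function(n_frames = 1000L, seed = 1L,
                             feo_range = c(1.8, 4.0),
                             feoo_angle_range = c(100, 180),
                             geom_jitter_sigma = 0.05,
                             charge_noise_sigma = 0.01,
                             total_charge = 0) {
  if (!is.numeric(n_frames) || n_frames < 1L) cac_config_error("n_frames must be >= 1")
  chk_range <- function(r, nm) {
    if (length(r) != 2L || !all(is.finite(r)) || r[2L] <= r[1L]) {
      cac_config_error(paste0(nm, " must be a non-degenerate (lo, hi) range"))
    }
  }
  chk_range(feo_range, "feo_range")
  chk_range(feoo_angle_range, "feoo_angle_range")
  if (geom_jitter_sigma < 0 || charge_noise_sigma < 0) {
    cac_config_error("jitter/noise sigmas must be >= 0")
  }
  structure(list(n_frames = as.integer(n_frames), seed = as.integer(seed),
                 feo_range = as.double(feo_range),
                 feoo_angle_range = as.double(feoo_angle_range),
                 geom_jitter_sigma = as.double(geom_jitter_sigma),
                 charge_noise_sigma = as.double(charge_noise_sigma),
                 total_charge = as.double(total_charge)),
            class = "cac_generator_params")
}

#' Ground-truth charge model of the synthetic generator
#'
#' Per-atom, per-spin baseline charges `mu` plus geometry couplings: `alpha`
#' multiplies a centered sigmoid `g - 1/2` of the Fe-O12 distance (`g`
#' normalized to `[0, 1]` over the default 1.8-4.0 Angstrom range, center
#' 2.9 Angstrom, scale 0.35 Angstrom) and `beta` multiplies the centered
#' `cos` of the Fe-O12-O13 angle. Because both geometry terms have mean
#' approximately zero under the default sampler, `mu` is the center of each
#' atom's charge distribution. Defaults encode the spin structure of the
#' heme system: Fe charges centered at 1.2 e (singlet), 1.3 e (triplet),
#' 1.5 e (quintuplet) with an overall singlet range of roughly 0.2-2.1 e;
#' per-atom spreads of 0.5-0.7 e for the non-iron atoms and about 1.9 e for
#' Fe; and column sums of zero for every table so the total-charge
#' constraint never shifts the spin offsets.
#'
#' @return A `cac_charge_params` list with 14 x 3 matrices `mu`, `alpha`,
#'   `beta` (rows in [heme_atom_table()] order, columns singlet / triplet /
#'   quintuplet) and the sigmoid constants `g_center`, `g_scale`, `g_range`.
#' @export
true_charge_params <- function() {
  spins <- names(CAC_SPINS)
  mu <- cbind(
    singlet    = c(1.2, -0.390, -0.387, -0.457, -0.451, 0.350, -0.369, 0.363,
                   0.371, -0.372, 0.348, 0.052, -0.217, -0.229),
    triplet    = c(1.3, -0.382, -0.378, -0.449, -0.443, 0.357, -0.371, 0.368,
                   0.375, -0.373, 0.354, 0.051, -0.266, -0.224),
    quintuplet = c(1.5, -0.390, -0.385, -0.458, -0.452, 0.374, -0.377, 0.384,
                   0.390, -0.378, 0.370, 0.007, -0.306, -0.238)
  )
  ## re-center the 13 non-Fe baselines so each spin column sums to zero
  ## (keeps sum-to-total_charge enforcement from touching the Fe offsets)
  mu[-1L, ] <- sweep(mu[-1L, ], 2L, colSums(mu) / 13, "-")

  ## binding-distance coupling alpha: carried by every atom (zero column sum);
  ## orientation coupling beta: concentrated on the axial site (Fe, N11, O12,
  ## O13) -- remote ring atoms barely sense how O2 is tilted, so their charge
  ## response is dominated by the Fe-O binding distance
  alpha0 <- c(1.50, -0.55, -0.55, 0.53, 0.53, -0.55, 0.50, -0.55, 0.50,
              -0.55, 0.50, -0.45, -0.40, -0.46)
  ## small zero-sum spin perturbation on the ring atoms so the geometry
  ## coupling itself is spin dependent (not just the baseline)
  dalpha <- c(0, 0.02, -0.02, 0.02, -0.02, -0.02, 0.02, -0.02, 0.02,
              -0.02, 0.02, 0, 0, 0)
  alpha <- cbind(singlet = alpha0 - dalpha, triplet = alpha0,
                 quintuplet = alpha0 + dalpha)
  beta0 <- c(-0.45, 0.02, -0.02, 0.02, -0.02, 0.02, -0.02, 0.02, -0.02,
             0.02, -0.02, 0.20, 0.35, -0.10)
  beta <- cbind(singlet = beta0, triplet = beta0, quintuplet = beta0)
  rownames(mu) <- rownames(alpha) <- rownames(beta) <- HEME_LABELS
  colnames(mu) <- colnames(alpha) <- colnames(beta) <- spins
  ## geometry terms are centered (g - 1/2, cos theta - mean cos) so mu is the
  ## center of each atom's charge distribution under the default sampler;
  ## cos_center is E[cos theta] for theta ~ U(100 deg, 180 deg)
  structure(list(mu = mu, alpha = alpha, beta = beta,
                 g_center = 2.9, g_scale = 0.35, g_range = c(1.8, 4.0),
                 cos_center = (sin(pi) - sin(100 * pi / 180)) / (80 * pi / 180)),
            class = "cac_charge_params")
}

## bounded sigmoid of the Fe-O distance, normalized to [0,1] over g_range
charge_sigmoid <- function(d, params) {
  raw <- function(x) 1 / (1 + exp(-(x - params$g_center) / params$g_scale))
  lo <- raw(params$g_range[1L]); hi <- raw(params$g_range[2L])
  (raw(d) - lo) / (hi - lo)
}

#' Sample synthetic heme-O2 conformations
#'
#' Deterministic given `params$seed`; frames are labelled 0 to n-1. The
#' pre-jitter draws of the binding coordinate are attached as attribute
#' `draws` (a data frame with `frame`, `d_feo`, `feoo_angle`).
#'
#' @param params A [generator_params()].
#' @return List of [structure3d()] frames (23 atoms each).
#' @export
sample_conformations <- function(params) {
  with_seed(params$seed, sample_conformations_impl(params))
}

sample_conformations_impl <- function(params) {
  template <- heme_template()
  n_at <- n_atoms(template)
  d <- runif(params$n_frames, params$feo_range[1L], params$feo_range[2L])
  th <- runif(params$n_frames, params$feoo_angle_range[1L], params$feoo_angle_range[2L])
  frames <- vector("list", params$n_frames)
  for (f in seq_len(params$n_frames)) {
    base <- template$coords
    base[13L, ] <- c(0, 0, d[f])
    base[14L, ] <- base[13L, ] + o13_offset(th[f])
    for (try in seq_len(20L)) {
      jit <- matrix(rnorm(n_at * 3L, 0, params$geom_jitter_sigma), n_at, 3L)
      coords <- base + jit
      if (min(stats::dist(coords)) > 1e-6) break
      if (try == 20L) cac_geometry_error("jitter kept producing coincident atoms")
    }
    s <- structure3d(template$elements, coords, frame_id = f - 1L)
    attr(s, "atom_labels") <- attr(template, "atom_labels")
    frames[[f]] <- s
  }
  attr(frames, "draws") <- data.frame(frame = seq_len(params$n_frames) - 1L,
                                      d_feo = d, feoo_angle = th)
  frames
}

#' Ground-truth charges for one conformation and spin state
#'
#' `q_a = mu[a, s] + alpha[a, s] * g(d_FeO12) + beta[a, s] * cos(theta)` plus
#' optional Gaussian noise, where `d_FeO12` and the Fe-O12-O13 angle `theta`
#' are measured on the structure as given (jitter included). After the noise
#' draw the 14 charges are shifted uniformly so they sum to `total_charge`
#' exactly. Uses the session RNG; seed with `set.seed()` (or go through
#' [generate_dataset()], which seeds everything).
#'
#' @param structure A structure whose first 14 atoms are the labelled heavy
#'   atoms of [heme_atom_table()].
#' @param spin `"singlet"`, `"triplet"` or `"quintuplet"`.
#' @param charge_params A [true_charge_params()].
#' @param noise_sigma Per-charge Gaussian noise (e).
#' @param total_charge Enforced sum of the 14 charges (e).
#' @return Named numeric vector of 14 charges (e).
#' @export
true_charges <- function(structure, spin, charge_params = true_charge_params(),
                         noise_sigma = 0, total_charge = 0) {
  spin <- match.arg(spin, names(CAC_SPINS))
  if (n_atoms(structure) < 14L ||
      !identical(structure$elements[1:14], HEME_ELEMENTS)) {
    cac_data_error("structure does not carry the 14 labelled heavy atoms in table order")
  }
  X <- structure$coords
  d <- coord_distance(X[1L, ], X[13L, ])
  theta <- coord_angle(X[1L, ], X[13L, ], X[14L, ])
  g <- charge_sigmoid(d, charge_params)
  q <- charge_params$mu[, spin] +
    charge_params$alpha[, spin] * (g - 0.5) +
    charge_params$beta[, spin] * (cos(theta * pi / 180) - charge_params$cos_center)
  if (noise_sigma > 0) q <- q + rnorm(14L, 0, noise_sigma)
  q <- q + (total_charge - sum(q)) / 14
  stats::setNames(q, HEME_LABELS)
}

#' Generate an aligned synthetic dataset of frames and 3-spin charges
#'
#' Runs [sample_conformations()] and [true_charges()] under a single seeded
#' RNG stream: the same `params` always reproduce the same dataset.
#'
#' @param params A [generator_params()].
#' @param charge_params A [true_charge_params()].
#' @return List with `structures` (list of frames) and `charges` (a charge
#'   table data frame as in [read_charge_table()]).
#' @export
generate_dataset <- function(params, charge_params = true_charge_params()) {
  with_seed(params$seed, {
    structures <- sample_conformations_impl(params)
    tabs <- lapply(structures, function(s) {
      qs <- vapply(names(CAC_SPINS), function(sp)
        true_charges(s, sp, charge_params,
                     noise_sigma = params$charge_noise_sigma,
                     total_charge = params$total_charge),
        numeric(14L))
      data.frame(frame = s$frame_id, atom_index = 0:13, element = HEME_ELEMENTS,
                 q_singlet = qs[, "singlet"], q_triplet = qs[, "triplet"],
                 q_quintuplet = qs[, "quintuplet"], row.names = NULL)
    })
    list(structures = structures, charges = do.call(rbind, tabs))
  })
}
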