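# Multi-center synthetic cohort generator.
#
# The generative model is this module's own (no public data accompany the
# analysis): a logistic streamline-budget model with planted inter/intra
# coupling, per-center batch effects and disease effects. See the methods
# vignette for the full account.

# Per-center demographic parameters loosely matching the 7-center cohort the
# generator emulates (sample sizes, age, sex, disease duration).
center_params <- function() {
  data.frame(
    center = c("Amsterdam", "Barcelona", "London", "Mainz", "Milan",
               "Naples", "Oslo"),
    n_hc = c(48, 8, 19, 26, 30, 53, 24),
    n_ms = c(173, 58, 43, 50, 56, 51, 58),
    age_hc_mean = c(48.41, 29.94, 33.19, 27.85, 37.26, 41.30, 35.12),
    age_hc_sd = c(9.3, 10.6, 7.0, 6.4, 9.3, 11.6, 8.7),
    age_ms_mean = c(48.80, 48.81, 34.43, 35.78, 42.18, 42.48, 40.59),
    age_ms_sd = c(11.3, 9.6, 7.9, 11.6, 9.7, 12.9, 7.2),
    female_hc = c(0.5833, 0.8750, 0.6316, 0.5000, 0.4000, 0.6226, 0.6250),
    female_ms = c(0.7168, 0.7241, 0.6279, 0.6400, 0.5536, 0.6667, 0.7069),
    dd_mean = c(15.26, 19.54, 0.41, 4.99, 10.81, 13.29, 10.09),
    dd_sd = c(8.7, 9.4, 0.5, 6.6, 9.8, 9.0, 5.3),
    stringsAsFactors = FALSE)
}

# Internal generator constants (not config knobs; see vignette):
# baseline interhemispheric share, loading of the conservation latent on the
# logit share, and the effect of the latent intra-strength factor on the
# subject fiber-length scale.
.gen <- list(mu0 = stats::qlogis(0.15), load_u = 0.3, len_effect = 0.15,
             intra_density = 0.35, inter_extra_frac = 0.10,
             intra_meanlog = log(60), intra_sdlog = 0.35,
             inter_meanlog = log(105), inter_sdlog = 0.25)

#' Parcellation label table
#'
#' Region labels with hemisphere tags and cortical flags. At the default
#' sizes (30 cortical regions per hemisphere, 16 subcortical) the labels are
#' a Desikan-Killiany-style list: paired cortical regions, seven paired
#' subcortical structures, the brainstem and the corpus callosum (the two
#' midline regions). Other sizes get generic labels with the same structure:
#' two midline regions (three if the subcortical count is odd), the rest
#' paired.
#'
#' @param n_cortical_per_hemi cortical regions per hemisphere.
#' @param n_subcortical subcortical regions in total.
#' @return `data.frame` with columns `label`, `hemisphere`, `cortical`.
#' @export
parcellation_labels <- function(n_cortical_per_hemi = 30, n_subcortical = 16) {
  dk <- c("superiorfrontal", "rostralmiddlefrontal", "caudalmiddlefrontal",
          "parsopercularis", "parstriangularis", "parsorbitalis",
          "lateralorbitofrontal", "medialorbitofrontal", "precentral",
          "paracentral", "postcentral", "supramarginal", "superiorparietal",
          "inferiorparietal", "precuneus", "cuneus", "pericalcarine",
          "lateraloccipital", "lingual", "fusiform", "parahippocampal",
          "superiortemporal", "middletemporal", "inferiortemporal",
          "transversetemporal", "insula", "caudalanteriorcingulate",
          "rostralanteriorcingulate", "posteriorcingulate", "isthmuscingulate")
  sub_pairs <- c("thalamus", "caudate", "putamen", "pallidum", "hippocampus",
                 "amygdala", "accumbens")
  cort_names <- if (n_cortical_per_hemi <= length(dk)) {
    dk[seq_len(n_cortical_per_hemi)]
  } else {
    c(dk, paste0("extra-cortical-", seq_len(n_cortical_per_hemi - length(dk))))
  }
  out <- data.frame(
    label = c(paste0("ctx-lh-", cort_names), paste0("ctx-rh-", cort_names)),
    hemisphere = rep(c("L", "R"), each = n_cortical_per_hemi),
    cortical = TRUE, stringsAsFactors = FALSE)
  if (n_subcortical > 0) {
    n_mid <- min(n_subcortical, 2L + n_subcortical %% 2L)
    n_pair <- (n_subcortical - n_mid) / 2
    pair_names <- if (n_pair <= length(sub_pairs)) {
      sub_pairs[seq_len(n_pair)]
    } else {
      c(sub_pairs, paste0("extra-sub-", seq_len(n_pair - length(sub_pairs))))
    }
    mid_names <- c("brainstem", "corpuscallosum",
                   "midline-3")[seq_len(n_mid)]
    out <- rbind(out, data.frame(
      label = c(paste0("left-", pair_names), paste0("right-", pair_names),
                mid_names),
      hemisphere = c(rep(c("L", "R"), each = n_pair), rep("M", n_mid)),
      cortical = FALSE, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Cohort generator configuration
#'
#' Defaults emulate the 7-center cohort the analysis targets: 697 subjects
#' (489 with MS), per-center sample sizes and demographics following the
#' cohort table, a planted inter/intra coupling of -0.4, a moderate disease
#' effect lowering the interhemispheric share in MS, and per-center batch
#' effects on weights and volumetric scalars. `total_streamlines` defaults to
#' a desk-scale 10,000 (the emulated tractograms use 6,000,000); the
#' commissural ratio and all planted correlations are invariant to it.
#'
#' @param n_subjects cohort size.
#' @param ms_fraction fraction of subjects with MS, in (0, 1).
#' @param n_centers number of acquisition centers.
#' @param n_cortical_per_hemi,n_subcortical parcellation sizes.
#' @param total_streamlines streamline-weight budget per subject.
#' @param conservation_coupling planted correlation in \[-1, 1\] between the
#'   interhemispheric share and the latent intrahemispheric strength.
#' @param disease_effect_inter standardized effect of MS severity on the
#'   logit interhemispheric share.
#' @param site_shift_sd,site_scale_sd per-center additive-shift and
#'   log-multiplicative-scale batch magnitudes (scale sd >= 0).
#' @param noise_sd residual sd on the logit interhemispheric share.
#' @param seed integer RNG seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 697, ms_fraction = 489 / 697,
                          n_centers = 7, n_cortical_per_hemi = 30,
                          n_subcortical = 16, total_streamlines = 10000,
                          conservation_coupling = -0.4,
                          disease_effect_inter = 0.5,
                          site_shift_sd = 0.2, site_scale_sd = 0.1,
                          noise_sd = 0.25, seed = 1) {
  cfg <- list(n_subjects = n_subjects, ms_fraction = ms_fraction,
              n_centers = n_centers,
              n_cortical_per_hemi = n_cortical_per_hemi,
              n_subcortical = n_subcortical,
              total_streamlines = total_streamlines,
              conservation_coupling = conservation_coupling,
              disease_effect_inter = disease_effect_inter,
              site_shift_sd = site_shift_sd, site_scale_sd = site_scale_sd,
              noise_sd = noise_sd, seed = as.integer(seed))
  num <- unlist(cfg[setdiff(names(cfg), "seed")])
  if (any(!is.finite(num))) stop("non-finite config value", call. = FALSE)
  counts <- c("n_subjects", "n_centers", "n_cortical_per_hemi",
              "total_streamlines")
  if (any(unlist(cfg[counts]) < 1)) stop("counts must be positive", call. = FALSE)
  if (cfg$n_subcortical < 0) stop("n_subcortical must be >= 0", call. = FALSE)
  if (cfg$ms_fraction <= 0 || cfg$ms_fraction >= 1)
    stop("ms_fraction must be in (0, 1)", call. = FALSE)
  if (abs(cfg$conservation_coupling) > 1)
    stop("conservation_coupling must be in [-1, 1]", call. = FALSE)
  if (cfg$site_scale_sd < 0 || cfg$site_shift_sd < 0 || cfg$noise_sd < 0)
    stop("sd parameters must be >= 0", call. = FALSE)
  if (cfg$ms_fraction * cfg$n_subjects < 1)
    stop("ms_fraction * n_subjects < 1: no MS subject would be generated",
         call. = FALSE)
  class(cfg) <- "cohort_config"
  cfg
}

# Deterministic per-subject substream seed (kept < 2^31).
subject_seed <- function(seed, i, stage = 0L) {
  ((abs(as.numeric(seed)) %% 97777) * 10007 + i * 101 + stage * 17) %%
    2147483629
}

rtruncnorm1 <- function(n, lo, hi) {
  stats::qnorm(stats::runif(n, stats::pnorm(lo), stats::pnorm(hi)))
}

round_half <- function(x) round(x * 2) / 2

# Random connected support (spanning tree + extra random pairs) over nodes
# `idx`; returns a 2-column matrix of index pairs.
random_connected_support <- function(idx, density) {
  n <- length(idx)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  ord <- sample(idx)
  tree <- cbind(ord[-1], vapply(2:n, function(k) ord[sample.int(k - 1, 1)],
                                integer(1)))
  all_pairs <- t(utils::combn(sort(idx), 2))
  key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  remaining <- all_pairs[!(key(all_pairs) %in% key(tree)), , drop = FALSE]
  n_extra <- max(0L, round(density * nrow(all_pairs)) - nrow(tree))
  if (n_extra > 0 && nrow(remaining) > 0) {
    extra <- remaining[sample.int(nrow(remaining), min(n_extra,
                                                       nrow(remaining))), ,
                       drop = FALSE]
    tree <- rbind(tree, extra)
  }
  tree
}

#' Generate a synthetic multi-center cohort
#'
#' Draws, per subject, a latent conservation factor and (for MS) a latent
#' severity; forms the interhemispheric streamline share on the logit scale
#' (baseline + conservation loading - disease effect + center shift + noise);
#' allocates the streamline budget over random connected intrahemispheric
#' supports and an interhemispheric support that always includes homotopic
#' cortical pairs; draws lognormal fiber lengths (interhemispheric fibers
#' longer on average) scaled by a subject-level length factor that plants the
#' configured inter/intra coupling; and generates demographics, clinical
#' scores and volumetric scalars with per-center batch effects.
#'
#' Midline regions (brainstem, corpus callosum label) carry no streamline
#' weight, keeping the budget allocation exact over L/R regions.
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_cohort` with elements `connectomes`
#'   (named list of [connectome()]), `records` (subject table), and
#'   `ground_truth` (planted per-subject latents and per-center batch
#'   parameters).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  regions <- parcellation_labels(config$n_cortical_per_hemi,
                                 config$n_subcortical)
  cp <- center_params()
  k <- config$n_centers
  cp <- cp[((seq_len(k) - 1) %% nrow(cp)) + 1, ]
  cp$center <- if (k <= 7) cp$center else paste0(cp$center, "-", seq_len(k))

  # centers and diagnosis: center shares follow the emulated cohort table,
  # per-center MS fractions rescaled to the configured global fraction
  share <- (cp$n_hc + cp$n_ms) / sum(cp$n_hc + cp$n_ms)
  p_ms_center <- pmin(0.98, pmax(0.02, (cp$n_ms / (cp$n_hc + cp$n_ms)) *
                                   config$ms_fraction / (sum(cp$n_ms) /
                                                         sum(cp$n_hc + cp$n_ms))))
  # deterministic largest-remainder allocation so every center is filled in
  # proportion even at small n, then a random subject-to-center shuffle
  counts <- floor(share * n)
  frac_rank <- order(share * n - counts, decreasing = TRUE)
  counts[frac_rank[seq_len(n - sum(counts))]] <-
    counts[frac_rank[seq_len(n - sum(counts))]] + 1
  center_idx <- sample(rep.int(seq_len(k), counts))
  is_ms <- stats::runif(n) < p_ms_center[center_idx]
  if (!any(is_ms)) is_ms[sample.int(n, 1)] <- TRUE
  if (!any(!is_ms)) is_ms[sample.int(n, 1)] <- FALSE

  # per-center batch effects
  center_shift <- stats::rnorm(k, 0, config$site_shift_sd)
  center_scale <- exp(stats::rnorm(k, 0, config$site_scale_sd))

  # latents and logit interhemispheric share; severity is a positive
  # truncated normal (mean ~1.3) so MS lowers the interhemispheric share on
  # average, with a gradient over severity. The disease shift is expressed
  # in units of the healthy biological spread of the logit share.
  u <- stats::rnorm(n)
  s <- ifelse(is_ms, 1 + rtruncnorm1(n, -1, 2.5), 0)
  eps <- stats::rnorm(n, 0, config$noise_sd)
  sigma_bio <- sqrt(.gen$load_u^2 + config$noise_sd^2)
  eta_bio <- .gen$mu0 + .gen$load_u * u -
    config$disease_effect_inter * sigma_bio * s * is_ms + eps
  eta <- eta_bio + center_shift[center_idx]
  p_inter <- stats::plogis(eta)
  p_inter_bio <- stats::plogis(eta_bio)

  # latent intrahemispheric strength: correlation with the biological logit
  # share equals conservation_coupling by construction
  # correlation is planted exactly: the independent component is
  # orthogonalized against the standardized logit share before mixing
  cc <- config$conservation_coupling
  u_hat <- if (stats::sd(eta_bio) > 0) {
    (eta_bio - mean(eta_bio)) / stats::sd(eta_bio)
  } else rep(0, n)
  z <- stats::rnorm(n)
  if (n > 3 && stats::sd(u_hat) > 0 && abs(cc) < 1) {
    z <- stats::residuals(stats::lm(z ~ u_hat))
    z <- z / stats::sd(z)
  }
  g <- cc * u_hat + sqrt(max(0, 1 - cc^2)) * z

  # subject fiber-length scale: compensates the mechanical budget dependence
  # of intra edge strength on (1 - p_inter), then applies the latent factor
  length_scale <- ((1 - p_inter) / (1 - mean(p_inter))) *
    exp(-.gen$len_effect * g)

  # demographics / clinical scores
  ms_col <- function(hc, ms) ifelse(is_ms, ms[center_idx], hc[center_idx])
  age <- pmin(80, pmax(18, stats::rnorm(
    n, ms_col(cp$age_hc_mean, cp$age_ms_mean),
    ms_col(cp$age_hc_sd, cp$age_ms_sd))))
  sex <- as.integer(stats::runif(n) < ms_col(cp$female_hc, cp$female_ms))
  subtype <- ifelse(is_ms,
                    c("CIS", "RRMS", "SPMS", "PPMS")[
                      findInterval(stats::runif(n), c(0.10, 0.80, 0.95)) + 1],
                    NA_character_)
  edss <- ifelse(is_ms,
                 pmin(10, pmax(0, round_half(1.0 + 1.6 * s +
                                               stats::rnorm(n, 0, 0.5)))),
                 NA_real_)
  sdmt <- ifelse(is_ms,
                 pmax(0, round(57 - 8 * s - 0.3 * (age - 40) +
                                 stats::rnorm(n, 0, 6))),
                 NA_real_)
  dd <- ifelse(is_ms, pmax(0.1, stats::rnorm(n, cp$dd_mean[center_idx],
                                             cp$dd_sd[center_idx])),
               NA_real_)

  # volumetric scalars (biological values, before batch effects)
  gmf <- pmin(0.6, pmax(0.3, 0.45 - 0.010 * s * is_ms -
                          0.0006 * (age - 40) + stats::rnorm(n, 0, 0.010)))
  wmf <- pmin(0.5, pmax(0.2, 0.33 + 0.10 * (p_inter_bio - 0.15) -
                          0.005 * s * is_ms + stats::rnorm(n, 0, 0.015)))
  lvf <- ifelse(is_ms, pmin(0.15, pmax(0, 0.002 + 0.006 * s +
                                         stats::rnorm(n, 0, 0.004))), 0)
  brain_volume <- stats::rnorm(n, 1.5e6, 1e5)
  cc_area <- pmax(100, 4000 * p_inter_bio + stats::rnorm(n, 0, 300))

  # per-center batch on scalars: multiplicative scale + additive shift at a
  # per-variable reference scale
  sc <- center_scale[center_idx]
  sh <- center_shift[center_idx]
  gmf <- gmf * sc + sh * 0.010
  wmf <- wmf * sc + sh * 0.010
  lvf <- pmax(0, lvf * sc + is_ms * sh * 0.003)
  cc_area <- cc_area * sc + sh * 40
  brain_volume <- brain_volume * sc + sh * 5e4

  ids <- sprintf("sub-%04d", seq_len(n))
  records <- data.frame(
    id = ids, center = cp$center[center_idx], age = age, sex = sex,
    diagnosis = ifelse(is_ms, "MS", "HC"), subtype = subtype,
    edss = edss, sdmt = sdmt, disease_duration = dd,
    gmf = gmf, wmf = wmf, lvf = lvf,
    cc_area = cc_area, brain_volume = brain_volume,
    stringsAsFactors = FALSE)

  connectomes <- vector("list", n)
  names(connectomes) <- ids
  for (i in seq_len(n)) {
    set.seed(subject_seed(config$seed, i, 1L))
    connectomes[[i]] <- build_subject_connectome(
      regions, p_inter[i], length_scale[i], center_scale[center_idx[i]],
      config$total_streamlines)
  }

  ground_truth <- list(
    subjects = data.frame(id = ids, center = cp$center[center_idx],
                          u = u, severity = s,
                          intra_strength = g,
                          p_inter = p_inter, p_inter_bio = p_inter_bio,
                          length_scale = length_scale,
                          stringsAsFactors = FALSE),
    centers = data.frame(center = cp$center, shift = center_shift,
                         scale = center_scale, stringsAsFactors = FALSE),
    config = unclass(config))

  structure(list(connectomes = connectomes, records = records,
                 ground_truth = ground_truth),
            class = "synthetic_cohort")
}

# One subject's weight/length matrices given the interhemispheric share, the
# subject fiber-length scale and the center weight scale.
build_subject_connectome <- function(regions, p_inter, length_scale,
                                     center_scale, total_streamlines) {
  nreg <- nrow(regions)
  w <- matrix(0, nreg, nreg)
  len <- matrix(0, nreg, nreg)
  left <- which(regions$hemisphere == "L")
  right <- which(regions$hemisphere == "R")
  lh_ctx <- which(regions$hemisphere == "L" & regions$cortical)
  rh_ctx <- which(regions$hemisphere == "R" & regions$cortical)

  sup_l <- random_connected_support(left, .gen$intra_density)
  sup_r <- random_connected_support(right, .gen$intra_density)
  # interhemispheric support: homotopic cortical pairs + random L x R pairs
  homot <- cbind(lh_ctx, rh_ctx)
  lr <- expand.grid(left, right)
  lr <- as.matrix(lr[!(lr[, 1] %in% homot[, 1] & lr[, 2] ==
                         homot[match(lr[, 1], homot[, 1]), 2]), ])
  n_extra <- round(.gen$inter_extra_frac * nrow(lr))
  sup_i <- rbind(homot, lr[sample.int(nrow(lr), n_extra), , drop = FALSE])

  fill_block <- function(sup, mass, meanlog, sdlog) {
    m <- nrow(sup)
    wts <- stats::rgamma(m, shape = 2, rate = 1)
    wts <- wts / sum(wts) * mass
    lens <- stats::rlnorm(m, meanlog, sdlog) * length_scale
    idx <- cbind(sup[, 1], sup[, 2])
    w[idx] <<- w[idx] + wts
    len[idx] <<- lens
  }
  fill_block(sup_l, (1 - p_inter) * total_streamlines / 2,
             .gen$intra_meanlog, .gen$intra_sdlog)
  fill_block(sup_r, (1 - p_inter) * total_streamlines / 2,
             .gen$intra_meanlog, .gen$intra_sdlog)
  fill_block(sup_i, p_inter * total_streamlines,
             .gen$inter_meanlog, .gen$inter_sdlog)

  w <- (w + t(w)) * center_scale
  len <- len + t(len)
  diag(w) <- 0
  connectome(w, len, regions$label, regions$hemisphere, regions$cortical,
             validate = FALSE)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%d MS, %d HC), %d centers\n",
              nrow(x$records), sum(x$records$diagnosis == "MS"),
              sum(x$records$diagnosis == "HC"),
              length(unique(x$records$center))))
  invisible(x)
}
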