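# Parametric empirical-Bayes location/scale batch correction (ComBat) with an
# explicit fit/apply split and JSON-serializable model, so a model estimated
# on one table can be reapplied to aligned data.

as_feature_matrix <- function(features) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (is.null(colnames(x)))
    colnames(x) <- paste0("feature_", seq_len(ncol(x)))
  x
}

as_covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  x <- as.matrix(covariates)
  storage.mode(x) <- "double"
  if (nrow(x) != n) stop("covariate rows do not match subjects", call. = FALSE)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("covariate_", seq_len(ncol(x)))
  x
}

#' Fit an empirical-Bayes batch-correction (ComBat) model
#'
#' Location/scale harmonization across acquisition centers, preserving
#' covariate effects (here typically age, sex, diagnosis). Steps: (1)
#' least-squares fit of per-batch means plus covariate effects, with the grand
#' mean taken as the batch-proportion-weighted combination of batch means;
#' (2) pooled residual variance per feature; (3) standardization; (4)
#' per-batch per-feature sample location/scale of the standardized data; (5)
#' moment-matched parametric priors (normal for locations, inverse-gamma for
#' scales); (6) iterated conditional posterior means until the largest
#' absolute change in any adjustment falls below `tol`.
#'
#' @param features subjects x features numeric matrix or data frame.
#' @param batch factor/character of center labels, one per subject.
#' @param covariates optional numeric design columns (no intercept) whose
#'   effects are preserved; must not be collinear with batch.
#' @param mode `"full"` (location and scale) or `"mean_only"` (location only;
#'   scale adjustments fixed at 1).
#' @param tol convergence tolerance on the empirical-Bayes adjustments.
#' @param max_iter iteration cap.
#' @return object of class `combat_model`.
#' @export
fit_combat <- function(features, batch, covariates = NULL,
                       mode = c("full", "mean_only"), tol = 1e-4,
                       max_iter = 100) {
  mode <- match.arg(mode)
  x <- as_feature_matrix(features)
  n <- nrow(x)
  p <- ncol(x)
  batch <- factor(batch)
  if (length(batch) != n) stop("batch length does not match subjects",
                               call. = FALSE)
  if (anyNA(x)) stop("features contain missing values; apply a row-drop ",
                     "policy first", call. = FALSE)
  cov <- as_covariate_matrix(covariates, n)
  levels_b <- levels(batch)
  nb <- table(batch)
  model <- list(feature_names = colnames(x), batch_levels = levels_b,
                covariate_names = colnames(cov), mode = mode, tol = tol)

  if (length(levels_b) < 2) {
    warning("single batch: returning identity model (no batch effect to ",
            "estimate)", call. = FALSE)
    model$identity <- TRUE
    class(model) <- "combat_model"
    return(model)
  }
  if (any(nb < 2)) stop("batch(es) with < 2 subjects: ",
                        paste(levels_b[nb < 2], collapse = ", "),
                        call. = FALSE)

  onehot <- stats::model.matrix(~ batch - 1)
  design <- cbind(onehot, cov)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    stop("design is rank deficient: covariate(s) collinear with batch ",
         "(columns: ",
         paste(colnames(design)[qr_d$pivot[seq.int(qr_d$rank + 1,
                                                   ncol(design))]],
               collapse = ", "), ")", call. = FALSE)
  }
  beta <- qr.coef(qr_d, x)                       # (B + q) x p
  b_levels <- seq_along(levels_b)
  grand_mean <- crossprod(as.numeric(nb) / n, beta[b_levels, , drop = FALSE])
  beta_cov <- if (is.null(cov)) NULL else beta[-b_levels, , drop = FALSE]

  fitted <- design %*% beta
  var_pooled <- colSums((x - fitted)^2) / n
  const_feat <- var_pooled <= .Machine$double.eps
  pooled_sd <- sqrt(ifelse(const_feat, 1, var_pooled))

  stand_mean <- matrix(grand_mean, n, p, byrow = TRUE)
  if (!is.null(cov)) stand_mean <- stand_mean + cov %*% beta_cov
  z <- sweep(x - stand_mean, 2, pooled_sd, "/")

  B <- length(levels_b)
  gamma_hat <- t(vapply(levels_b, function(b)
    colMeans(z[batch == b, , drop = FALSE]), numeric(p)))
  delta_hat <- t(vapply(levels_b, function(b)
    apply(z[batch == b, , drop = FALSE], 2, stats::var), numeric(p)))
  zero_var <- !is.finite(delta_hat) | delta_hat <= .Machine$double.eps
  if (any(zero_var))
    warning("feature(s) with zero variance within a batch: scale left ",
            "unadjusted there", call. = FALSE)
  delta_hat[zero_var] <- 1

  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1, stats::var)
  m_d <- rowMeans(delta_hat)
  s2_d <- apply(delta_hat, 1, stats::var)
  s2_d[s2_d <= .Machine$double.eps] <- .Machine$double.eps
  a_prior <- (2 * s2_d + m_d^2) / s2_d
  b_prior <- (m_d * s2_d + m_d^3) / s2_d

  gamma_star <- gamma_hat
  delta_star <- matrix(1, B, p)
  iterations <- rep(0L, B)
  final_change <- rep(0, B)
  for (bi in seq_len(B)) {
      nb_i <- as.numeric(nb[bi])
      g_old <- gamma_hat[bi, ]
      d_old <- if (mode == "full") delta_hat[bi, ] else rep(1, p)
      change <- Inf
      it <- 0L
      while (change > tol && it < max_iter) {
        g_new <- (nb_i * t2[bi] * gamma_hat[bi, ] + d_old * gamma_bar[bi]) /
          (nb_i * t2[bi] + d_old)
        if (mode == "full") {
          sum2 <- (nb_i - 1) * delta_hat[bi, ] +
            nb_i * (gamma_hat[bi, ] - g_new)^2
          d_new <- (b_prior[bi] + 0.5 * sum2) / (nb_i / 2 + a_prior[bi] - 1)
        } else d_new <- rep(1, p)
        change <- max(abs(g_new - g_old), abs(d_new - d_old))
        g_old <- g_new
        d_old <- d_new
        it <- it + 1L
      }
      gamma_star[bi, ] <- g_old
      delta_star[bi, ] <- d_old
      iterations[bi] <- it
      final_change[bi] <- change
  }
  delta_star[zero_var] <- 1
  delta_star[, const_feat] <- 1
  gamma_star[, const_feat] <- 0
  delta_star[delta_star <= 0] <- 1

  model <- c(model, list(
    identity = FALSE,
    grand_mean = as.numeric(grand_mean),
    beta_cov = beta_cov,
    pooled_sd = pooled_sd,
    constant_feature = const_feat,
    gamma_star = gamma_star, delta_star = delta_star,
    gamma_hat = gamma_hat, delta_hat = delta_hat,
    prior = list(gamma_bar = gamma_bar, tau2 = t2,
                 a = a_prior, b = b_prior),
    batch_sizes = as.numeric(nb),
    iterations = iterations, final_change = final_change))
  class(model) <- "combat_model"
  model
}

#' Apply a fitted batch-correction model
#'
#' Standardizes the input with the stored grand mean, covariate coefficients
#' and pooled scale, removes the per-batch empirical-Bayes location/scale
#' adjustments, and restores the preserved mean structure:
#' `y* = pooled_sd / sqrt(delta_star) * (z - gamma_star) + grand_mean +
#' covariate effects`.
#'
#' @param model a [fit_combat()] model.
#' @param features,batch,covariates data aligned as at fit time; batch levels
#'   must have been seen at fit time.
#' @return harmonized matrix with the shape and dimnames of `features`.
#' @export
apply_combat <- function(model, features, batch, covariates = NULL) {
  stopifnot(inherits(model, "combat_model"))
  x <- as_feature_matrix(features)
  if (isTRUE(model$identity)) return(x)
  if (!identical(colnames(x), model$feature_names))
    stop("feature columns do not match the fitted model", call. = FALSE)
  batch <- as.character(batch)
  unseen <- setdiff(unique(batch), model$batch_levels)
  if (length(unseen) > 0)
    stop("unseen batch level(s): ", paste(unseen, collapse = ", "),
         call. = FALSE)
  n <- nrow(x)
  p <- ncol(x)
  cov <- as_covariate_matrix(covariates, n)
  if (!identical(colnames(cov), model$covariate_names))
    stop("covariates do not match the fitted model", call. = FALSE)

  stand_mean <- matrix(model$grand_mean, n, p, byrow = TRUE)
  if (!is.null(cov)) stand_mean <- stand_mean + cov %*% model$beta_cov
  z <- sweep(x - stand_mean, 2, model$pooled_sd, "/")
  bi <- match(batch, model$batch_levels)
  adj <- (z - model$gamma_star[bi, , drop = FALSE]) /
    sqrt(model$delta_star[bi, , drop = FALSE])
  out <- sweep(adj, 2, model$pooled_sd, "*") + stand_mean
  out[, model$constant_feature] <- x[, model$constant_feature]
  dimnames(out) <- dimnames(x)
  out
}

#' Fit and apply in one step
#'
#' @inheritParams fit_combat
#' @return harmonized matrix.
#' @export
combat <- function(features, batch, covariates = NULL,
                   mode = c("full", "mean_only"), tol = 1e-4,
                   max_iter = 100) {
  model <- fit_combat(features, batch, covariates, mode = mode, tol = tol,
                      max_iter = max_iter)
  apply_combat(model, features, batch, covariates)
}

#' Serialize / restore a ComBat model as JSON
#'
#' @param model a `combat_model`.
#' @param path file path.
#' @return `combat_read_json` returns the restored model.
#' @export
combat_write_json <- function(model, path) {
  stopifnot(inherits(model, "combat_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname combat_write_json
#' @export
combat_read_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("gamma_star", "delta_star", "gamma_hat", "delta_hat",
              "beta_cov")) {
    if (!is.null(m[[f]])) m[[f]] <- as.matrix(m[[f]])
  }
  if (!is.null(m$beta_cov)) colnames(m$beta_cov) <- m$feature_names
  m$constant_feature <- as.logical(m$constant_feature)
  class(m) <- "combat_model"
  m
}

#' @export
print.combat_model <- function(x, ...) {
  if (isTRUE(x$identity)) {
    cat("<combat_model> identity (single batch)\n")
  } else {
    cat(sprintf("<combat_model> %d features, %d batches, mode=%s, iters=%s\n",
                length(x$feature_names), length(x$batch_levels), x$mode,
                paste(x$iterations, collapse = "/")))
  }
  invisible(x)
}

#' PCA diagnostic of harmonization
#'
#' Standardized principal-component projections of the feature table before
#' and after harmonization, with a center-separation statistic on PC1
#' (between-center variance over within-center variance of the PC1 scores).
#' A successful harmonization shrinks the statistic.
#'
#' @param features_before,features_after aligned subjects x features tables.
#' @param batch center labels.
#' @param n_components number of components to return (reduced with a warning
#'   on rank-deficient input).
#' @return list with `before`/`after` score matrices and a named
#'   `separation` vector.
#' @export
pca_diagnostic <- function(features_before, features_after, batch,
                           n_components = 2) {
  xb <- as_feature_matrix(features_before)
  xa <- as_feature_matrix(features_after)
  if (nrow(xb) < 3) stop("need at least 3 subjects", call. = FALSE)
  batch <- factor(batch)
  project <- function(x) {
    keep <- apply(x, 2, stats::sd) > 0
    pr <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
    k <- min(n_components, ncol(pr$x))
    if (k < n_components)
      warning("rank-deficient input: returning ", k, " component(s)",
              call. = FALSE)
    pr$x[, seq_len(k), drop = FALSE]
  }
  sep_stat <- function(scores) {
    pc1 <- scores[, 1]
    mu <- mean(pc1)
    gm <- tapply(pc1, batch, mean)
    ng <- tapply(pc1, batch, length)
    ssb <- sum(ng * (gm - mu)^2)
    ssw <- sum((pc1 - gm[batch])^2)
    (ssb / max(1, length(gm) - 1)) / (ssw / max(1, length(pc1) - length(gm)))
  }
  sb <- project(xb)
  sa <- project(xa)
  list(before = sb, after = sa,
       separation = c(before = sep_stat(sb), after = sep_stat(sa)))
}
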