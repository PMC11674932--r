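#' Commissural ratio
#'
#' Fraction of connection weight whose endpoints lie in opposite hemispheres:
#' `inter / total`. With raw streamline counts this is the share of
#' streamlines crossing hemispheres; the pipeline default computes it on the
#' length-normalized matrix, the matrix every other measure uses.
#'
#' @param inter_weight_sum interhemispheric weight mass (unordered pairs).
#' @param total_weight_sum total weight mass (unordered pairs), > 0.
#' @return proportion in \[0, 1\].
#' @export
commissural_ratio <- function(inter_weight_sum, total_weight_sum) {
  if (!is.finite(total_weight_sum) || total_weight_sum <= 0)
    stop("commissural ratio undefined: total weight sum must be > 0",
         call. = FALSE)
  if (inter_weight_sum < 0 || inter_weight_sum > total_weight_sum)
    stop("inter weight sum must lie in [0, total]", call. = FALSE)
  inter_weight_sum / total_weight_sum
}

#' Corpus callosum area ratio
#'
#' Midsagittal corpus callosum area normalized by brain volume. For
#' dimensional consistency (area over area) the default normalizer is
#' `brain_volume^(2/3)`; the exponent is exposed because the normalization
#' convention varies in the conservation-principle literature.
#'
#' @param cc_area midsagittal CC area, mm^2, > 0.
#' @param brain_volume total brain volume, mm^3, > 0.
#' @param exponent power applied to `brain_volume` (default 2/3).
#' @return dimensionless ratio.
#' @export
cc_ratio <- function(cc_area, brain_volume, exponent = 2 / 3) {
  if (!is.finite(cc_area) || cc_area <= 0)
    stop("cc_area must be positive", call. = FALSE)
  if (!is.finite(brain_volume) || brain_volume <= 0)
    stop("brain_volume must be positive", call. = FALSE)
  cc_area / brain_volume^exponent
}

shortest_path_matrix <- function(g) {
  el <- g$edge_length
  n <- nrow(el)
  ig <- igraph::graph_from_adjacency_matrix(el, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  igraph::distances(ig, algorithm = "dijkstra")
}

#' Mean shortest path length
#'
#' Mean graph distance over all unordered node pairs. The textbook form sums
#' over ordered pairs and divides by N(N-1); by symmetry that equals the
#' unordered-pair mean used here. On disconnected graphs the mean is taken
#' over reachable pairs only and the number of unreachable pairs is attached
#' as attribute `n_unreachable` (mean SPL has no standard convention for
#' infinite distances; efficiency is the robust measure there).
#'
#' @param g a `distance_graph` with at least 2 nodes.
#' @return mean shortest path length (`NaN` if no pair is reachable), with
#'   attribute `n_unreachable`.
#' @export
mean_spl <- function(g) {
  n <- length(g$labels)
  if (n < 2) stop("mean SPL needs at least 2 nodes", call. = FALSE)
  d <- shortest_path_matrix(g)[upper.tri(diag(n))]
  reachable <- is.finite(d)
  out <- if (any(reachable)) mean(d[reachable]) else NaN
  attr(out, "n_unreachable") <- sum(!reachable)
  out
}

#' Network efficiency
#'
#' Mean inverse shortest path length over all unordered node pairs, with
#' unreachable pairs contributing 0. Efficiency quantifies network
#' integration and, unlike mean SPL, degrades gracefully on graphs with
#' disconnected nodes.
#'
#' @param g a `distance_graph` with at least 2 nodes.
#' @return efficiency >= 0.
#' @export
efficiency <- function(g) {
  n <- length(g$labels)
  if (n < 2) stop("efficiency needs at least 2 nodes", call. = FALSE)
  d <- shortest_path_matrix(g)[upper.tri(diag(n))]
  inv <- ifelse(is.finite(d), 1 / d, 0)
  mean(inv)
}

#' Per-subject hemispheric connectivity measures
#'
#' Runs the full per-subject measurement chain on a cortical,
#' length-normalized connectome: hemispheric partition, commissural ratio
#' (interhemispheric, tractography-derived), CC area ratio (interhemispheric,
#' volumetric), and per-hemisphere mean shortest path length and efficiency on
#' the inverse-weight distance graphs (intrahemispheric), averaged across
#' hemispheres. The four inter/intra ratios are the interhemispheric measures
#' divided by the averaged intrahemispheric measures.
#'
#' @param c a cortical, length-normalized `connectome`.
#' @param cc_area midsagittal CC area, mm^2.
#' @param brain_volume brain volume, mm^3.
#' @param cc_exponent exponent passed to [cc_ratio()].
#' @param midline passed to [hemisphere_blocks()].
#' @return one-row `data.frame` with columns `commissural_ratio`, `cc_ratio`,
#'   `spl_left`, `spl_right`, `spl_mean`, `eff_left`, `eff_right`, `eff_mean`,
#'   `ratio_commissural_spl`, `ratio_commissural_eff`, `ratio_ccratio_spl`,
#'   `ratio_ccratio_eff`.
#' @export
subject_metrics <- function(c, cc_area, brain_volume, cc_exponent = 2 / 3,
                            midline = "exclude") {
  blocks <- hemisphere_blocks(c, midline = midline)
  cr <- commissural_ratio(blocks$inter_weight_sum, blocks$total_weight_sum)
  ccr <- cc_ratio(cc_area, brain_volume, exponent = cc_exponent)
  gl <- to_distance_graph(blocks$left)
  gr <- to_distance_graph(blocks$right)
  spl_l <- as.numeric(mean_spl(gl))
  spl_r <- as.numeric(mean_spl(gr))
  eff_l <- efficiency(gl)
  eff_r <- efficiency(gr)
  spl_m <- (spl_l + spl_r) / 2
  eff_m <- (eff_l + eff_r) / 2
  data.frame(
    commissural_ratio = cr, cc_ratio = ccr,
    spl_left = spl_l, spl_right = spl_r, spl_mean = spl_m,
    eff_left = eff_l, eff_right = eff_r, eff_mean = eff_m,
    ratio_commissural_spl = cr / spl_m,
    ratio_commissural_eff = cr / eff_m,
    ratio_ccratio_spl = ccr / spl_m,
    ratio_ccratio_eff = ccr / eff_m)
}

#' Hemispheric measures for every subject of a cohort
#'
#' Applies the standard processing order — length-normalize, restrict to
#' cortical regions, measure — to each connectome and binds the per-subject
#' rows into one table keyed by subject id.
#'
#' @param connectomes named list of raw `connectome` objects (weights =
#'   streamline counts, not yet length-normalized).
#' @param records subject table containing `id`, `cc_area`, `brain_volume`
#'   aligned with `names(connectomes)`.
#' @param cc_exponent,midline passed to [subject_metrics()].
#' @param commissural_weights matrix the commissural ratio is computed on:
#'   `"normalized"` (default; the length-normalized matrix every other
#'   measure uses) or `"raw"` streamline counts.
#' @return `data.frame`: one row per subject, `id` plus the
#'   [subject_metrics()] columns.
#' @export
cohort_metrics <- function(connectomes, records, cc_exponent = 2 / 3,
                           midline = "exclude",
                           commissural_weights = c("normalized", "raw")) {
  commissural_weights <- match.arg(commissural_weights)
  ids <- names(connectomes)
  if (is.null(ids) || !setequal(ids, records$id))
    stop("connectome names and record ids do not match", call. = FALSE)
  rows <- lapply(ids, function(id) {
    rec <- records[records$id == id, ]
    row <- tryCatch({
      c <- cortical_subgraph(normalize_by_length(connectomes[[id]]))
      m <- subject_metrics(c, rec$cc_area, rec$brain_volume,
                           cc_exponent = cc_exponent, midline = midline)
      if (commissural_weights == "raw") {
        raw <- suppressWarnings(hemisphere_blocks(
          cortical_subgraph(connectomes[[id]]), midline = midline))
        m$commissural_ratio <- commissural_ratio(raw$inter_weight_sum,
                                                 raw$total_weight_sum)
        m$ratio_commissural_spl <- m$commissural_ratio / m$spl_mean
        m$ratio_commissural_eff <- m$commissural_ratio / m$eff_mean
      }
      m
    }, error = function(e) {
      stop("subject ", id, ": ", conditionMessage(e), call. = FALSE)
    })
    cbind(data.frame(id = id, stringsAsFactors = FALSE), row)
  })
  do.call(rbind, rows)
}
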