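#' Construct a connectome object
#'
#' A connectome bundles a labeled, symmetric streamline-weight matrix with the
#' matching fiber-length matrix over a parcellation whose regions carry a
#' hemisphere tag (`"L"`, `"R"` or `"M"` for midline) and a cortical flag.
#' Weights are SIFT2-weighted streamline counts or any derived connection
#' strength; lengths are mean streamline lengths in mm, positive wherever a
#' connection exists.
#'
#' @param weights symmetric non-negative numeric matrix, zero diagonal.
#' @param lengths symmetric numeric matrix, strictly positive wherever
#'   `weights > 0`; entries without a connection are ignored.
#' @param labels character vector of region identifiers, one per row.
#' @param hemisphere character vector of `"L"`, `"R"`, `"M"` tags.
#' @param cortical logical vector flagging cortical regions.
#' @param validate if `TRUE` (default), check all invariants and stop on
#'   violation.
#' @return an object of class `connectome`.
#' @export
connectome <- function(weights, lengths, labels, hemisphere, cortical,
                       validate = TRUE) {
  weights <- as.matrix(weights)
  lengths <- as.matrix(lengths)
  obj <- structure(
    list(labels = as.character(labels),
         hemisphere = as.character(hemisphere),
         cortical = as.logical(cortical),
         weights = weights,
         lengths = lengths),
    class = "connectome")
  if (validate) {
    problems <- validate_connectome(obj)
    if (length(problems) > 0L) {
      stop("invalid connectome: ", paste(problems, collapse = "; "),
           call. = FALSE)
    }
  }
  obj
}

#' Validate connectome invariants
#'
#' Checks symmetry (within 1e-9), non-negativity, zero diagonal, positive
#' lengths wherever weights are positive, tag validity, and that at least one
#' cortical region exists per hemisphere.
#'
#' @param x a `connectome`.
#' @return character vector of violated invariants; `character(0)` if valid.
#' @export
validate_connectome <- function(x) {
  problems <- character(0)
  n <- length(x$labels)
  w <- x$weights
  len <- x$lengths
  if (!is.matrix(w) || nrow(w) != n || ncol(w) != n)
    return("weights is not an n x n matrix matching labels")
  if (!is.matrix(len) || nrow(len) != n || ncol(len) != n)
    return("lengths is not an n x n matrix matching labels")
  if (length(x$hemisphere) != n || length(x$cortical) != n)
    return("hemisphere/cortical tags do not match number of regions")
  if (anyNA(w)) problems <- c(problems, "weights contain NA")
  if (max(abs(w - t(w))) > 1e-9)
    problems <- c(problems, "weights not symmetric within 1e-9")
  if (any(diag(w) != 0)) problems <- c(problems, "weight diagonal not zero")
  if (any(w < 0)) problems <- c(problems, "negative weights")
  conn <- w > 0
  if (any(conn & !(len > 0)))
    problems <- c(problems, "non-positive length on a connected pair")
  if (max(abs(len - t(len)), na.rm = TRUE) > 1e-9)
    problems <- c(problems, "lengths not symmetric within 1e-9")
  if (!all(x$hemisphere %in% c("L", "R", "M")))
    problems <- c(problems, "hemisphere tags outside {L,R,M}")
  for (h in c("L", "R")) {
    if (!any(x$cortical & x$hemisphere == h))
      problems <- c(problems, paste0("no cortical region in hemisphere ", h))
  }
  problems
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d regions (%d cortical; L=%d R=%d M=%d), %d connections\n",
              length(x$labels), sum(x$cortical),
              sum(x$hemisphere == "L"), sum(x$hemisphere == "R"),
              sum(x$hemisphere == "M"),
              sum(x$weights[upper.tri(x$weights)] > 0)))
  invisible(x)
}

#' Divide connection weights by fiber length
#'
#' Length normalization of the structural connectivity matrix: every non-zero
#' weight is divided by the corresponding fiber length, removing the bias of
#' streamline counts toward long fibers. Zero weights stay zero regardless of
#' length; the length matrix is carried through unchanged. The operation is
#' deliberately not idempotent — applying it twice divides by length twice.
#'
#' @param c a `connectome`.
#' @return a `connectome` with length-normalized weights.
#' @export
normalize_by_length <- function(c) {
  w <- c$weights
  conn <- w > 0
  if (any(conn & !(c$lengths > 0)))
    stop("invalid connectome: connection with non-positive fiber length",
         call. = FALSE)
  w[conn] <- w[conn] / c$lengths[conn]
  out <- c
  out$weights <- w
  out
}

#' Restrict a connectome to cortical regions
#'
#' Drops all subcortical rows/columns, keeping only connections between
#' cortical areas (the hemispheric measures are defined on the cortical
#' subgraph).
#'
#' @param c a `connectome`.
#' @return a `connectome` over the cortical regions only, with attribute
#'   `n_dropped` giving the number of removed regions.
#' @export
cortical_subgraph <- function(c) {
  keep <- which(c$cortical)
  if (length(keep) == 0L)
    stop("connectome has no cortical regions", call. = FALSE)
  out <- connectome(c$weights[keep, keep, drop = FALSE],
                    c$lengths[keep, keep, drop = FALSE],
                    c$labels[keep], c$hemisphere[keep], c$cortical[keep],
                    validate = FALSE)
  attr(out, "n_dropped") <- length(c$labels) - length(keep)
  out
}

#' Convert a connectome to an inverse-weight distance graph
#'
#' Edge lengths are the reciprocal of the (length-normalized) connection
#' weights: strong connections become short edges. Pairs with zero weight get
#' no edge (absence, never an infinite length). The caller is responsible for
#' length-normalizing first; the pipeline enforces that order.
#'
#' @param c a `connectome`.
#' @return an object of class `distance_graph` with fields `labels`,
#'   `hemisphere`, and `edge_length` (dense symmetric matrix, 0 = no edge).
#' @export
to_distance_graph <- function(c) {
  d <- c$weights
  conn <- d > 0
  d[conn] <- 1 / d[conn]
  structure(list(labels = c$labels, hemisphere = c$hemisphere,
                 edge_length = d),
            class = "distance_graph")
}

#' @export
print.distance_graph <- function(x, ...) {
  cat(sprintf("<distance_graph> %d nodes, %d edges\n", length(x$labels),
              sum(x$edge_length[upper.tri(x$edge_length)] > 0)))
  invisible(x)
}

#' Partition a connectome into hemispheric blocks
#'
#' Splits the graph into the two within-hemisphere subgraphs and sums the
#' interhemispheric weight mass (pairs whose endpoints carry opposed L/R tags,
#' each unordered pair counted once) and the total weight mass over all
#' unordered pairs.
#'
#' @param c a `connectome`.
#' @param midline what to do with `"M"`-tagged regions: `"exclude"` (default;
#'   dropped with a warning if any carry weight) or `"error"`.
#' @return list with elements `left`, `right` (connectomes), `inter_weight_sum`
#'   and `total_weight_sum`.
#' @export
hemisphere_blocks <- function(c, midline = c("exclude", "error")) {
  midline <- match.arg(midline)
  is_m <- c$hemisphere == "M"
  if (any(is_m)) {
    if (midline == "error")
      stop("midline-tagged region(s) present: ",
           paste(c$labels[is_m], collapse = ", "), call. = FALSE)
    if (any(c$weights[is_m, ] > 0))
      warning("excluding ", sum(is_m),
              " midline region(s) carrying connection weight", call. = FALSE)
    keep <- which(!is_m)
    c <- connectome(c$weights[keep, keep, drop = FALSE],
                    c$lengths[keep, keep, drop = FALSE],
                    c$labels[keep], c$hemisphere[keep], c$cortical[keep],
                    validate = FALSE)
  }
  block <- function(h) {
    idx <- which(c$hemisphere == h)
    connectome(c$weights[idx, idx, drop = FALSE],
               c$lengths[idx, idx, drop = FALSE],
               c$labels[idx], c$hemisphere[idx], c$cortical[idx],
               validate = FALSE)
  }
  ut <- upper.tri(c$weights)
  opposed <- outer(c$hemisphere, c$hemisphere,
                   function(a, b) (a == "L" & b == "R") | (a == "R" & b == "L"))
  list(left = block("L"),
       right = block("R"),
       inter_weight_sum = sum(c$weights[ut & opposed]),
       total_weight_sum = sum(c$weights[ut]))
}
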