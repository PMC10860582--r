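#' Thresholded volume of a 3D map
#'
#' Counts voxels satisfying a predicate and converts to millilitres
#' (voxel volume = product of spacings in mm^3 / 1000).
#'
#' @param map 3D numeric array.
#' @param predicate Function mapping the array to a logical array, e.g.
#'   `function(x) x > 6`.
#' @param spacing Voxel spacing in mm (length 3, > 0).
#' @return Volume in mL.
#' @export
#' @examples
#' m <- array(c(0, 8, 12, 0), dim = c(2, 2, 1))
#' thresholded_volume(m, function(x) x > 6, spacing = c(1, 1, 1))
thresholded_volume <- function(map, predicate, spacing) {
  stopifnot(length(dim(map)) == 3, length(spacing) == 3, all(spacing > 0))
  if (!all(is.finite(map)))
    stop("thresholded_volume: non-finite map values", call. = FALSE)
  sum(predicate(map)) * prod(spacing) / 1000
}

#' Core and penumbra volumes from perfusion maps
#'
#' Core is relative CBF < 30% of normal; penumbra is Tmax > 6 s.
#'
#' @param maps A `perfusion_maps` object (`rcbf_ratio`, `tmax`, `spacing`).
#' @return A tibble with `core_mL` and `penumbra_mL`.
#' @export
perfusion_volumes <- function(maps) {
  tibble::tibble(
    core_mL = thresholded_volume(maps$rcbf_ratio, function(x) x < 0.3,
                                 maps$spacing),
    penumbra_mL = thresholded_volume(maps$tmax, function(x) x > 6,
                                     maps$spacing)
  )
}

#' Hypoperfusion intensity ratio
#'
#' HIR = volume(Tmax > 10 s) / volume(Tmax > 6 s), a perfusion surrogate for
#' collateral quality (lower = better collaterals). Threshold nesting
#' guarantees a value in \[0, 1\].
#'
#' @param maps A `perfusion_maps` object.
#' @param severe_s,any_s Numerator and denominator Tmax thresholds (s);
#'   defaults 10 and 6.
#' @return HIR in \[0, 1\].
#' @export
compute_hir <- function(maps, severe_s = 10, any_s = 6) {
  den <- thresholded_volume(maps$tmax, function(x) x > any_s, maps$spacing)
  if (den == 0)
    stop("compute_hir: no Tmax > 6 s volume; HIR undefined", call. = FALSE)
  num <- thresholded_volume(maps$tmax, function(x) x > severe_s, maps$spacing)
  num / den
}

#' Dichotomise collateral status from HIR
#'
#' HIR < 0.5 marks good and HIR >= 0.5 poor collaterals.
#'
#' @param hir HIR value(s) in \[0, 1\]; vectorised.
#' @return Character vector, `"good"` or `"poor"`.
#' @export
classify_collaterals_hir <- function(hir) {
  if (any(!is.finite(hir) | hir < 0 | hir > 1))
    stop("classify_collaterals_hir: HIR must lie in [0, 1]", call. = FALSE)
  ifelse(hir < 0.5, "good", "poor")
}

# 26-connected components of a 3D logical mask, via igraph on the
# suprathreshold-voxel adjacency graph. Returns an integer label array
# (0 = background).
label_components_26 <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, dim = d)
  if (length(idx) == 0) return(lab)
  coord <- arrayInd(idx, d)
  pos <- integer(prod(d)); pos[idx] <- seq_along(idx)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0 & (off[, 1] > 0 |
             (off[, 1] == 0 & (off[, 2] > 0 | (off[, 2] == 0 & off[, 3] > 0)))), ,
             drop = FALSE]  # half the neighbourhood; edges are undirected
  edges <- NULL
  for (r in seq_len(nrow(off))) {
    nb <- sweep(coord, 2, off[r, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- (nb[ok, 3] - 1) * d[1] * d[2] + (nb[ok, 2] - 1) * d[1] + nb[ok, 1]
    hit <- pos[nb_lin] > 0
    if (any(hit))
      edges <- rbind(edges, cbind(which(ok)[hit], pos[nb_lin[hit]]))
  }
  if (is.null(edges)) {
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  }
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

#' Lesion volume from a probability map with inclusion filtering
#'
#' Binarises a voxelwise lesion-probability map at `prob_threshold`
#' (inclusive), labels 26-connected components, and applies the inclusion
#' rules: components with volume `<= min_volume_mL` are dropped, as are
#' components whose majority voxel lies in the contralateral hemisphere or
#' cerebellum (false positives outside the affected hemisphere).
#'
#' @param prob 3D probability map in \[0, 1\].
#' @param hemisphere 3D label array over the same grid, with values
#'   `"ipsilateral"`, `"contralateral"`, `"cerebellum"`, `"outside"`.
#' @param spacing Voxel spacing (mm).
#' @param prob_threshold Probability cut, inclusive; default 0.5.
#' @param min_volume_mL Strict minimum component volume; default 0.1 mL.
#' @return A tibble with `volume_mL`, `n_components_kept`,
#'   `n_components_rejected`.
#' @export
lesion_volume_from_probability <- function(prob, hemisphere, spacing,
                                           prob_threshold = 0.5,
                                           min_volume_mL = 0.1) {
  stopifnot(length(dim(prob)) == 3, all(spacing > 0))
  if (any(prob < 0 | prob > 1))
    stop("lesion_volume_from_probability: probabilities outside [0, 1]",
         call. = FALSE)
  if (is.null(hemisphere) || !identical(dim(hemisphere), dim(prob)))
    stop("lesion_volume_from_probability: hemisphere labels missing or misshapen",
         call. = FALSE)
  voxvol <- prod(spacing) / 1000
  lab <- label_components_26(prob >= prob_threshold)
  ncomp <- max(lab)
  kept <- 0L; rejected <- 0L; vol <- 0
  if (ncomp > 0) {
    for (k in seq_len(ncomp)) {
      in_k <- lab == k
      v <- sum(in_k) * voxvol
      side <- names(which.max(table(hemisphere[in_k])))
      if (v > min_volume_mL && side == "ipsilateral") {
        kept <- kept + 1L; vol <- vol + v
      } else rejected <- rejected + 1L
    }
  }
  tibble::tibble(volume_mL = vol, n_components_kept = kept,
                 n_components_rejected = rejected)
}
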