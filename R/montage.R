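#' Standard 32-channel montage with auxiliary electrodes
#'
#' Approximate 2D head-plane coordinates (azimuthal projection, head radius
#' 1, x toward the right ear, y toward the nasion) for the 32 scalp
#' electrodes of the 10-20 layout used throughout the package, plus the
#' four auxiliary electrodes (two EOG above/below the right eye, two
#' mastoids). Coordinates are used for neighbor adjacency in the cluster
#' permutation test, bad-channel interpolation, and simulated topographies;
#' they are a layout, not a conduction model.
#'
#' @return A data.frame with columns `label`, `x`, `y` and `type`
#'   (`"scalp"`, `"eog"` or `"mastoid"`).
#' @export
#' @examples
#' head(standard_montage())
standard_montage <- function() {
  scalp <- data.frame(
    label = c("Fp1", "AF3", "F7", "F3", "FC1", "FC5", "T7", "C3",
              "CP1", "CP5", "P7", "P3", "Pz", "PO3", "O1", "Oz",
              "O2", "PO4", "P4", "P8", "CP6", "CP2", "C4", "T8",
              "FC6", "FC2", "F4", "F8", "AF4", "Fp2", "Fz", "Cz"),
    x = c(-0.31, -0.34, -0.81, -0.44, -0.23, -0.69, -1.00, -0.50,
          -0.23, -0.69, -0.81, -0.44,  0.00, -0.34, -0.31,  0.00,
           0.31,  0.34,  0.44,  0.81,  0.69,  0.23,  0.50,  1.00,
           0.69,  0.23,  0.44,  0.81,  0.34,  0.31,  0.00,  0.00),
    y = c( 0.95,  0.83,  0.59,  0.56,  0.28,  0.30,  0.00,  0.00,
          -0.28, -0.30, -0.59, -0.56, -0.50, -0.83, -0.95, -1.00,
          -0.95, -0.83, -0.56, -0.59, -0.30, -0.28,  0.00,  0.00,
           0.30,  0.28,  0.56,  0.59,  0.83,  0.95,  0.50,  0.00),
    type = "scalp",
    stringsAsFactors = FALSE
  )
  aux <- data.frame(
    label = c("EOG1", "EOG2", "M1", "M2"),
    x = c(0.42, 0.42, -1.15, 1.15),
    y = c(1.15, 0.85, -0.10, -0.10),
    type = c("eog", "eog", "mastoid", "mastoid"),
    stringsAsFactors = FALSE
  )
  rbind(scalp, aux)
}

#' Frontotemporal electrode cluster used for cortical peak extraction
#'
#' The auditory-relevant frontotemporal cluster over which cortical TRF and
#' AEP waveforms are averaged before N1/P2 extraction.
#'
#' @return Character vector of electrode labels.
#' @export
frontotemporal_cluster <- function() {
  c("F3", "FC1", "FC5", "FC6", "FC2", "F4")
}

#' Electrode adjacency from montage distances
#'
#' Builds a symmetric logical adjacency matrix over scalp electrodes:
#' two electrodes are neighbors when their planar distance is below
#' `threshold` (head radius = 1). Used to form spatial clusters in
#' [electrode_permutation_test()].
#'
#' @param labels electrode labels; default all scalp channels of
#'   [standard_montage()].
#' @param threshold neighbor distance threshold.
#' @return logical matrix with dimnames `labels`; diagonal is `FALSE`.
#' @export
montage_adjacency <- function(labels = NULL, threshold = 0.55) {
  mon <- standard_montage()
  if (is.null(labels)) labels <- mon$label[mon$type == "scalp"]
  idx <- match(labels, mon$label)
  if (anyNA(idx)) {
    stop("unknown electrode label(s): ",
         paste(labels[is.na(idx)], collapse = ", "))
  }
  xy <- cbind(mon$x[idx], mon$y[idx])
  d <- as.matrix(dist(xy))
  adj <- d > 0 & d < threshold
  dimnames(adj) <- list(labels, labels)
  adj
}

# connected components of an undirected adjacency over `nodes` (indices
# into the adjacency); tiny graphs only, so a plain stack walk is enough
.components <- function(adj, nodes) {
  comps <- list()
  remaining <- nodes
  while (length(remaining)) {
    stack <- remaining[1]
    comp <- integer(0)
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (v %in% comp) next
      comp <- c(comp, v)
      nb <- intersect(which(adj[v, ]), remaining)
      stack <- c(stack, setdiff(nb, comp))
    }
    comps[[length(comps) + 1L]] <- sort(comp)
    remaining <- setdiff(remaining, comp)
  }
  comps
}
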