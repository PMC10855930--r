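# --- background removal and per-seed spectrum extraction --------------------

#' Mask the acquisition background of a reflectance cube
#'
#' Foreground pixels are those whose band-averaged reflectance exceeds a
#' threshold: either Otsu's threshold computed on the band-mean image
#' (`method = "otsu"`, parameter-free default) or a fixed value
#' (`method = "fixed"`, via `threshold`).
#'
#' @param cube Reflectance [hypercube()].
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Fixed reflectance threshold (only for
#'   `method = "fixed"`).
#' @return Logical rows x cols matrix, TRUE = foreground. Errors if the mask
#'   comes out all-foreground or all-background (degenerate segmentation).
#' @export
background_mask <- function(cube, method = c("otsu", "fixed"),
                            threshold = NULL) {
  stopifnot(inherits(cube, "hypercube"))
  if (cube$kind != "reflectance")
    stop("background_mask expects a reflectance cube; calibrate first")
  method <- match.arg(method)
  bm <- rowMeans(matrix(cube$data, prod(dim(cube$data)[1:2]),
                        dim(cube$data)[3]))
  bm <- matrix(bm, dim(cube$data)[1], dim(cube$data)[2])
  thr <- if (method == "fixed") {
    if (is.null(threshold)) stop("method 'fixed' needs a threshold")
    threshold
  } else {
    rng <- range(bm)
    if (diff(rng) < 1e-12)
      stop("degenerate segmentation: band-mean image is uniform (value ",
           signif(rng[1], 4), ")")
    # Otsu on the [0,1]-rescaled band-mean image
    sc <- (bm - rng[1]) / diff(rng)
    EBImage::otsu(EBImage::Image(sc), range = c(0, 1)) * diff(rng) + rng[1]
  }
  mask <- bm > thr
  nf <- sum(mask)
  if (nf == 0L || nf == length(mask))
    stop("degenerate segmentation: ", nf, " of ", length(mask),
         " pixels foreground at threshold ", signif(thr, 4),
         " (band-mean range ", signif(min(bm), 4), "-", signif(max(bm), 4), ")")
  mask
}

# Label connected foreground components. EBImage::bwlabel is 4-connected;
# for 8-connectivity, labels that touch diagonally are merged afterwards.
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (connectivity == 8 && max(lab) > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    # diagonal neighbour label pairs
    pairs <- rbind(
      cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
      cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1])))
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                     pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      # union-find over the (small) label graph
      parent <- seq_len(max(lab))
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (r in seq_len(nrow(pairs))) {
        a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      root <- vapply(seq_along(parent), find, integer(1))
      dense <- match(root, sort(unique(root)))
      lab[lab > 0L] <- dense[lab[lab > 0L]]
    }
  }
  lab
}

#' Extract per-object mean spectra from a masked cube
#'
#' Connected foreground components with at least `min_object_size` pixels
#' become objects; each object's spectrum is the arithmetic mean of its
#' pixels at every band. Objects are ordered deterministically by centroid,
#' row-major (row first, then column), and re-labelled 1..n in that order
#' (0 is background).
#'
#' @param cube Reflectance [hypercube()].
#' @param mask Logical rows x cols foreground mask.
#' @param min_object_size Minimum component size in px; default 20.
#' @param connectivity Pixel connectivity, 4 or 8 (default).
#' @return A [spectrum_table()] with `object_ids`, `pixel_counts` and a
#'   `label_image` attribute holding the relabelled component image.
#' @export
extract_mean_spectra <- function(cube, mask, min_object_size = 20,
                                 connectivity = 8) {
  stopifnot(inherits(cube, "hypercube"), is.logical(mask))
  if (!identical(dim(mask), dim(cube$data)[1:2]))
    stop("mask shape does not match cube")
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_object_size)
  if (length(keep) == 0L)
    stop("empty table: no component reaches min_object_size = ",
         min_object_size)

  nr <- nrow(lab)
  idx_by_obj <- split(seq_along(lab), lab)
  idx_by_obj <- idx_by_obj[as.character(keep)]
  # row-major centroid ordering (0-based coords)
  cent <- t(vapply(idx_by_obj, function(ix) {
    c(mean((ix - 1L) %% nr), mean((ix - 1L) %/% nr))
  }, numeric(2)))
  ord <- order(cent[, 1], cent[, 2])
  idx_by_obj <- idx_by_obj[ord]

  nb <- dim(cube$data)[3]
  flat <- matrix(cube$data, ncol = nb)
  sp <- t(vapply(idx_by_obj, function(ix) colMeans(flat[ix, , drop = FALSE]),
                 numeric(nb)))
  relab <- matrix(0L, nr, ncol(lab))
  for (i in seq_along(idx_by_obj)) relab[idx_by_obj[[i]]] <- i

  st <- spectrum_table(sp, cube$wavelengths, labels = NULL,
                       object_ids = seq_along(idx_by_obj),
                       pixel_counts = lengths(idx_by_obj))
  attr(st, "label_image") <- relab
  st
}

#' Attach ground-truth class labels to an extracted spectrum table
#'
#' Matches extracted objects to ground-truth objects by majority overlap of
#' their label images.
#'
#' @param st Result of [extract_mean_spectra()] (needs its `label_image`).
#' @param truth Ground truth from [render_scene()].
#' @return The table with `labels` filled in.
#' @export
label_from_truth <- function(st, truth) {
  relab <- attr(st, "label_image")
  if (is.null(relab)) stop("spectrum table carries no label image")
  labs <- character(nrow(st$spectra))
  for (i in seq_len(nrow(st$spectra))) {
    tl <- truth$label_image[relab == i]
    tl <- tl[tl > 0L]
    if (length(tl) == 0L) stop("extracted object ", i,
                               " overlaps no ground-truth object")
    labs[i] <- truth$object_classes[[names(which.max(table(tl)))]]
  }
  st$labels <- labs
  st
}
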