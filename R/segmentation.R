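#' Segment 3D nodules from a microscopy frame
#'
#' Standard morphology pipeline: global automatic threshold (Otsu by
#' default, on the min--max normalised image, so segmentation is invariant
#' to positive intensity rescaling), morphological opening with a disc
#' brush, hole filling, 8-connected component labelling, and removal of
#' objects below the minimum area (in um^2, so results are
#' resolution-independent). The background mask is the logical negation of
#' the foreground ("negative binary mask"), defining the ECM pixels.
#'
#' @param image Numeric matrix (a.u.), finite-valued.
#' @param config A [study_config()]; `config$segmentation` supplies
#'   `method` ("otsu" or "fixed"), `fixed_threshold` (on the normalised
#'   0--1 scale), `min_area_um2` and `opening_radius_px`.
#' @return An object of class `mask_pair`: list with `foreground` and
#'   `background` (disjoint, jointly exhaustive logical matrices),
#'   `labels` (integer matrix, nonzero ids inside the foreground) and
#'   `threshold` (on the normalised scale).
#' @export
segment_nodules <- function(image, config = study_config()) {
  if (!is.matrix(image) || any(!is.finite(image))) {
    stop("`image` must be a finite-valued matrix", call. = FALSE)
  }
  sg <- config$segmentation
  rng <- range(image)
  if (diff(rng) <= 0) {
    warning("blank image (zero variance): empty foreground")
    return(.mask_pair(matrix(FALSE, nrow(image), ncol(image)),
                      matrix(0L, nrow(image), ncol(image)), NA_real_))
  }
  xn <- (image - rng[1]) / diff(rng)
  thr <- if (identical(sg$method, "fixed") && is.finite(sg$fixed_threshold)) {
    sg$fixed_threshold
  } else {
    EBImage::otsu(EBImage::Image(xn), range = c(0, 1), levels = 256)
  }
  fg <- xn > thr
  if (sg$opening_radius_px > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(sg$opening_radius_px) + 1L,
                                shape = "disc")
    fg <- EBImage::opening(fg, brush) > 0
  }
  fg <- EBImage::fillHull(fg) > 0
  labels <- .label8(fg)
  # size filter in physical units
  min_px <- config$segmentation$min_area_um2 / config$pixel_size_um^2
  tab <- tabulate(labels[labels > 0L])
  drop <- which(tab < min_px)
  if (length(drop)) labels[labels %in% drop] <- 0L
  # relabel sequentially
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids)) {
    labels[labels > 0L] <- match(labels[labels > 0L], ids)
  }
  .mask_pair(labels > 0L, labels, thr)
}

.mask_pair <- function(fg, labels, threshold) {
  out <- list(foreground = fg, background = !fg, labels = labels,
              threshold = threshold)
  class(out) <- "mask_pair"
  stopifnot(!any(out$foreground & out$background),
            all(out$foreground | out$background),
            all(labels[!fg] == 0L))
  out
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a union-find pass.
.label8 <- function(fg) {
  labels <- EBImage::imageData(EBImage::bwlabel(fg))
  storage.mode(labels) <- "integer"
  nmax <- max(labels)
  if (nmax < 2L) return(labels)
  H <- nrow(labels); W <- ncol(labels)
  a1 <- labels[-H, -W]; b1 <- labels[-1, -1]   # diag down-right
  a2 <- labels[-H, -1]; b2 <- labels[-1, -W]   # diag down-left
  pairs <- rbind(
    cbind(a1[a1 > 0L & b1 > 0L & a1 != b1], b1[a1 > 0L & b1 > 0L & a1 != b1]),
    cbind(a2[a2 > 0L & b2 > 0L & a2 != b2], b2[a2 > 0L & b2 > 0L & a2 != b2])
  )
  parent <- seq_len(nmax)
  find <- function(i) { while (parent[i] != i) i <- parent[i] <<- parent[parent[i]]; i }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(nmax), find, integer(1))
  root <- match(root, sort(unique(root)))
  labels[labels > 0L] <- root[labels[labels > 0L]]
  labels
}

#' Ellipse fit of a labelled region from second central moments
#'
#' Semi-axes are derived from the eigenvalues of the pixel-coordinate
#' covariance so that a solid disc of radius r returns a = b = r
#' (for a solid ellipse the variance along a principal axis is a^2/4).
#' `a >= b` is enforced by ordering; the orientation is the major-axis
#' angle in radians measured from the column (x) axis, in `[0, pi)`.
#'
#' @param labels Integer label matrix (from [segment_nodules()]).
#' @param label Region id to fit (must exist with >= 5 pixels).
#' @param pixel_size Pixel size in um/px.
#' @return List with `a_um`, `b_um`, `orientation`.
#' @export
fit_ellipse <- function(labels, label, pixel_size = 1) {
  idx <- which(labels == label, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("label ", label, " not found", call. = FALSE)
  if (nrow(idx) < 5L) {
    stop("degenerate region: label ", label, " has fewer than 5 pixels",
         call. = FALSE)
  }
  n <- nrow(idx)
  C <- stats::cov(idx) * (n - 1) / n  # population central moments
  e <- eigen(C, symmetric = TRUE)
  ax <- 2 * sqrt(pmax(e$values, 0)) * pixel_size
  v <- e$vectors[, 1]                 # (row, col) components, major axis
  th <- atan2(v[1], v[2]) %% pi
  list(a_um = ax[1], b_um = ax[2], orientation = th)
}

#' Ellipsoid volume estimate of a nodule
#'
#' A nodule with in-plane semi-major axis `a` and semi-minor axis `b` is
#' modelled as a prolate ellipsoid of revolution about the major axis:
#' \eqn{V = \frac{4}{3}\pi a b^2}.
#'
#' @param a_um Semi-major axis (um), `>= b_um`.
#' @param b_um Semi-minor axis (um), `> 0`.
#' @return Volume in um^3.
#' @examples
#' ellipsoid_volume(3, 2) # 16*pi
#' @export
ellipsoid_volume <- function(a_um, b_um) {
  if (any(b_um <= 0) || any(a_um < b_um)) {
    stop("require a_um >= b_um > 0", call. = FALSE)
  }
  (4 / 3) * pi * a_um * b_um^2
}

#' Morphometry records for every nodule in a frame
#'
#' Combines pixel area, the moment-based ellipse fit and the ellipsoid
#' volume for each labelled object. Objects whose ellipse fit fails
#' (degenerate regions) are skipped with a warning.
#'
#' @param image Intensity frame (unused by the geometric measures; kept so
#'   intensity summaries can be added per record), may be `NULL`.
#' @param masks A `mask_pair` from [segment_nodules()].
#' @param pixel_size Pixel size in um/px.
#' @return Data frame (one row per label, sorted by label): `label`,
#'   `area_um2`, `a_um`, `b_um`, `volume_um3`, `centroid_row`,
#'   `centroid_col`, `orientation`.
#' @export
measure_frame <- function(image, masks, pixel_size) {
  stopifnot(inherits(masks, "mask_pair"))
  labels <- masks$labels
  ids <- sort(unique(labels[labels > 0L]))
  rows <- lapply(ids, function(id) {
    idx <- which(labels == id, arr.ind = TRUE)
    fe <- tryCatch(fit_ellipse(labels, id, pixel_size),
                   error = function(e) {
                     warning("skipping label ", id, ": ",
                             conditionMessage(e), call. = FALSE)
                     NULL
                   })
    if (is.null(fe)) return(NULL)
    data.frame(label = id,
               area_um2 = nrow(idx) * pixel_size^2,
               a_um = fe$a_um, b_um = fe$b_um,
               volume_um3 = ellipsoid_volume(fe$a_um, fe$b_um),
               centroid_row = mean(idx[, 1]) - 1,
               centroid_col = mean(idx[, 2]) - 1,
               orientation = fe$orientation)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(label = integer(0), area_um2 = numeric(0),
                      a_um = numeric(0), b_um = numeric(0),
                      volume_um3 = numeric(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), orientation = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
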