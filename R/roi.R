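#' Construct a set of regions of interest
#'
#' ROIs are stored as an H x W integer label map (0 = background, 1..k =
#' ROIs) plus a role per label. Roles follow the three-site recording
#' layout: `stim_site` (ROI-1, at the stimulation electrode in L4),
#' `same_column` (ROI-2, L2/3 of the input column) and `adjacent_column`
#' (ROI-3, L2/3 of the neighbouring column). Exactly one ROI must carry
#' the `stim_site` role.
#'
#' @param label_map Integer H x W matrix of labels.
#' @param roles Character vector naming the role of each label, names =
#'   label numbers, values in `stim_site`, `same_column`, `adjacent_column`.
#' @return An object of class `roi_set` with fields `label_map`, `roles`
#'   and `pixel_counts`.
#' @export
roi_set <- function(label_map, roles) {
  if (!is.matrix(label_map)) stop("label_map must be a matrix", call. = FALSE)
  storage.mode(label_map) <- "integer"
  labels <- sort(unique(label_map[label_map > 0L]))
  if (length(labels) == 0L) stop("no ROI labels present", call. = FALSE)
  roles <- unlist(roles)
  if (is.null(names(roles))) names(roles) <- as.character(labels)
  missing <- setdiff(as.character(labels), names(roles))
  if (length(missing)) {
    stop("role missing for ROI label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  allowed <- c("stim_site", "same_column", "adjacent_column")
  if (!all(roles %in% allowed)) {
    stop("roles must be one of: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  }
  if (sum(roles[as.character(labels)] == "stim_site") != 1L) {
    stop("exactly one ROI must carry the stim_site role", call. = FALSE)
  }
  counts <- vapply(labels, function(l) sum(label_map == l), 0L)
  names(counts) <- as.character(labels)
  structure(
    list(label_map = label_map, roles = roles[as.character(labels)],
         pixel_counts = counts),
    class = "roi_set"
  )
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %dx%d map, %d ROI(s)\n",
              nrow(x$label_map), ncol(x$label_map), length(x$pixel_counts)))
  for (l in names(x$pixel_counts)) {
    cat(sprintf("  ROI %s: %d px (%s)\n", l, x$pixel_counts[[l]],
                x$roles[[l]]))
  }
  invisible(x)
}

#' Label of the ROI holding a given role
#'
#' @param rois A [roi_set()].
#' @param role One of `"stim_site"`, `"same_column"`, `"adjacent_column"`.
#' @return Integer label.
#' @export
roi_label_for_role <- function(rois, role) {
  stopifnot(inherits(rois, "roi_set"))
  hit <- names(rois$roles)[rois$roles == role]
  if (length(hit) != 1L) stop("no unique ROI with role ", role, call. = FALSE)
  as.integer(hit)
}

# Pixel mask (H x W logical) of the n pixels nearest a centre.
# Ties in distance are broken by row-major order, so counts are exact —
# this is how the 57-px and 37-px analysis apertures are built.
disc_mask <- function(shape, center, n_pixels) {
  h <- shape[1]; w <- shape[2]
  rr <- matrix(rep(seq_len(h), w), h, w)
  cc <- matrix(rep(seq_len(w), each = h), h, w)
  d2 <- (rr - center[1])^2 + (cc - center[2])^2
  ord <- order(d2, rr, cc)
  if (n_pixels > h * w) stop("ROI larger than frame", call. = FALSE)
  mask <- matrix(FALSE, h, w)
  mask[ord[seq_len(n_pixels)]] <- TRUE
  mask
}

#' Build the standard three-ROI layout
#'
#' Creates compact, fixed-pixel-count apertures (nearest-n-pixel discs) at
#' the stimulation site and at the two remote recording sites.
#'
#' @param shape `c(H, W)` of the movie frames.
#' @param centers List with elements `stim_site`, `same_column`,
#'   `adjacent_column`, each `c(row, col)` (1-based).
#' @param n_pixels Pixels per ROI (57 for the summation branch, 37 for the
#'   propagation branch).
#' @return A [roi_set()] with labels 1, 2, 3 in the role order above.
#' @export
standard_rois <- function(shape, centers, n_pixels = 37) {
  stopifnot(all(c("stim_site", "same_column", "adjacent_column") %in%
                  names(centers)))
  lm <- matrix(0L, shape[1], shape[2])
  order_roles <- c("stim_site", "same_column", "adjacent_column")
  for (i in seq_along(order_roles)) {
    m <- disc_mask(shape, centers[[order_roles[i]]], n_pixels)
    if (any(lm[m] != 0L)) stop("ROIs overlap at this geometry", call. = FALSE)
    lm[m] <- i
  }
  roi_set(lm, stats::setNames(order_roles, as.character(1:3)))
}

# Even-odd point-in-polygon on pixel centres. Vertices are 0-based
# (row, col); the centre of pixel (r, c) (0-based) sits at (r+0.5, c+0.5).
polygon_mask <- function(vertices, shape) {
  vy <- vertices[, 1]; vx <- vertices[, 2]
  h <- shape[1]; w <- shape[2]
  mask <- matrix(FALSE, h, w)
  n <- length(vy)
  for (r in seq_len(h)) {
    py <- r - 0.5
    for (c in seq_len(w)) {
      px <- c - 0.5
      inside <- FALSE
      j <- n
      for (i in seq_len(n)) {
        if ((vy[i] > py) != (vy[j] > py)) {
          xcross <- vx[j] + (py - vy[j]) / (vy[i] - vy[j]) * (vx[i] - vx[j])
          if (px < xcross) inside <- !inside
        }
        j <- i
      }
      if (inside) mask[r, c] <- TRUE
    }
  }
  mask
}

#' Read ROIs from a label image or polygon JSON
#'
#' Two on-disk forms are supported: a PNG label image (gray levels are
#' labels) or a JSON file with `rois: [{label, role, polygon: [[r,c],...]},
#' ...]` using 0-based (row, col) vertices; polygons are rasterized with
#' the pixel-center-inside (even-odd) rule. Roles may alternatively be
#' supplied via `roles` for label images.
#'
#' @param path File path (`.png` or `.json`).
#' @param shape `c(H, W)` the map must match.
#' @param roles Named character vector of roles per label (label images).
#' @return A [roi_set()].
#' @export
read_roiset <- function(path, shape, roles = NULL) {
  if (!file.exists(path)) stop("ROI file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    spec <- jsonlite::read_json(path, simplifyVector = TRUE)
    lm <- matrix(0L, shape[1], shape[2])
    roles <- character()
    rois <- spec$rois
    for (i in seq_len(nrow(rois))) {
      poly <- rois$polygon[[i]]
      if (is.list(poly)) poly <- do.call(rbind, poly)
      poly <- matrix(as.numeric(poly), ncol = 2)
      m <- polygon_mask(poly, shape)
      if (!any(m)) stop("empty ROI after rasterization", call. = FALSE)
      lab <- as.integer(rois$label[i])
      if (any(lm[m] != 0L)) stop("overlapping ROI labels", call. = FALSE)
      lm[m] <- lab
      roles[as.character(lab)] <- rois$role[i]
    }
    roi_set(lm, roles)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG label images requires the png package", call. = FALSE)
    }
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    lm <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
    if (!all(dim(lm) == shape)) stop("ROI/movie shape mismatch", call. = FALSE)
    if (is.null(roles)) stop("roles must be supplied for label images",
                             call. = FALSE)
    roi_set(lm, roles)
  } else {
    stop("unsupported ROI format: ", ext, call. = FALSE)
  }
}
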