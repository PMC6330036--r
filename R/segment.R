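# Segmentation: bone vs background by density threshold, then a
# cortical/cancellous split by a boundary-connected high-density shell.
# These emulate an automatic recognition step plus replayable manual
# corrections; the shell rule is an explicit stand-in for the (unpublished)
# vendor algorithm, tuned only through its two thresholds.

# logical OR of the 8-neighbourhood, treating pixels beyond the image border
# as `border` (TRUE when used to seed from the image edge)
neighbor_any <- function(m, border = FALSE) {
  nr <- nrow(m)
  nc <- ncol(m)
  pad <- matrix(border, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- matrix(FALSE, nr, nc)
  for (di in -1:1) {
    for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      out <- out | pad[(2:(nr + 1L)) + di, (2:(nc + 1L)) + dj]
    }
  }
  out
}

#' Segment bone pixels in a density map
#'
#' A pixel is bone iff its density is at least `bone_threshold`; of the
#' resulting connected components only the largest is kept (smaller ones are
#' presumed neighbouring structures or noise). If no pixel reaches the
#' threshold, an all-zero mask is returned with attribute `excluded = TRUE`
#' so the slice can be dropped downstream.
#'
#' @param slice density matrix, mg/cm^3.
#' @param bone_threshold soft-tissue/bone cutoff, mg/cm^3 (default 160, a
#'   conventional in-vivo CT magnitude).
#' @return integer matrix (0 background, 1 bone), possibly with attribute
#'   `excluded`.
#' @export
segment_bone <- function(slice, bone_threshold = 160) {
  stopifnot(is.matrix(slice), bone_threshold > 0)
  bin <- slice >= bone_threshold
  if (!any(bin)) {
    out <- matrix(0L, nrow(slice), ncol(slice))
    attr(out, "excluded") <- TRUE
    return(out)
  }
  lab <- EBImage::bwlabel(bin * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  out <- matrix(0L, nrow(slice), ncol(slice))
  out[lab == keep] <- 1L
  out
}

# TRUE if any cancellous pixel can reach the image border without crossing
# the cortical shell (4-connected flood over non-blocking pixels). When an
# eligibility map is supplied, only cortical pixels at or above the shell
# density block the flood: the boundary-seeded skirt alone cannot close a
# ring whose high-density shell has a gap.
ring_is_broken <- function(label_map, eligible = NULL) {
  if (!any(label_map == 2L)) return(FALSE)
  blocking <- label_map == 1L
  if (!is.null(eligible)) blocking <- blocking & eligible
  open_map <- (!blocking) * 1
  comp <- EBImage::bwlabel(open_map)
  border_ids <- unique(c(comp[1, ], comp[nrow(comp), ],
                         comp[, 1], comp[, ncol(comp)]))
  border_ids <- border_ids[border_ids > 0]
  any(comp[label_map == 2L] %in% border_ids)
}

#' Classify bone pixels as cortical shell or cancellous interior
#'
#' The cortical compartment is grown from the bone pixels that touch the
#' background (the periosteal boundary): first through any bone for
#' `skirt_px` pixels (the partial-volume transition of the outer edge, whose
#' blurred densities dip below the shell threshold), then through bone
#' pixels whose density is at least `cortical_threshold`, up to a geodesic
#' depth of `max_shell_depth` pixels; the remaining bone pixels are
#' cancellous. On an intact vertebral cross-section the high-density shell
#' forms a single closed ring; if that ring does not enclose the cancellous
#' pixels the result carries attribute `ring_broken = TRUE`, with a warning.
#'
#' @param mask binary bone mask from [segment_bone()].
#' @param slice the density matrix the mask belongs to.
#' @param cortical_threshold minimum density for shell growth, mg/cm^3.
#' @param max_shell_depth maximum geodesic shell depth, pixels
#'   (default unlimited).
#' @param skirt_px periosteal transition depth grown through any bone,
#'   pixels (about two to three times the imaging blur sigma).
#' @return integer label matrix: 0 background, 1 cortical, 2 cancellous,
#'   with attribute `ring_broken` when enclosure fails.
#' @export
classify_cortical <- function(mask, slice, cortical_threshold = 500,
                              max_shell_depth = Inf, skirt_px = 2L) {
  stopifnot(is.matrix(mask), identical(dim(mask), dim(slice)))
  bone <- mask > 0
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (!any(bone)) return(out)
  eligible <- bone & slice >= cortical_threshold
  shell <- bone & neighbor_any(!bone, border = TRUE)
  frontier <- shell
  depth <- 0
  while (any(frontier) && depth < skirt_px) {
    nxt <- neighbor_any(frontier) & bone & !shell
    if (!any(nxt)) break
    shell <- shell | nxt
    frontier <- nxt
    depth <- depth + 1
  }
  frontier <- shell
  depth <- 0
  while (any(frontier) && depth < max_shell_depth) {
    nxt <- neighbor_any(frontier) & eligible & !shell
    if (!any(nxt)) break
    shell <- shell | nxt
    frontier <- nxt
    depth <- depth + 1
  }
  out[bone] <- 2L
  out[shell] <- 1L
  if (ring_is_broken(out, eligible)) {
    attr(out, "ring_broken") <- TRUE
    warning("cortical ring is broken: cancellous pixels reach the border")
  }
  out
}

#' Manual correction of a bone mask (replayable ROI edit)
#'
#' @param slice_index slice the edit applies to.
#' @param polygon two-column matrix of (x, y) pixel coordinates (column,
#'   row; vertices of the region to relabel).
#' @param label forced label: 0 background, 1 cortical, 2 cancellous.
#' @return an object of class `roi_edit`.
#' @export
roi_edit <- function(slice_index, polygon, label) {
  polygon <- matrix(as.numeric(polygon), ncol = 2L)
  stopifnot(nrow(polygon) >= 3L, label %in% 0:2, slice_index >= 1L)
  structure(list(slice_index = as.integer(slice_index), polygon = polygon,
                 label = as.integer(label)), class = "roi_edit")
}

#' Read ROI edits from a JSON file
#'
#' Format: `[{"slice": i, "polygon": [[x, y], ...], "label": l}, ...]`.
#'
#' @param path JSON file path.
#' @return list of [roi_edit()] objects.
#' @export
read_roi_edits <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(e) {
    roi_edit(e$slice, do.call(rbind, lapply(e$polygon, unlist)), e$label)
  })
}

# even-odd rule point-in-polygon, vectorized over points
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep.int(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Apply manual ROI corrections to per-slice label masks
#'
#' Edits are applied in the order given (later edits win on overlap): every
#' pixel whose centre falls inside the edit polygon receives the forced
#' label. Any out-of-bounds edit aborts the whole call, leaving the masks
#' unchanged. Enclosure of the cancellous compartment is re-validated per
#' edited slice; violations set the `ring_broken` attribute with a warning.
#'
#' @param masks list of label matrices (one per slice), as from
#'   [classify_cortical()].
#' @param edits list of [roi_edit()] objects (may be empty).
#' @return the edited list of masks.
#' @export
apply_edits <- function(masks, edits) {
  stopifnot(is.list(masks))
  if (length(edits) == 0L) return(masks)
  if (inherits(edits, "roi_edit")) edits <- list(edits)
  nr <- nrow(masks[[1L]])
  nc <- ncol(masks[[1L]])
  for (e in edits) {
    if (!inherits(e, "roi_edit")) stop("edits must be roi_edit objects")
    if (e$slice_index > length(masks)) {
      stop("edit references slice ", e$slice_index, " of ", length(masks))
    }
    if (any(e$polygon[, 1] < 0) || any(e$polygon[, 1] > nc) ||
        any(e$polygon[, 2] < 0) || any(e$polygon[, 2] > nr)) {
      stop("edit polygon exceeds slice bounds (", nc, " x ", nr, " px)")
    }
  }
  touched <- integer(0)
  for (e in edits) {
    m <- masks[[e$slice_index]]
    cx <- rep(seq_len(nc) - 0.5, each = nr)
    cy <- rep(seq_len(nr) - 0.5, times = nc)
    sel <- point_in_polygon(cx, cy, e$polygon)
    m[matrix(sel, nr, nc)] <- e$label
    masks[[e$slice_index]] <- m
    touched <- union(touched, e$slice_index)
  }
  for (i in touched) {
    attr(masks[[i]], "ring_broken") <- NULL
    if (ring_is_broken(masks[[i]])) {
      attr(masks[[i]], "ring_broken") <- TRUE
      warning("edit broke the cortical ring on slice ", i)
    }
  }
  masks
}
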