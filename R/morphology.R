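#' Structuring element for morphological filtering
#'
#' A centered flat structuring element. Spans are in grid cells, must be odd
#' and >= 1 so the element has a well-defined center.
#'
#' @param lat_cells,lon_cells span in latitude / longitude grid cells.
#' @param shape `"rectangle"` (default) or `"disk"` (cells within the
#'   inscribed ellipse).
#' @return an object of class `structuring_element` (a 0/1 matrix with the
#'   shape recorded as an attribute).
#' @export
structuring_element <- function(lat_cells = 5L, lon_cells = 5L,
                                shape = c("rectangle", "disk")) {
  shape <- match.arg(shape)
  if (lat_cells < 1 || lon_cells < 1 ||
      lat_cells %% 2 == 0 || lon_cells %% 2 == 0)
    stop("structuring-element spans must be odd and >= 1")
  kern <- matrix(1, lat_cells, lon_cells)
  if (shape == "disk") {
    ci <- (lat_cells + 1) / 2; cj <- (lon_cells + 1) / 2
    ri <- max(ci - 1, 0.5); rj <- max(cj - 1, 0.5)
    d <- outer(seq_len(lat_cells), seq_len(lon_cells),
               function(i, j) ((i - ci) / ri)^2 + ((j - cj) / rj)^2)
    kern[d > 1 + 1e-9] <- 0
  }
  structure(kern, class = c("structuring_element", "matrix"),
            shape = shape)
}

# One grayscale dilation or erosion of a lat x lon matrix with the domain's
# boundary rule: periodic in longitude (columns), edge-replicated in latitude
# (rows). Replicating the edge row only duplicates values already inside the
# symmetric window, so this is exactly domain-clipped morphology, and the
# dilation/erosion pair remains an adjunction: closing and opening built from
# single passes are idempotent. EBImage's grayscale morphology assumes
# intensities in [0, 1]; flat-element dilation/erosion commute with monotone
# affine maps, so each pass rescales exactly and maps back.
.morph_once <- function(m, kern, op) {
  pr <- (nrow(kern) - 1L) %/% 2L
  pc <- (ncol(kern) - 1L) %/% 2L
  nr <- nrow(m); nl <- ncol(m)
  if (pc > 0) {
    wrap <- function(i) ((i - 1L) %% nl) + 1L
    m <- cbind(m[, wrap((nl - pc + 1L):nl), drop = FALSE], m,
               m[, wrap(1:pc), drop = FALSE])
  }
  if (pr > 0) {
    m <- rbind(matrix(rep(m[1, ], each = pr), pr),
               m,
               matrix(rep(m[nrow(m), ], each = pr), pr))
  }
  lo <- min(m); hi <- max(m)
  if (hi > lo) m <- (m - lo) / (hi - lo) else m[] <- 0
  f <- if (op == "dilate") EBImage::dilate(m, kern) else EBImage::erode(m, kern)
  if (hi > lo) f <- f * (hi - lo) + lo else f[] <- lo
  f[(pr + 1L):(pr + nr), (pc + 1L):(pc + nl)]
}

.morph_apply <- function(field, elem, op) {
  stopifnot(inherits(field, "gridded_field"),
            inherits(elem, "structuring_element"))
  if (anyNA(field$values))
    stop("missing values inside the detection domain; morphology needs a complete field")
  kr <- nrow(elem); kc <- ncol(elem)
  d <- dim(field$values)
  if (kr > d[1] || kc > d[2])
    stop("structuring element larger than the field domain")
  kern <- unclass(elem); attributes(kern) <- list(dim = dim(elem))
  out <- field
  for (t in seq_len(d[3])) {
    m <- field$values[, , t]
    out$values[, , t] <- if (op == "close")
      .morph_once(.morph_once(m, kern, "dilate"), kern, "erode")
    else
      .morph_once(.morph_once(m, kern, "erode"), kern, "dilate")
  }
  out
}

#' Grayscale morphological closing of a gridded field
#'
#' Dilation followed by erosion with a flat structuring element, applied to
#' the wind values directly (no binarisation). Fills narrow low-speed gaps
#' inside high-speed channels and so sharpens the jet-core structure before
#' axis extraction. Longitude is treated as periodic; latitude edges are
#' replicated.
#'
#' @param field a [gridded_field()] without missing values.
#' @param elem a [structuring_element()].
#' @return the closed [gridded_field()]; pointwise `>=` the input, and
#'   idempotent.
#' @export
morph_close <- function(field, elem = structuring_element()) {
  .morph_apply(field, elem, "close")
}

#' Grayscale morphological opening of a gridded field
#'
#' Erosion followed by dilation; removes isolated high-wind anomalies smaller
#' than the structuring element while leaving the broad jet untouched.
#' Pointwise `<=` the input, and idempotent.
#'
#' @inheritParams morph_close
#' @return the opened [gridded_field()].
#' @export
morph_open <- function(field, elem = structuring_element()) {
  .morph_apply(field, elem, "open")
}
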