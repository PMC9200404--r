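#' Build an electrode montage
#'
#' A montage holds ordered electrode labels, unit-sphere 3D positions and a
#' symmetric, irreflexive neighbourhood relation used for spatial clustering.
#' Electrodes are declared neighbours when the great-circle (angular) distance
#' between their idealized scalp positions is at or below a threshold.
#'
#' @param layout Name of a bundled layout. `"biosemi64"` is the 64-channel
#'   Biosemi/10-05 cap (labels such as `"PO7"`, `"O1"`, `"O2"`, `"PO8"`).
#'   Ignored when `positions` is supplied.
#' @param positions Optional data frame with columns `label`, `x`, `y`, `z`
#'   giving electrode positions. Positions are projected onto the unit sphere.
#' @param adjacency_threshold Great-circle distance (radians) at or below
#'   which two electrodes count as neighbours. The default 0.63 gives a
#'   median neighbour count of 8 on the bundled 64-channel layout and makes
#'   the canonical bilateral posterior cluster (PO7/O1/O2/PO8) spatially
#'   connected across the midline.
#' @return An object of class `spn_montage` with elements `labels`
#'   (character), `positions` (numeric matrix, one row per label, unit norm)
#'   and `neighbours` (two-column character matrix, one row per unordered
#'   neighbour pair).
#' @examples
#' m <- build_montage("biosemi64")
#' montage_adjacent(m, "PO7", "O1")
#' @export
build_montage <- function(layout = "biosemi64", positions = NULL,
                          adjacency_threshold = 0.63) {
  if (is.null(positions)) {
    if (!identical(layout, "biosemi64")) {
      stop("unknown layout '", layout, "'; bundled layouts: 'biosemi64'")
    }
    path <- system.file("extdata", "biosemi64_sphere.tsv", package = "spnmeta")
    positions <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  positions <- as.data.frame(positions)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(positions))) {
    stop("positions must have columns label, x, y, z")
  }
  labels <- as.character(positions$label)
  if (anyDuplicated(labels)) {
    stop("duplicate electrode labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (length(labels) < 2L) stop("a montage needs at least 2 electrodes")
  pos <- as.matrix(positions[, c("x", "y", "z")])
  storage.mode(pos) <- "double"
  if (any(!is.finite(pos))) stop("non-finite electrode coordinates")
  nrm <- sqrt(rowSums(pos^2))
  if (any(nrm == 0)) stop("zero-length position vector")
  pos <- pos / nrm
  pos[abs(pos) < 1e-12] <- 0  # avoid -0 / denormal jitter in serialization
  rownames(pos) <- labels

  # pairwise great-circle distance on the unit sphere
  cosang <- tcrossprod(pos)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  ang <- acos(cosang)
  adj <- ang <= adjacency_threshold
  diag(adj) <- FALSE
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  neighbours <- cbind(labels[idx[, 1L]], labels[idx[, 2L]])
  colnames(neighbours) <- c("a", "b")

  m <- structure(
    list(labels = labels, positions = pos, neighbours = neighbours,
         adjacency_threshold = adjacency_threshold),
    class = "spn_montage")
  validate_montage(m)
  m
}

#' Validate a montage object
#'
#' Checks label uniqueness, unit-norm positions, and that the neighbour
#' relation is symmetric, irreflexive and closed over the known labels.
#'
#' @param m An `spn_montage`.
#' @return `m`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_montage <- function(m) {
  stopifnot(inherits(m, "spn_montage"))
  if (anyDuplicated(m$labels)) stop("montage labels are not unique")
  if (!all(m$neighbours %in% m$labels)) {
    stop("neighbour pair references unknown electrode label")
  }
  if (any(m$neighbours[, 1L] == m$neighbours[, 2L])) {
    stop("montage adjacency must be irreflexive")
  }
  nrm <- sqrt(rowSums(m$positions^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("electrode positions must have unit norm")
  invisible(m)
}

#' Adjacency matrix of a montage
#'
#' @param m An `spn_montage`.
#' @return Symmetric logical matrix with `FALSE` diagonal, dimnames the
#'   montage labels.
#' @export
montage_adjacency <- function(m) {
  n <- length(m$labels)
  A <- matrix(FALSE, n, n, dimnames = list(m$labels, m$labels))
  if (nrow(m$neighbours)) {
    i <- match(m$neighbours[, 1L], m$labels)
    j <- match(m$neighbours[, 2L], m$labels)
    A[cbind(i, j)] <- TRUE
    A[cbind(j, i)] <- TRUE
  }
  A
}

#' Are two electrodes neighbours?
#'
#' @param m An `spn_montage`.
#' @param a,b Electrode labels.
#' @return Logical scalar.
#' @export
montage_adjacent <- function(m, a, b) {
  if (!all(c(a, b) %in% m$labels)) stop("unknown electrode label")
  any((m$neighbours[, 1L] == a & m$neighbours[, 2L] == b) |
      (m$neighbours[, 1L] == b & m$neighbours[, 2L] == a))
}

#' @export
print.spn_montage <- function(x, ...) {
  cnt <- table(factor(c(x$neighbours[, 1L], x$neighbours[, 2L]),
                      levels = x$labels))
  cat("<spn_montage> ", length(x$labels), " electrodes, ",
      nrow(x$neighbours), " neighbour pairs (median degree ",
      stats::median(cnt), ")\n", sep = "")
  invisible(x)
}
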