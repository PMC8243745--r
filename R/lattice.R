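#' Toroidal square-lattice specification
#'
#' Describes a 2-D lattice of square cells with periodic (toroidal) boundary
#' conditions. Cells are addressed by 1-based `(row, col)` pairs; fields over
#' the lattice are stored as `height x width` numeric matrices.
#'
#' @param width Number of columns (positive integer, at least 3).
#' @param height Number of rows (positive integer, at least 3). Defaults to
#'   `width`.
#' @return An object of class `lattice_spec` with elements `width` and
#'   `height`.
#' @examples
#' lattice_spec(20, 20)
#' @export
lattice_spec <- function(width = 20L, height = width) {
  width <- as.integer(width)
  height <- as.integer(height)
  if (is.na(width) || is.na(height) || width < 3L || height < 3L) {
    stop("lattice dimensions must be integers >= 3 so that a cell and its ",
         "four neighbors are distinct", call. = FALSE)
  }
  structure(list(width = width, height = height), class = "lattice_spec")
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("<lattice_spec> %d x %d torus (%d cells)\n",
              x$height, x$width, x$height * x$width))
  invisible(x)
}

#' Number of cells on a lattice
#' @param lattice A [lattice_spec()].
#' @return Integer cell count.
#' @export
n_cells <- function(lattice) lattice$height * lattice$width

#' Centre cell of a lattice
#'
#' The default placement for a single portal-vein cell. On a torus the
#' position is immaterial (translation equivariance); the centre is used for
#' readable plots.
#'
#' @param lattice A [lattice_spec()].
#' @return A 1x2 integer matrix `(row, col)`.
#' @export
lattice_center <- function(lattice) {
  cbind(row = ceiling(lattice$height / 2), col = ceiling(lattice$width / 2))
}

check_cells <- function(cells, lattice) {
  cells <- as.matrix(cells)
  if (ncol(cells) != 2L) stop("cells must be a two-column (row, col) matrix",
                              call. = FALSE)
  storage.mode(cells) <- "integer"
  bad <- cells[, 1L] < 1L | cells[, 1L] > lattice$height |
    cells[, 2L] < 1L | cells[, 2L] > lattice$width
  if (any(bad)) {
    stop(sprintf("cell index out of range for %d x %d lattice: (%d, %d)",
                 lattice$height, lattice$width,
                 cells[which(bad)[1L], 1L], cells[which(bad)[1L], 2L]),
         call. = FALSE)
  }
  cells
}

#' Von Neumann neighbors of a cell
#'
#' The four orthogonally adjacent cells (up, down, left, right) with toroidal
#' wraparound.
#'
#' @param cell A length-2 vector or 1x2 matrix `(row, col)`, 1-based.
#' @param lattice A [lattice_spec()].
#' @return A 4x2 integer matrix with columns `row`, `col`; rows are the up,
#'   down, left and right neighbors in that order.
#' @examples
#' von_neumann_neighbors(c(1, 1), lattice_spec(20))
#' @export
von_neumann_neighbors <- function(cell, lattice) {
  cell <- check_cells(matrix(as.integer(cell), ncol = 2L), lattice)
  r <- cell[1L, 1L]
  co <- cell[1L, 2L]
  h <- lattice$height
  w <- lattice$width
  wrap <- function(i, n) ((i - 1L) %% n) + 1L
  out <- cbind(
    row = c(wrap(r - 1L, h), wrap(r + 1L, h), r, r),
    col = c(co, co, wrap(co - 1L, w), wrap(co + 1L, w))
  )
  storage.mode(out) <- "integer"
  out
}

# Toroidal shift of a matrix: entry (r, c) of the result holds
# field[r + dr, c + dc] with wraparound.
shift_torus <- function(field, dr, dc) {
  nr <- nrow(field)
  nc <- ncol(field)
  field[((seq_len(nr) - 1L + dr) %% nr) + 1L,
        ((seq_len(nc) - 1L + dc) %% nc) + 1L, drop = FALSE]
}

#' Von Neumann neighbor average of a field
#'
#' For every cell, the arithmetic mean of the field over its four von Neumann
#' neighbors on the torus. This is the spatial coupling term of the LIMI
#' model: `<D_j>_i` and `<N_j>_i`.
#'
#' @param field A `height x width` numeric matrix.
#' @param lattice A [lattice_spec()] the field must match. If `NULL` the
#'   field's own dimensions are used.
#' @return A numeric matrix of the same shape.
#' @examples
#' f <- matrix(1, 4, 4)
#' neighbor_average(f)  # still all 1
#' @export
neighbor_average <- function(field, lattice = NULL) {
  if (!is.matrix(field) || !is.numeric(field)) {
    stop("field must be a numeric matrix", call. = FALSE)
  }
  if (!is.null(lattice) &&
      (nrow(field) != lattice$height || ncol(field) != lattice$width)) {
    stop(sprintf("field is %d x %d but lattice is %d x %d",
                 nrow(field), ncol(field), lattice$height, lattice$width),
         call. = FALSE)
  }
  if (nrow(field) < 3L || ncol(field) < 3L) {
    stop("field must be at least 3 x 3", call. = FALSE)
  }
  (shift_torus(field, -1L, 0L) + shift_torus(field, 1L, 0L) +
      shift_torus(field, 0L, -1L) + shift_torus(field, 0L, 1L)) / 4
}
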