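#' Build a periodic square lattice of locations
#'
#' Constructs an `L x L` torus of `M = L^2` locations.  Every location can
#' reach exactly five destinations at unit mobility cost: itself and its four
#' von Neumann neighbours (up, down, left, right), with wrap-around at the
#' edges.  All other pairs are unreachable (infinite cost), so mobility is
#' strictly local.
#'
#' Locations are indexed `1..M` in column-major order of an `L x L` matrix:
#' location `i` sits at `row = (i - 1) %% L + 1`, `col = (i - 1) %/% L + 1`.
#'
#' @param L side length of the lattice; must be at least 3 so that the four
#'   wrapped neighbours are distinct from each other and from the location
#'   itself.
#' @return An object of class `"lattice"`: a list with elements `L`, `M`, and
#'   `nbr`, an `M x 5` integer matrix of destination indices in the order
#'   self, up, down, left, right.  Each column of `nbr` is a permutation of
#'   `1:M` (a torus shift).
#' @examples
#' lat <- build_lattice(5)
#' neighbours(lat, 1)
#' @export
build_lattice <- function(L) {
  if (!is.numeric(L) || length(L) != 1 || is.na(L) || L != round(L)) {
    stop("`L` must be a single integer", call. = FALSE)
  }
  if (L < 3) {
    stop("`L` must be at least 3: wrap-around is degenerate below that",
         call. = FALSE)
  }
  L <- as.integer(L)
  M <- L * L
  i <- seq_len(M)
  row0 <- (i - 1L) %% L      # 0-based row
  col0 <- (i - 1L) %/% L     # 0-based col
  idx <- function(r, c) ((c %% L)) * L + ((r %% L)) + 1L
  nbr <- cbind(
    self  = i,
    up    = idx(row0 - 1L, col0),
    down  = idx(row0 + 1L, col0),
    left  = idx(row0, col0 - 1L),
    right = idx(row0, col0 + 1L)
  )
  structure(list(L = L, M = M, nbr = nbr), class = "lattice")
}

#' Reachable destinations of a location
#'
#' @param lattice a [build_lattice()] object.
#' @param i location index in `1..M`.
#' @return Integer vector of the five reachable destination indices
#'   (self, up, down, left, right).
#' @export
neighbours <- function(lattice, i) {
  stopifnot(inherits(lattice, "lattice"))
  if (any(i < 1 | i > lattice$M)) stop("location index out of range", call. = FALSE)
  lattice$nbr[i, , drop = TRUE]
}

#' @export
print.lattice <- function(x, ...) {
  cat(sprintf("<lattice> %d x %d torus, %d locations, 5 reachable destinations each\n",
              x$L, x$L, x$M))
  invisible(x)
}

# location index <-> (row, col) helpers (column-major, 1-based)
loc_index <- function(row, col, L) (col - 1L) * L + row
loc_rowcol <- function(i, L) cbind(row = (i - 1L) %% L + 1L, col = (i - 1L) %/% L + 1L)
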