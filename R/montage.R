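#' Electrode montage layouts
#'
#' @description
#' `build_layout()` returns one of the montage layouts shipped with the
#' package, or loads a user-supplied layout from a JSON file mapping channel
#' names to integer `[row, col]` grid cells. The default `"bci2a"` layout is
#' the 22-channel motor-imagery montage: a 2-D grid of 10-20 channel
#' positions in which, for example, `Cz` sits at cell `(2, 3)` surrounded by
#' its eight grid neighbours (`FCz`, `CPz`, `C1`, `C2`, `FC1`, `FC2`, `CP1`,
#' `CP2`).
#'
#' A layout is the geometric substrate for the structural connectivity graph:
#' two electrodes are considered structurally connected when their grid cells
#' are vertical, horizontal or diagonal neighbours (Chebyshev distance 1).
#'
#' @param montage_name name of a packaged montage (currently `"bci2a"`), or
#'   the path to a JSON layout file with fields `name` and `grid`.
#' @return An object of class `electrode_layout`: a list with `name`,
#'   `channels` (ordered channel names) and `grid` (an `n x 2` integer matrix
#'   of `(row, col)` cells with channel rownames).
#' @examples
#' lay <- build_layout("bci2a")
#' lay$grid["Cz", ]
#' @seealso [build_adjacency()], [normalize_adjacency()]
#' @export
build_layout <- function(montage_name = "bci2a") {
  stopifnot(is.character(montage_name), length(montage_name) == 1L)
  packaged <- c("bci2a")
  if (montage_name %in% packaged) {
    path <- system.file("extdata", paste0("montage_", montage_name, ".json"),
                        package = "graphmi", mustWork = TRUE)
  } else if (file.exists(montage_name)) {
    path <- montage_name
  } else {
    stop("unknown montage '", montage_name, "'; available packaged montages: ",
         paste(packaged, collapse = ", "),
         " (or pass the path to a layout JSON file)", call. = FALSE)
  }
  spec <- jsonlite::read_json(path)
  grid <- t(vapply(spec$grid, function(p) as.integer(unlist(p)), integer(2)))
  colnames(grid) <- c("row", "col")
  layout <- structure(
    list(name = spec$name %||% montage_name,
         channels = rownames(grid),
         grid = grid),
    class = "electrode_layout")
  validate_layout(layout)
  layout
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_layout <- function(layout) {
  ch <- layout$channels
  if (anyDuplicated(ch)) stop("duplicate channel names in layout", call. = FALSE)
  cells <- paste(layout$grid[, 1], layout$grid[, 2])
  if (anyDuplicated(cells)) stop("two channels share a grid cell", call. = FALSE)
  invisible(layout)
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat("<electrode_layout> '", x$name, "': ", length(x$channels),
      " channels on a ", max(x$grid[, 1]) + 1L, "x", max(x$grid[, 2]) + 1L,
      " grid\n", sep = "")
  invisible(x)
}

#' Structural adjacency graph of an electrode layout
#'
#' @description
#' Builds the structural connectivity graph over a montage: channels are
#' nodes and an (undirected, unweighted) edge joins every pair of channels
#' whose grid cells are at Chebyshev distance 1 — vertical, horizontal and
#' diagonal neighbours. Boundary channels simply have fewer neighbours.
#' Each node is additionally connected to itself through the `A + I` term of
#' the spectral normalization (see [normalize_adjacency()]).
#'
#' @param layout an `electrode_layout`, see [build_layout()].
#' @return An object of class `structural_graph`: a list with
#'   \describe{
#'     \item{`A`}{binary symmetric adjacency matrix, zero diagonal;}
#'     \item{`A_tilde`}{`A + I`, the self-loop-augmented adjacency;}
#'     \item{`D_tilde`}{diagonal degree matrix of `A_tilde`;}
#'     \item{`A_hat`}{the normalized matrix
#'       `D_tilde^(-1/2) A_tilde D_tilde^(-1/2)`;}
#'     \item{`layout`}{the layout the graph was built from.}
#'   }
#'   All matrices carry channel names as dimnames.
#' @examples
#' g <- build_adjacency(build_layout("bci2a"))
#' names(which(g$A["Cz", ] == 1))   # the eight neighbours of Cz
#' g$A_hat["Cz", "Cz"]              # 1/9: Cz has degree 9 in A + I
#' @export
build_adjacency <- function(layout) {
  stopifnot(inherits(layout, "electrode_layout"))
  g <- layout$grid
  n <- nrow(g)
  dr <- abs(outer(g[, 1], g[, 1], "-"))
  dc <- abs(outer(g[, 2], g[, 2], "-"))
  A <- (pmax(dr, dc) == 1) * 1
  dimnames(A) <- list(layout$channels, layout$channels)
  A_hat <- normalize_adjacency(A)
  A_tilde <- A + diag(n)
  D_tilde <- diag(rowSums(A_tilde))
  dimnames(A_tilde) <- dimnames(A)
  dimnames(D_tilde) <- dimnames(A)
  structure(
    list(A = A, A_tilde = A_tilde, D_tilde = D_tilde, A_hat = A_hat,
         layout = layout),
    class = "structural_graph")
}

#' @export
print.structural_graph <- function(x, ...) {
  cat("<structural_graph> ", nrow(x$A), " nodes, ", sum(x$A) / 2,
      " edges (plus self-loops in A_tilde)\n", sep = "")
  invisible(x)
}

#' Grid neighbours of a channel
#'
#' @param graph a `structural_graph`.
#' @param channel channel name.
#' @return Character vector of the channels adjacent to `channel`.
#' @export
graph_neighbors <- function(graph, channel) {
  stopifnot(inherits(graph, "structural_graph"))
  if (!channel %in% rownames(graph$A))
    stop("unknown channel '", channel, "'", call. = FALSE)
  names(which(graph$A[channel, ] == 1))
}

#' Spectral normalization of a binary adjacency matrix
#'
#' @description
#' Computes the symmetrically normalized adjacency
#' \deqn{\hat A = \tilde D^{-1/2} (A + I) \tilde D^{-1/2}}
#' where \eqn{\tilde D} is the diagonal degree matrix of \eqn{\tilde A = A + I}.
#' This is the propagation operator of spectral graph convolutions: entry
#' \eqn{[i,j]} equals \eqn{\tilde A_{ij} / \sqrt{\tilde D_{ii}\tilde D_{jj}}},
#' the matrix is symmetric, its eigenvalues lie in \eqn{[-1, 1]}, and the
#' vector with entries \eqn{\sqrt{\tilde D_{ii}}} is a fixed point
#' (eigenvalue 1). Multiplying a channels-by-samples trial by \eqn{\hat A}
#' replaces every channel with a degree-weighted average of itself and its
#' grid neighbours.
#'
#' @param A square binary symmetric matrix with zero diagonal.
#' @return The normalized matrix, same dimnames as `A`.
#' @export
normalize_adjacency <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("adjacency matrix must be square", call. = FALSE)
  if (!isTRUE(all.equal(A, t(A)))) stop("adjacency matrix must be symmetric", call. = FALSE)
  if (!all(A %in% c(0, 1))) stop("adjacency entries must be 0/1", call. = FALSE)
  if (any(diag(A) != 0)) stop("adjacency diagonal must be zero (self-loops are added internally)", call. = FALSE)
  A_tilde <- A + diag(nrow(A))
  d <- rowSums(A_tilde)
  inv_sqrt <- 1 / sqrt(d)
  A_hat <- A_tilde * tcrossprod(inv_sqrt)
  dimnames(A_hat) <- dimnames(A)
  A_hat
}

#' Write a channel-by-channel matrix as CSV with name headers
#'
#' @param m square matrix with channel dimnames (adjacency, normalized
#'   adjacency, or a PLV matrix).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
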