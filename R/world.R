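#' Bounded 3D lattice world
#'
#' The world is a bounded integer lattice; each site holds at most one cell
#' and an extracellular-matrix (ECM) density in `[0, 1]`.  One site
#' corresponds to 5 micrometres.  All coordinates in this package are 0-based
#' integer triples `(x, y, z)` with `0 <= x < dims[1]` etc., matching the
#' coordinate convention of every exported file format.
#'
#' @param dims integer vector of three positive lattice dimensions.
#' @return An object of class `"tumor_world"`: a list with `dims`, an
#'   occupancy environment, and a 3D `ecm` array initialised to 1.
#' @examples
#' w <- new_world(c(10, 10, 10))
#' w$dims
#' @export
new_world <- function(dims) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L))
  structure(
    list(dims = dims,
         occupancy = new.env(parent = emptyenv()),
         ecm = array(1, dim = dims)),
    class = "tumor_world")
}

pos_key <- function(pos) paste(pos, collapse = ",")

assert_in_bounds <- function(pos, dims) {
  pos <- as.integer(pos)
  if (length(pos) != 3L || anyNA(pos) || any(pos < 0L) || any(pos >= dims)) {
    stop("position (", paste(pos, collapse = ", "),
         ") is outside the ", paste(dims, collapse = "x"), " world",
         call. = FALSE)
  }
  pos
}

#' Place or remove a cell id on the occupancy map
#'
#' @param world a [new_world()] object.
#' @param pos 0-based `(x, y, z)` position.
#' @param id a cell identifier, or `NULL` to clear the site.
#' @return The world (modified in place; the occupancy map is an environment).
#' @export
world_occupy <- function(world, pos, id) {
  pos <- assert_in_bounds(pos, world$dims)
  key <- pos_key(pos)
  if (is.null(id)) {
    if (exists(key, envir = world$occupancy, inherits = FALSE)) {
      rm(list = key, envir = world$occupancy)
    }
  } else {
    if (exists(key, envir = world$occupancy, inherits = FALSE)) {
      stop("site (", paste(pos, collapse = ", "), ") is already occupied",
           call. = FALSE)
    }
    assign(key, id, envir = world$occupancy)
  }
  invisible(world)
}

#' Occupant of a site
#' @inheritParams world_occupy
#' @return The occupying cell id, or `NULL` for an empty site.
#' @export
world_occupant <- function(world, pos) {
  pos <- assert_in_bounds(pos, world$dims)
  key <- pos_key(pos)
  if (exists(key, envir = world$occupancy, inherits = FALSE)) {
    get(key, envir = world$occupancy, inherits = FALSE)
  } else {
    NULL
  }
}

# 26 Moore offsets, faces then edges then corners, fixed order
moore_offsets <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
      off <- off[rowSums(off != 0) > 0L, , drop = FALSE]
      cache <<- off[order(rowSums(off^2), off[, 1], off[, 2], off[, 3]), ,
                    drop = FALSE]
    }
    cache
  }
})

#' Moore neighborhood of a lattice site
#'
#' Returns the in-bounds subset of the 26 Moore neighbors of `pos`, in a
#' fixed deterministic order (faces, then edges, then corners).
#'
#' @param pos 0-based `(x, y, z)` position.
#' @param dims world dimensions.
#' @return An integer matrix with one `(x, y, z)` row per neighbor.
#' @examples
#' nrow(neighbors(c(5, 5, 5), c(10, 10, 10))) # 26
#' nrow(neighbors(c(0, 0, 0), c(10, 10, 10))) # 7
#' @export
neighbors <- function(pos, dims) {
  dims <- as.integer(dims)
  pos <- assert_in_bounds(pos, dims)
  nb <- sweep(moore_offsets(), 2L, pos, `+`)
  keep <- nb[, 1] >= 0L & nb[, 2] >= 0L & nb[, 3] >= 0L &
    nb[, 1] < dims[1] & nb[, 2] < dims[2] & nb[, 3] < dims[3]
  out <- nb[keep, , drop = FALSE]
  dimnames(out) <- list(NULL, c("x", "y", "z"))
  out
}

#' Convert a physical length to lattice sites
#'
#' One lattice site corresponds to 5 micrometres; distances round to the
#' nearest whole site.
#'
#' @param d length in micrometres, `d >= 0`.
#' @return Integer site count, `round(d / 5)`.
#' @examples
#' microns_to_sites(300) # 60
#' microns_to_sites(200) # 40
#' @export
microns_to_sites <- function(d) {
  if (any(d < 0)) stop("length must be non-negative", call. = FALSE)
  as.integer(round(d / 5))
}

#' Uniformly random empty Moore neighbor
#'
#' @inheritParams world_occupy
#' @return A `(x, y, z)` integer vector, or `NULL` if every in-bounds
#'   neighbor is occupied.  Uses R's RNG stream.
#' @export
random_empty_neighbor <- function(world, pos) {
  nb <- neighbors(pos, world$dims)
  empty <- vapply(seq_len(nrow(nb)), function(i) {
    is.null(world_occupant(world, nb[i, ]))
  }, logical(1))
  if (!any(empty)) return(NULL)
  idx <- which(empty)
  nb[idx[[sample.int(length(idx), 1L)]], ]
}

#' Degrade the ECM around a site
#'
#' Multiplies the ECM density at `pos` and its Moore neighbors by
#' `(1 - rate)`; densities stay within `[0, 1]`.
#'
#' @inheritParams world_occupy
#' @param rate fraction removed per application, in `[0, 1]`.
#' @return The world with the updated `ecm` array.
#' @export
degrade_ecm <- function(world, pos, rate) {
  stopifnot(rate >= 0, rate <= 1)
  pos <- assert_in_bounds(pos, world$dims)
  sites <- rbind(pos, neighbors(pos, world$dims))
  for (i in seq_len(nrow(sites))) {
    p <- sites[i, ] + 1L
    world$ecm[p[1], p[2], p[3]] <-
      min(1, max(0, world$ecm[p[1], p[2], p[3]] * (1 - rate)))
  }
  world
}
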