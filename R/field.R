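#' Molecular field on the lattice
#'
#' A per-species non-negative amount on every lattice site.  Species move by
#' a random-walk-equivalent diffusion kernel, enter by deposits (secretion)
#' and leave only through consumption; diffusion conserves total mass.
#'
#' @param species one of `"oxygen"`, `"vegf"`, `"fgf"`, `"hgf"`.
#' @param dims integer vector of three lattice dimensions.
#' @param initial uniform initial amount per site (default 0).
#' @return An object of class `"mol_field"`: a list with `species` and a 3D
#'   `amounts` array.
#' @examples
#' f <- new_field("vegf", c(9, 9, 9))
#' field_mass(f)
#' @export
new_field <- function(species = c("oxygen", "vegf", "fgf", "hgf"), dims,
                      initial = 0) {
  species <- match.arg(species)
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L), initial >= 0)
  structure(list(species = species, amounts = array(initial, dim = dims)),
            class = "mol_field")
}

#' @export
print.mol_field <- function(x, ...) {
  cat("<mol_field> ", x$species, " on ",
      paste(dim(x$amounts), collapse = "x"),
      " lattice, total mass ", format(field_mass(x)), "\n", sep = "")
  invisible(x)
}

#' Total mass of a field
#' @param field a [new_field()] object.
#' @return Sum of all site amounts.
#' @export
field_mass <- function(field) sum(field$amounts)

#' Deposit (secrete) an amount at a site
#'
#' @param field a [new_field()] object.
#' @param pos 0-based `(x, y, z)` position.
#' @param amount non-negative amount to add.
#' @return The field with `amount` added at `pos`; total mass grows by
#'   exactly `amount`.
#' @export
field_deposit <- function(field, pos, amount) {
  if (amount < 0) stop("deposit amount must be non-negative", call. = FALSE)
  pos <- assert_in_bounds(pos, dim(field$amounts)) + 1L
  field$amounts[pos[1], pos[2], pos[3]] <-
    field$amounts[pos[1], pos[2], pos[3]] + amount
  field
}

#' Diffuse a field
#'
#' Applies the random-walk expectation kernel `steps` times: at interior
#' sites each site keeps `1/27` of its mass and spreads the rest equally
#' over its 26 Moore neighbors; at the boundary the mass that would leave
#' the world stays (reflecting boundary).  The kernel is the expectation of
#' a walk taking independent uniform `{-1, 0, +1}` steps per axis, and is
#' applied as three separable per-axis passes.  Total mass is conserved.
#'
#' @param field a [new_field()] object.
#' @param steps number of diffusion steps, `>= 1`.
#' @return The diffused field.
#' @examples
#' f <- new_field("vegf", c(9, 9, 9))
#' f <- field_deposit(f, c(4, 4, 4), 27)
#' f <- field_diffuse(f, 1)
#' f$amounts[5, 5, 5] # 1: stay share of the point mass
#' @export
field_diffuse <- function(field, steps = 1L) {
  steps <- as.integer(steps)
  if (steps < 1L) stop("steps must be >= 1", call. = FALSE)
  field$amounts <- .field_diffuse_cpp(field$amounts, steps)
  field
}

#' Consume from a site, pooled nearest-first over its neighborhood
#'
#' Grants `min(requested, available)` where the available amount pools the
#' site itself and its Moore neighbors, drawn nearest-first (site, then face,
#' edge and corner neighbors; proportionally within a distance class).
#'
#' @param field a [new_field()] object.
#' @param pos 0-based `(x, y, z)` position.
#' @param requested non-negative amount requested.
#' @return A list with `granted` (units actually removed) and `field` (the
#'   reduced field).
#' @export
field_consume <- function(field, pos, requested) {
  if (requested < 0) stop("requested amount must be non-negative", call. = FALSE)
  pos <- assert_in_bounds(pos, dim(field$amounts))
  res <- .field_consume_cpp(field$amounts, pos, requested)
  field$amounts <- res$amounts
  list(granted = res$granted, field = field)
}

#' Step direction up the local field gradient
#'
#' Returns the unit lattice step from `pos` toward its highest-amount Moore
#' neighbor.  Ties are broken uniformly at random; when every neighbor
#' equals the amount at `pos` the step is uniformly random over the
#' in-bounds neighbors.  Uses R's RNG stream.
#'
#' @inheritParams field_consume
#' @return An integer `(dx, dy, dz)` offset with entries in `{-1, 0, 1}`.
#' @export
gradient_direction <- function(field, pos) {
  dims <- dim(field$amounts)
  pos <- assert_in_bounds(pos, dims)
  nb <- neighbors(pos, dims)
  amt <- field$amounts[nb + 1L]
  here <- field$amounts[matrix(pos + 1L, nrow = 1L)]
  if (all(abs(amt - here) < 1e-12)) {
    pick <- sample.int(nrow(nb), 1L)
  } else {
    best <- which(amt > max(amt) - 1e-12)
    pick <- best[[sample.int(length(best), 1L)]]
  }
  as.integer(nb[pick, ] - pos)
}

#' Monte-Carlo random-walk reference for the diffusion kernel
#'
#' Simulates discrete walkers that take independent uniform `{-1, 0, +1}`
#' steps on each axis per time step, clamped at the world boundary, and
#' returns their site occupancy counts.  This is the stochastic process
#' whose expectation [field_diffuse()] applies; it is retained as an
#' independent cross-check, not as a simulation path.
#'
#' @param dims lattice dimensions.
#' @param start 0-based starting position of every walker.
#' @param walkers number of walkers.
#' @param steps number of steps.
#' @return A 3D array of walker counts per site (sums to `walkers`).
#' @export
walker_occupancy <- function(dims, start, walkers, steps) {
  dims <- as.integer(dims)
  start <- assert_in_bounds(start, dims)
  pos <- matrix(rep(start, each = walkers), ncol = 3L)
  for (s in seq_len(steps)) {
    step <- matrix(sample(c(-1L, 0L, 1L), walkers * 3L, replace = TRUE),
                   ncol = 3L)
    pos <- pos + step
    for (a in 1:3) {
      pos[, a] <- pmin(pmax(pos[, a], 0L), dims[a] - 1L)
    }
  }
  counts <- array(0, dim = dims)
  idx <- pos[, 1] + dims[1] * (pos[, 2] + dims[2] * pos[, 3]) + 1L
  tab <- tabulate(idx, nbins = prod(dims))
  counts[] <- tab
  counts
}
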