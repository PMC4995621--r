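#' Radial profile around the tumor centroid
#'
#' Histograms entities (or a molecular species' mass) by Euclidean distance
#' from the centroid of the living tumor cells.  Anchoring on the living
#' tumor centroid, rather than the world centre, keeps profiles meaningful
#' for drifting tumors; with no living tumor cell the centroid falls back
#' to all tumor cells, then to the world centre.
#'
#' @param snapshot a [sim_snapshot()].
#' @param kind `"tumor_living"`, `"tumor_necrotic"`, `"tumor"`,
#'   `"endothelial"`, `"fibroblast"`, `"caf"`, or a species
#'   (`"oxygen"`, `"vegf"`, `"fgf"`, `"hgf"`).
#' @param bin_width bin width in lattice sites.
#' @return A data frame of class `"radial_profile"` with `bin_lo`,
#'   `bin_mid`, `bin_hi` and `count` (entity count, or total species mass,
#'   per bin).  Empty selections give an empty profile.
#' @export
radial_profile <- function(snapshot, kind, bin_width = 2) {
  stopifnot(inherits(snapshot, "tumor_snapshot"), bin_width > 0)
  ctr <- tumor_centroid(snapshot)
  if (kind %in% c("oxygen", "vegf", "fgf", "hgf")) {
    f <- snapshot$fields[[kind]]
    dm <- dim(f)
    keep <- which(f > 0)
    if (length(keep) == 0L) return(empty_profile())
    co <- arrayInd(keep, dm) - 1L
    d <- sqrt((co[, 1] - ctr[1])^2 + (co[, 2] - ctr[2])^2 +
                (co[, 3] - ctr[3])^2)
    w <- f[keep]
  } else {
    cells <- snapshot$cells
    sel <- switch(kind,
      tumor_living = cells$kind == "tumor" & cells$state != "necrotic",
      tumor_necrotic = cells$kind == "tumor" & cells$state == "necrotic",
      tumor = cells$kind == "tumor",
      endothelial = cells$kind == "endothelial",
      fibroblast = cells$kind == "fibroblast",
      caf = cells$kind == "fibroblast" & cells$state == "caf",
      stop("unknown kind '", kind, "'", call. = FALSE))
    cells <- cells[sel, , drop = FALSE]
    if (nrow(cells) == 0L) return(empty_profile())
    d <- sqrt((cells$x - ctr[1])^2 + (cells$y - ctr[2])^2 +
                (cells$z - ctr[3])^2)
    w <- rep(1, length(d))
  }
  bin_profile(d, w, bin_width)
}

empty_profile <- function() {
  structure(data.frame(bin_lo = numeric(0), bin_mid = numeric(0),
                       bin_hi = numeric(0), count = numeric(0)),
            class = c("radial_profile", "data.frame"))
}

bin_profile <- function(d, w, bin_width) {
  nb <- max(1L, ceiling((max(d) + 1e-9) / bin_width))
  idx <- pmin(nb, floor(d / bin_width) + 1L)
  cnt <- vapply(seq_len(nb), function(b) sum(w[idx == b]), numeric(1))
  structure(data.frame(bin_lo = (seq_len(nb) - 1) * bin_width,
                       bin_mid = (seq_len(nb) - 0.5) * bin_width,
                       bin_hi = seq_len(nb) * bin_width,
                       count = cnt),
            class = c("radial_profile", "data.frame"))
}

tumor_centroid <- function(snapshot) {
  cells <- snapshot$cells
  liv <- cells[cells$kind == "tumor" & cells$state != "necrotic", ,
               drop = FALSE]
  if (nrow(liv) == 0L) {
    liv <- cells[cells$kind == "tumor", , drop = FALSE]
  }
  if (nrow(liv) == 0L) return((snapshot$dims - 1) / 2)
  c(mean(liv$x), mean(liv$y), mean(liv$z))
}

#' Necrotic-core statistics
#'
#' @param snapshot a [sim_snapshot()].
#' @return A list with `fraction` (necrotic / (living + necrotic) tumor
#'   cells) and `core_radius` (95th percentile of necrotic-cell distances
#'   from the living-tumor centroid; 0 with no necrotic cells).
#' @export
necrotic_core_stats <- function(snapshot) {
  stopifnot(inherits(snapshot, "tumor_snapshot"))
  cells <- snapshot$cells
  tum <- cells[cells$kind == "tumor", , drop = FALSE]
  nec <- tum[tum$state == "necrotic", , drop = FALSE]
  n_tot <- nrow(tum)
  if (n_tot == 0L) return(list(fraction = 0, core_radius = 0))
  if (nrow(nec) == 0L) return(list(fraction = 0, core_radius = 0))
  ctr <- tumor_centroid(snapshot)
  d <- sqrt((nec$x - ctr[1])^2 + (nec$y - ctr[2])^2 + (nec$z - ctr[3])^2)
  list(fraction = nrow(nec) / n_tot,
       core_radius = unname(stats::quantile(d, 0.95)))
}

#' Radial profile of vessel branch events
#'
#' The brush-border effect: vessels branch more frequently the closer they
#' come to the tumor.  Branch events are histogrammed by the distance of
#' their occurrence position to the living-tumor centroid of `snapshot`.
#'
#' @param events an event log ([sim_events()]).
#' @param snapshot a [sim_snapshot()] supplying the centroid.
#' @param bin_width bin width in sites.
#' @return A `"radial_profile"` data frame (all-zero `count` when the log
#'   holds no branch events).
#' @export
branching_profile <- function(events, snapshot, bin_width = 5) {
  stopifnot(inherits(snapshot, "tumor_snapshot"))
  br <- events[events$event == "branch", , drop = FALSE]
  if (nrow(br) == 0L) {
    pr <- empty_profile()
    return(pr)
  }
  ctr <- tumor_centroid(snapshot)
  d <- sqrt((br$x - ctr[1])^2 + (br$y - ctr[2])^2 + (br$z - ctr[3])^2)
  bin_profile(d, rep(1, length(d)), bin_width)
}

#' Detect the linear-to-exponential turning point
#'
#' Scans every candidate change point of a two-piece growth model -- linear
#' counts before the change point, exponential growth (linear in log
#' counts) after it -- and returns the change point with the best
#' profile likelihood.  Each segment carries its own residual variance and
#' the exponential segment's likelihood includes the log-normal Jacobian,
#' so neither the huge late counts nor the tiny early ones dominate the
#' fit.  A change point only counts as a transition when the two-piece
#' model beats a single straight line by a deviance margin and the
#' post-transition growth rate is positive and exceeds the relative growth
#' the linear segment would imply.
#'
#' @param series numeric vector of living-cell counts per tick (the series
#'   index is the tick, starting at tick 0).
#' @param min_len minimum series length (50).
#' @param min_segment smallest number of points on each side of the change
#'   point.
#' @param threshold deviance margin the two-piece fit must achieve over
#'   the single-line fit.
#' @return The turning-point tick (0-based, matching the series' tick
#'   axis), or `NULL` when no transition is supported.  Zeros in the
#'   exponential segment are handled through `log(count + 1)`.
#' @examples
#' s <- c(2 * (0:100), 200 * 1.02^(1:60))
#' detect_turning_point(s)
#' @export
detect_turning_point <- function(series, min_len = 50, min_segment = 10,
                                 threshold = 25) {
  y <- as.numeric(series)
  n <- length(y)
  if (n < min_len) {
    stop("series must hold at least ", min_len, " ticks", call. = FALSE)
  }
  t <- seq_len(n) - 1
  logy <- log(y + 1)
  fit0 <- stats::lm.fit(cbind(1, t), y)
  nll0 <- n * log(max(sum(fit0$residuals^2), 1e-8) / n)
  best <- NULL
  for (k in min_segment:(n - min_segment)) {
    i1 <- 1:k
    i2 <- (k + 1):n
    f1 <- stats::lm.fit(cbind(1, t[i1]), y[i1])
    f2 <- stats::lm.fit(cbind(1, t[i2]), logy[i2])
    b1 <- f1$coefficients[2]
    b2 <- f2$coefficients[2]
    if (!is.finite(b2) || b2 <= 0) next
    # exponential growth must outpace the linear segment in relative terms
    if (b2 <= b1 / max(max(y[i1]), 1)) next
    s <- k * log(max(sum(f1$residuals^2), 1e-8) / k) +
      (n - k) * log(max(sum(f2$residuals^2), 1e-8) / (n - k)) +
      2 * sum(logy[i2])  # log-normal Jacobian: densities live on counts
    if (is.null(best) || s < best$s) best <- list(k = k, s = s)
  }
  if (is.null(best)) return(NULL)
  if (nll0 - best$s < threshold) return(NULL)
  t[best$k]
}

#' Time to development
#'
#' First tick at which the living count reaches ten times its
#' pre-turning-point maximum — the operational "fully developed"
#' criterion used by [classify_fate()].
#'
#' @inheritParams detect_turning_point
#' @return The tick, or `NA` when there is no turning point or the level is
#'   never reached.
#' @export
time_to_development <- function(series) {
  tp <- tryCatch(detect_turning_point(series), error = function(e) NULL)
  if (is.null(tp)) return(NA_integer_)
  pre_max <- max(series[seq_len(tp + 1)])
  hit <- which(series >= 10 * pre_max)
  if (length(hit) == 0L) return(NA_integer_)
  as.integer(hit[1] - 1L)
}

#' Classify the fate of a run
#'
#' Partitions every population trajectory into one of three fates:
#' `extinct` (no living tumor cell at the horizon), `developed` (a
#' turning point was detected and the final count is at least ten times the
#' pre-transition maximum), `arrested` otherwise.
#'
#' @param series living tumor cells per tick, from tick 0 up to `horizon`.
#' @param horizon the horizon the series must reach.
#' @return `"extinct"`, `"developed"` or `"arrested"`.
#' @export
classify_fate <- function(series, horizon = length(series) - 1L) {
  series <- as.numeric(series)
  if (length(series) < horizon + 1L) {
    stop("series is shorter than the horizon", call. = FALSE)
  }
  series <- series[seq_len(horizon + 1L)]
  if (series[length(series)] == 0) return("extinct")
  tp <- tryCatch(detect_turning_point(series), error = function(e) NULL)
  if (!is.null(tp)) {
    pre_max <- max(series[seq_len(tp + 1)])
    if (series[length(series)] >= 10 * pre_max) return("developed")
  }
  "arrested"
}
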