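# 8-connected flood fill over a predicate, vectorised frontier expansion.
# `start` and the return value are linear (column-major) indices.
.flood8 <- function(start, ok, h, w) {
  inreg <- logical(h * w)
  inreg[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    r <- ((frontier - 1L) %% h) + 1L
    cc <- ((frontier - 1L) %/% h) + 1L
    nb <- integer(0)
    for (dr in -1L:1L) for (dc in -1L:1L) {
      if (dr == 0L && dc == 0L) next
      keep <- r + dr >= 1L & r + dr <= h & cc + dc >= 1L & cc + dc <= w
      if (any(keep)) nb <- c(nb, frontier[keep] + dr + dc * h)
    }
    nb <- unique(nb)
    nb <- nb[ok[nb] & !inreg[nb]]
    inreg[nb] <- TRUE
    frontier <- nb
  }
  which(inreg)
}

# Maximum over the (in-bounds) 8 neighbours of every pixel; -Inf where a
# pixel has no neighbour on that side.
.neighbor_max <- function(v) {
  h <- nrow(v); w <- ncol(v)
  p <- matrix(-Inf, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- v
  r <- 2:(h + 1L); cc <- 2:(w + 1L)
  pmax(p[r - 1L, cc - 1L], p[r - 1L, cc], p[r - 1L, cc + 1L],
       p[r,      cc - 1L],                p[r,      cc + 1L],
       p[r + 1L, cc - 1L], p[r + 1L, cc], p[r + 1L, cc + 1L])
}

#' Noise-tolerant local maxima detection on a distance map
#'
#' Prominence-style maxima detection with merging, one accepted maximum
#' per cell: (a) every positive pixel that is `>=` all of its 8 neighbours
#' is a candidate; (b) candidates are processed in descending value (ties:
#' smaller row, then column, first); (c) from each still-unclaimed
#' candidate of value `v`, a flood fill (8-connected) claims every
#' positive pixel with value `> v - noise_tolerance`; if the flood reaches
#' territory already claimed by a previously accepted maximum, the
#' candidate merges into it and emits no marker, otherwise it is accepted;
#' (d) an accepted maximum sitting on an equal-valued plateau emits one
#' marker at the plateau pixel nearest the plateau centroid (ties: smaller
#' row, then column); (e) background (value 0) is never claimed, so
#' separate blobs can never merge.
#'
#' Raising `noise_tolerance` merges shallowly-separated peaks — e.g. the
#' two lobes of a waisted "bottleneck" footprint — and therefore never
#' increases the count.
#'
#' @param dm numeric matrix, a distance map from [distance_map()] (any
#'   non-negative single-peak-per-object height map works).
#' @param noise_tolerance positive prominence tolerance in distance-map
#'   units.
#' @param exclude_edge_maxima if `TRUE`, accepted maxima whose claimed
#'   region touches the raster border are dropped from markers, count, and
#'   tolerance mask.
#' @return An object of class `maxima_result`: `markers` (integer matrix
#'   with columns `row`, `col`), `count`, and `tolerance_mask` (logical
#'   matrix of all pixels claimed for an accepted maximum).
#' @export
find_maxima <- function(dm, noise_tolerance, exclude_edge_maxima = FALSE) {
  assert_scalar_positive(noise_tolerance, "noise_tolerance")
  stopifnot(is.matrix(dm), all(dm >= 0))
  h <- nrow(dm); w <- ncol(dm)
  v <- as.vector(dm)

  cand <- which(dm > 0 & dm >= .neighbor_max(dm))
  res_empty <- function() {
    structure(list(
      markers = matrix(integer(), 0L, 2L, dimnames = list(NULL, c("row", "col"))),
      count = 0L,
      tolerance_mask = matrix(FALSE, h, w)), class = "maxima_result")
  }
  if (length(cand) == 0L) return(res_empty())

  cr <- ((cand - 1L) %% h) + 1L
  ccol <- ((cand - 1L) %/% h) + 1L
  cand <- cand[order(-v[cand], cr, ccol)]

  claimed <- integer(h * w)
  markers <- list()
  touches_border <- logical(0)
  next_id <- 0L

  for (i in cand) {
    if (claimed[i] > 0L) next
    v0 <- v[i]
    ok <- v > (v0 - noise_tolerance) & v > 0
    region <- .flood8(i, ok, h, w)
    prior <- claimed[region]
    prior <- prior[prior > 0L]
    if (length(prior)) {
      # shallow saddle: merge into the already-accepted maximum
      claimed[region[claimed[region] == 0L]] <- min(prior)
    } else {
      next_id <- next_id + 1L
      claimed[region] <- next_id
      plat <- .flood8(i, v == v0, h, w)
      pr <- ((plat - 1L) %% h) + 1L
      pc <- ((plat - 1L) %/% h) + 1L
      d2 <- (pr - mean(pr))^2 + (pc - mean(pc))^2
      sel <- order(d2, pr, pc)[1L]
      markers[[next_id]] <- c(pr[sel], pc[sel])
      rr <- ((region - 1L) %% h) + 1L
      rc <- ((region - 1L) %/% h) + 1L
      touches_border[next_id] <- any(rr == 1L | rr == h | rc == 1L | rc == w)
    }
  }

  keep <- if (exclude_edge_maxima) which(!touches_border) else seq_len(next_id)
  if (length(keep) == 0L) return(res_empty())
  mk <- do.call(rbind, markers[keep])
  dimnames(mk) <- list(NULL, c("row", "col"))
  structure(list(
    markers = mk,
    count = length(keep),
    tolerance_mask = matrix(claimed %in% keep, h, w)),
    class = "maxima_result")
}

#' @export
print.maxima_result <- function(x, ...) {
  cat(sprintf("<maxima_result> %d accepted maxima, tolerance region %d px\n",
              x$count, sum(x$tolerance_mask)))
  invisible(x)
}
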