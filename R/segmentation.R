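# Rotating-projection density segmentation of the three neuropils.
#
# Neuropils are dense point clouds joined by thin backbone tracts, so the
# histogram of the pooled skeleton nodes projected onto a well-chosen axis
# shows deep local minima between neuropils. The scan rotates the cloud about
# the reference axes on a fixed angular grid and keeps the rotation whose
# profile minima are lowest and most consistent.

#' Density profile of projected points
#'
#' Rotates the points by sequential rotations about the x, y and z axes and
#' histograms the coordinate along one reference axis.
#'
#' @param points n x 3 numeric matrix (or a `skeleton`).
#' @param rotation numeric triple of angles in degrees (about x, y, z).
#' @param axis projection axis index (1 = x, 2 = y, 3 = z).
#' @param bin_width histogram bin width in micrometres (default 2).
#' @return a `projection_profile`: list with `axis`, `rotation`, `bin_edges`,
#'   `density` (counts per bin), `mids` and `smoothed` (Gaussian-smoothed
#'   counts, bandwidth = one bin).
#' @export
density_profile <- function(points, rotation = c(0, 0, 0), axis = 1L, bin_width = 2) {
  pts <- as_point_matrix(points)
  assert_that(nrow(pts) >= 2L, "need at least 2 points for a density profile")
  assert_that(axis %in% 1:3, "axis must be 1, 2 or 3")
  assert_that(is.numeric(bin_width) && bin_width > 0, "bin_width must be positive")
  coord <- rotate_points(pts, rotation)[, axis]
  rng <- range(coord)
  if (diff(rng) == 0) stop_("degenerate point set: all projected coordinates identical")
  edges <- seq(floor(rng[1] / bin_width) * bin_width,
               ceiling(rng[2] / bin_width) * bin_width + bin_width, by = bin_width)
  counts <- as.numeric(table(cut(coord, breaks = edges, right = FALSE,
                                 include.lowest = FALSE)))
  structure(list(axis = axis, rotation = rotation, bin_edges = edges,
                 density = counts, mids = edges[-length(edges)] + bin_width / 2,
                 smoothed = smooth_counts(counts, bandwidth_bins = 1)),
            class = "projection_profile")
}

#' Local minima of a projection profile
#'
#' Strict interior minima of the smoothed profile, filtered by a prominence of
#' at least `prominence_frac` of the profile maximum (suppresses spurious dips
#' in noisy node histograms).
#'
#' @param profile a `projection_profile`.
#' @param prominence_frac minimum prominence as a fraction of the maximum.
#' @return data frame with columns `position` (bin midpoint) and `density`
#'   (smoothed value); zero rows when no qualifying minimum exists.
#' @export
profile_minima <- function(profile, prominence_frac = 0.05) {
  y <- profile$smoothed
  idx <- local_minima(y, min_prominence = prominence_frac * max(y))
  data.frame(position = profile$mids[idx], density = y[idx])
}

#' Scan rotations for the best neuropil-separating projection
#'
#' Evaluates density profiles over a grid of single-axis rotations (each
#' reference axis independently, angles `0, increment, ..., 360 - increment`)
#' and selects the rotation minimising `mean(minima densities) + weight *
#' sd(minima densities)`, i.e. the projection whose inter-neuropil gaps are
#' lowest and most uniform. Ties are broken towards the smaller angle, then
#' the earlier rotation axis.
#'
#' @param points n x 3 matrix (or `skeleton`), typically pooled over neurons.
#' @param axis projection axis index (1 = x, 2 = y, 3 = z).
#' @param increment angular grid step in degrees; must divide 360.
#' @param bin_width histogram bin width in micrometres.
#' @param weight weight of the standard-deviation term in the criterion.
#' @param prominence_frac minimum prominence for a minimum to count.
#' @return list with `separable` (logical), and when separable: `rotation`
#'   (angle triple), `rotation_axis`, `angle`, `criterion`, `minima`
#'   (data frame) and `profile`. When no rotation exhibits an interior local
#'   minimum, `separable = FALSE` and the caller should fall back to a
#'   user-supplied rule.
#' @export
scan_rotations <- function(points, axis = 1L, increment = 5, bin_width = 2,
                           weight = 1, prominence_frac = 0.05) {
  pts <- as_point_matrix(points)
  assert_that(is.numeric(increment) && increment > 0 && 360 %% increment == 0,
              "increment must be a positive divisor of 360")
  angles <- seq(0, 360 - increment, by = increment)
  best <- NULL
  for (rot_axis in 1:3) {
    for (ang in angles) {
      rotation <- c(0, 0, 0)
      rotation[rot_axis] <- ang
      prof <- density_profile(pts, rotation = rotation, axis = axis,
                              bin_width = bin_width)
      mins <- profile_minima(prof, prominence_frac = prominence_frac)
      if (!nrow(mins)) next
      crit <- mean(mins$density) +
        weight * (if (nrow(mins) > 1L) stats::sd(mins$density) else 0)
      if (is.null(best) || crit < best$criterion - 1e-12) {
        best <- list(separable = TRUE, rotation = rotation,
                     rotation_axis = rot_axis, angle = ang, criterion = crit,
                     minima = mins, profile = prof)
      }
    }
  }
  if (is.null(best)) return(list(separable = FALSE))
  best
}

#' Define a segmentation rule
#'
#' A rule assigns a point to a neuropil iff the point satisfies every
#' condition. Each condition is a `(rotation, axis, interval)` triple with a
#' half-open interval `[lo, hi)` on the rotated coordinate (lower-closed, so a
#' boundary point belongs to the upper-adjacent region's lower bound).
#'
#' @param neuropil one of `"AL"`, `"MB_calyx"`, `"LH"`.
#' @param conditions list of conditions, each a list with `rotation` (angle
#'   triple), `axis` (1-3) and `interval` (`c(lo, hi)`, `-Inf`/`Inf` allowed).
#' @return a `segmentation_rule`.
#' @export
segmentation_rule <- function(neuropil, conditions) {
  assert_that(neuropil %in% NEUROPILS, "neuropil must be one of %s",
              paste(NEUROPILS, collapse = ", "))
  assert_that(length(conditions) >= 1L, "a rule needs at least one condition")
  for (cond in conditions) {
    assert_that(all(c("rotation", "axis", "interval") %in% names(cond)),
                "each condition needs rotation, axis and interval")
    assert_that(length(cond$interval) == 2L && cond$interval[1] < cond$interval[2],
                "condition interval must be c(lo, hi) with lo < hi")
  }
  structure(list(neuropil = neuropil, conditions = conditions),
            class = "segmentation_rule")
}

condition_matches <- function(cond, pts) {
  coord <- rotate_points(pts, cond$rotation)[, cond$axis]
  coord >= cond$interval[1] & coord < cond$interval[2]
}

#' Build neuropil masks from segmentation rules
#'
#' Applies a set of rules to every node of every skeleton. Nodes matching no
#' rule are backbone/unassigned and are simply absent from the output; a node
#' matching rules of two different neuropils is an error (the rules overlap).
#'
#' @param rules list of `segmentation_rule` objects (may cover a subset of the
#'   three neuropils; an empty list yields an empty mask).
#' @param skeletons list of `skeleton` objects.
#' @return data frame with columns `neuron_id`, `node_id`, `neuropil`.
#' @export
build_masks <- function(rules, skeletons) {
  assert_that(is.list(rules), "rules must be a list of segmentation_rule objects")
  for (r in rules) assert_that(inherits(r, "segmentation_rule"),
                               "rules must be segmentation_rule objects")
  out <- vector("list", length(skeletons))
  for (k in seq_along(skeletons)) {
    s <- skeletons[[k]]
    assert_that(inherits(s, "skeleton"), "skeletons must be skeleton objects")
    pts <- skeleton_points(s)
    assign <- rep(NA_character_, nrow(pts))
    for (r in rules) {
      inside <- Reduce(`&`, lapply(r$conditions, condition_matches, pts = pts))
      clash <- inside & !is.na(assign) & assign != r$neuropil
      if (any(clash)) {
        stop_("overlapping rules: node %d of neuron '%s' matches both '%s' and '%s'",
              s$nodes$node_id[which(clash)[1]], s$neuron_id,
              assign[which(clash)[1]], r$neuropil)
      }
      assign[inside] <- r$neuropil
    }
    hit <- !is.na(assign)
    if (any(hit)) {
      out[[k]] <- data.frame(neuron_id = s$neuron_id,
                             node_id = s$nodes$node_id[hit],
                             neuropil = assign[hit],
                             stringsAsFactors = FALSE)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(neuron_id = character(), node_id = integer(),
                      neuropil = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Automatic three-neuropil segmentation of a pooled scene
#'
#' Convenience wrapper mirroring the manual procedure: scan rotations for the
#' best separating projection, take the two most prominent profile minima as
#' inter-neuropil boundaries, trim each of the three intervals to the occupied
#' density support (bins above `support_frac` of the profile maximum) so deep
#' backbone gaps stay unassigned, and label the intervals `AL`, `MB_calyx`,
#' `LH` in increasing coordinate order (the generator's region order; pass
#' `neuropil_order` to override).
#'
#' @param skeletons list of `skeleton` objects.
#' @param axis,increment,bin_width,weight,prominence_frac passed to
#'   [scan_rotations()].
#' @param support_frac density fraction below which outer bins are trimmed.
#' @param neuropil_order labels for the three intervals in coordinate order.
#' @return list with `rules`, `masks` (from [build_masks()]), and `scan`.
#' @export
segment_scene <- function(skeletons, axis = 1L, increment = 5, bin_width = 2,
                          weight = 1, prominence_frac = 0.05,
                          support_frac = 0.05, neuropil_order = NEUROPILS) {
  pts <- do.call(rbind, lapply(skeletons, skeleton_points))
  scan <- scan_rotations(pts, axis = axis, increment = increment,
                         bin_width = bin_width, weight = weight,
                         prominence_frac = prominence_frac)
  if (!isTRUE(scan$separable)) {
    stop_("scene is inseparable along axis %d: no interior density minimum; supply rules manually", axis)
  }
  prof <- scan$profile
  # the three neuropil modes = the three tallest plateau-aware peaks; each
  # boundary is the lowest point of the profile between consecutive modes
  peaks <- local_extrema(prof$smoothed, minima = FALSE)
  assert_that(length(peaks) >= 3L,
              "need three density modes to carve three neuropils; found %d", length(peaks))
  top <- sort(peaks[order(-prof$smoothed[peaks], peaks)][1:3])
  cuts <- vapply(1:2, function(i) {
    span <- (top[i] + 1L):(top[i + 1L] - 1L)
    prof$mids[span[which.min(prof$smoothed[span])]]
  }, numeric(1))
  segs <- list(c(-Inf, cuts[1]), c(cuts[1], cuts[2]), c(cuts[2], Inf))
  thr <- support_frac * max(prof$smoothed)
  rules <- vector("list", 3L)
  for (i in 1:3) {
    inseg <- prof$mids >= segs[[i]][1] & prof$mids < segs[[i]][2] & prof$smoothed >= thr
    assert_that(any(inseg), "no occupied bins in segment %d; scene is not tri-modal", i)
    lo <- prof$bin_edges[min(which(inseg))]
    hi <- prof$bin_edges[max(which(inseg)) + 1L]
    rules[[i]] <- segmentation_rule(neuropil_order[i], list(
      list(rotation = scan$rotation, axis = axis, interval = c(lo, hi))))
  }
  list(rules = rules, masks = build_masks(rules, skeletons), scan = scan)
}

#' Write / read segmentation masks as delimited text
#'
#' @param masks mask data frame from [build_masks()].
#' @param path output (input) path; tab-separated with a header.
#' @return `write_masks` returns `path` invisibly; `read_masks` the data frame.
#' @export
write_masks <- function(masks, path) {
  utils::write.table(masks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_masks
#' @export
read_masks <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  assert_that(all(c("neuron_id", "node_id", "neuropil") %in% names(df)),
              "mask file must have neuron_id, node_id, neuropil columns")
  df$neuron_id <- as.character(df$neuron_id)
  df
}
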