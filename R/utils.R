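# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_ <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop_(fmt, ...)
  invisible(TRUE)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

#' Rotation matrix from sequential rotations about the reference axes
#'
#' Builds the 3x3 matrix for rotations applied sequentially about the x, y and
#' z axes (in that order), each angle in degrees. Points stored as rows are
#' rotated with `points %*% t(rotation_matrix(angles))`.
#'
#' @param angles numeric length-3 vector of angles in degrees (about x, y, z).
#' @return a 3x3 rotation matrix.
#' @export
rotation_matrix <- function(angles) {
  assert_that(is.numeric(angles) && length(angles) == 3L && all(is.finite(angles)),
              "angles must be a finite numeric triple (degrees about x, y, z)")
  a <- angles * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])), c(0, sin(a[1]), cos(a[1])))
  ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
  rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

rotate_points <- function(points, angles) {
  if (all(angles == 0)) return(points)
  points %*% t(rotation_matrix(angles))
}

as_point_matrix <- function(x, what = "points") {
  if (inherits(x, "skeleton")) x <- skeleton_points(x)
  m <- as.matrix(x)
  assert_that(is.numeric(m) && ncol(m) == 3L, "%s must be an n x 3 numeric matrix", what)
  assert_that(nrow(m) >= 1L, "%s must contain at least one point", what)
  assert_that(all(is.finite(m)), "%s contains non-finite coordinates", what)
  dimnames(m) <- NULL
  m
}

# Adjusted Rand index between two labelings (used for planted-truth recovery).
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sij <- sum(choose2(tab))
  si <- sum(choose2(rowSums(tab)))
  sj <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- si * sj / n2
  mx <- (si + sj) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}

# Gaussian kernel smoothing of a regular-grid count vector; bandwidth in bins.
smooth_counts <- function(counts, bandwidth_bins = 1) {
  n <- length(counts)
  if (n < 3L || bandwidth_bins <= 0) return(counts)
  half <- max(1L, ceiling(3 * bandwidth_bins))
  k <- stats::dnorm(seq(-half, half), sd = bandwidth_bins)
  k <- k / sum(k)
  padded <- c(rep(counts[1], half), counts, rep(counts[n], half))
  out <- stats::filter(padded, k, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

# Plateau-aware interior local extrema: a run of equal values is an extremum
# when both adjacent (differing) runs lie on the same side; the run's centre
# index is reported. Node histograms of evenly spaced backbone tracts produce
# constant-density plateaus in the inter-neuropil gaps, which strict
# neighbour comparisons would miss entirely.
local_extrema <- function(y, minima = TRUE) {
  r <- rle(y)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  j <- 2:(k - 1L)
  hit <- if (minima) {
    r$values[j] < r$values[j - 1L] & r$values[j] < r$values[j + 1L]
  } else {
    r$values[j] > r$values[j - 1L] & r$values[j] > r$values[j + 1L]
  }
  j <- j[hit]
  as.integer(floor((starts[j] + ends[j]) / 2))
}

# Local minima with a topographic prominence filter:
# prominence = min(max left, max right) - value.
local_minima <- function(y, min_prominence = 0) {
  idx <- local_extrema(y, minima = TRUE)
  if (!length(idx) || min_prominence <= 0) return(idx)
  n <- length(y)
  keep <- vapply(idx, function(i) {
    min(max(y[1:(i - 1)]), max(y[(i + 1):n])) - y[i] >= min_prominence
  }, logical(1))
  idx[keep]
}

# Minimal INI-style config parser: [section] blocks, key = value lines,
# '#'/';' comments. Values are auto-typed (logical, numeric, comma lists).
parse_ini <- function(path) {
  assert_that(file.exists(path), "config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[#;].*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  section <- "global"
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(cfg[[section]])) cfg[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      cfg[[section]][[key]] <- type_convert_scalar(val)
    } else {
      stop_("malformed config line: '%s'", ln)
    }
  }
  cfg
}

type_convert_scalar <- function(val) {
  if (grepl(",", val, fixed = TRUE)) {
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    return(unlist(lapply(parts, type_convert_scalar), use.names = FALSE))
  }
  if (tolower(val) %in% c("true", "false")) return(as.logical(val))
  num <- suppressWarnings(as.numeric(val))
  if (!is.na(num)) return(num)
  val
}

# Stable file hash used for the pipeline's no-op rerun detection.
content_hash <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (!length(paths)) return(NA_character_)
  paste(unname(tools::md5sum(paths)), collapse = "")
}
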