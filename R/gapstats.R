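# Gap statistics on intra-species ANI distributions: uniform-null deficit
# counts, KDE valley detection, dip test, species classification, the
# cross-species gap mode, the subsampling control, and the divergence-time
# closed form.

#' Intra-species ANI distribution
#'
#' Holds the pairwise ANI values of one species above a floor (default 95%,
#' the species-level ANI threshold); undefined (NA) values are dropped.
#'
#' @param values numeric ANI percents, one per genome pair.
#' @param species_id label.
#' @param floor values at or below this are excluded.
#' @return object of class `ani_distribution`.
#' @export
ani_distribution <- function(values, species_id = "species", floor = 95) {
  values <- values[!is.na(values) & values > floor]
  if (any(values > 100)) stop("ANI values above 100 are invalid")
  structure(list(species_id = species_id, values = values,
                 floor = floor, n = length(values)),
            class = "ani_distribution")
}

#' Expected pair count under a uniform ANI distribution
#'
#' If `N` genome pairs had ANI values spread uniformly over `[a, b]`, the
#' interval `[l, r]` would be expected to hold `N * (r - l) / (b - a)` pairs.
#' This is the chance-alone yardstick against which the observed count in a
#' candidate gap interval is compared.
#'
#' @param N total number of pairs in `[a, b]`.
#' @param a,b range endpoints (percent ANI).
#' @param l,r interval endpoints, `a <= l < r <= b`.
#' @return expected count (not rounded).
#' @export
#' @examples
#' expected_uniform(4280133, 96, 100, 99.2, 99.3)  # about 107,000
#' expected_uniform(4280133, 96, 100, 99.2, 99.8)  # about 642,000
expected_uniform <- function(N, a, b, l, r) {
  if (!(a < b)) stop("degenerate range: need a < b")
  if (!(a <= l && l < r && r <= b)) stop("interval must satisfy a <= l < r <= b")
  if (N < 0) stop("N must be nonnegative")
  N * (r - l) / (b - a)
}

#' Uniform-null deficit of an ANI interval
#'
#' Counts observed pairs in `[l, r)` (values exactly at the top of the range
#' are included through the closed top edge when `r == b`), computes the count
#' expected under a uniform distribution over `[a, b]`, and their ratio
#' R = expected / observed. R of about 3 reproduces the "threefold fewer
#' pairs than expected by chance" situation in the 99.2--99.8% window.
#'
#' @param dist an [ani_distribution()] (or numeric vector).
#' @param interval length-2 gap interval `c(l, r)`.
#' @param range length-2 uniform range `c(a, b)`.
#' @param bin_width reporting width for the expected-per-bin figure.
#' @return object of class `uniform_null_report`.
#' @export
deficit_ratio <- function(dist, interval = c(99.2, 99.8), range = c(96, 100),
                          bin_width = 0.1) {
  v <- if (inherits(dist, "ani_distribution")) dist$values else dist
  a <- range[1]; b <- range[2]; l <- interval[1]; r <- interval[2]
  in_range <- v >= a & v <= b
  N <- sum(in_range)
  O <- sum(v >= l & (v < r | (r == b & v == b)))
  E <- expected_uniform(N, a, b, l, r)
  structure(list(N = N, range = range, interval = interval,
                 bin_width = bin_width,
                 expected_per_bin = N * bin_width / (b - a),
                 expected_in_interval = E, observed_in_interval = O,
                 deficit_ratio = if (O >= 1L) E / O else NA_real_,
                 observed_zero = O == 0L),
            class = "uniform_null_report")
}

#' @export
print.uniform_null_report <- function(x, ...) {
  cat(sprintf("<uniform_null_report> N = %d in [%g, %g]; expected %.1f vs observed %d in [%g, %g)%s\n",
              x$N, x$range[1], x$range[2], x$expected_in_interval,
              x$observed_in_interval, x$interval[1], x$interval[2],
              if (x$observed_zero) "; deficit ratio undefined (no observations)"
              else sprintf("; deficit ratio %.2f", x$deficit_ratio)))
  invisible(x)
}

#' Find density valleys in an ANI distribution
#'
#' Gaussian kernel density estimate on a fixed grid; a local minimum is
#' reported as a valley when its density is at most `beta` times the density
#' of the lower of its two flanking peaks. The valley extent is the maximal
#' contiguous grid region around the minimum where the density stays at or
#' below that cutoff; the midpoint is the density argmin.
#'
#' @param values numeric ANI percents (at least 10).
#' @param bandwidth KDE bandwidth in ANI percentage units. The default 0.1
#'   matches the 0.1%-ANI bin width used by the uniform-null counts;
#'   Silverman's rule (`"nrd0"`) is available but oversmooths strongly
#'   bimodal ANI distributions and shifts valley midpoints.
#' @param grid length-2 grid range.
#' @param step grid step (percent ANI).
#' @param beta valley prominence cutoff in (0, 1).
#' @return data.frame with columns left, right, midpoint, depth_ratio
#'   (density at minimum / lower flanking peak); zero rows when no valley.
#' @export
find_valleys <- function(values, bandwidth = 0.1, grid = c(95, 100),
                         step = 0.01, beta = 0.5) {
  empty <- data.frame(left = numeric(0), right = numeric(0),
                      midpoint = numeric(0), depth_ratio = numeric(0))
  if (length(values) < 10L) return(empty)
  ngrid <- round(diff(grid) / step) + 1L
  d <- density(values, bw = bandwidth %||% "nrd0",
               from = grid[1], to = grid[2], n = ngrid)
  y <- d$y; x <- d$x; m <- length(y)
  y[y < 1e-9 * max(y)] <- 0         # FFT far-tail noise is not structure
  # interior local minima / maxima (one-sided strictness tolerates plateaus);
  # grid endpoints count as flanking peaks
  mid <- 2:(m - 1L)
  is_min <- c(FALSE, (y[mid] <= y[mid - 1L] & y[mid] < y[mid + 1L]) |
                     (y[mid] <  y[mid - 1L] & y[mid] <= y[mid + 1L]), FALSE)
  is_max <- c(TRUE,  (y[mid] >= y[mid - 1L] & y[mid] > y[mid + 1L]) |
                     (y[mid] >  y[mid - 1L] & y[mid] >= y[mid + 1L]), TRUE)
  max_idx <- which(is_max)
  rows <- list()
  for (i in which(is_min)) {
    left_peaks <- max_idx[max_idx < i]
    right_peaks <- max_idx[max_idx > i]
    if (!length(left_peaks) || !length(right_peaks)) next
    lp <- min(y[left_peaks[length(left_peaks)]], y[right_peaks[1L]])  # lower flanking peak
    if (lp <= 0) next
    if (y[i] > beta * lp) next
    cutoff <- beta * lp
    lo <- i; while (lo > 1L && y[lo - 1L] <= cutoff) lo <- lo - 1L
    hi <- i; while (hi < m && y[hi + 1L] <= cutoff) hi <- hi + 1L
    # midpoint: centre of the minimal-density plateau (argmin for a smooth
    # minimum; the centre of the flat region for a density that bottoms out)
    span <- lo:hi
    flat <- span[y[span] <= y[i] + 1e-9 * max(y)]
    midpt <- x[flat[ceiling(length(flat) / 2)]]
    rows[[length(rows) + 1L]] <- data.frame(
      left = x[lo], right = x[hi], midpoint = midpt, depth_ratio = y[i] / lp)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  # merge duplicate minima that share one extent (keep deepest)
  key <- paste(out$left, out$right)
  out <- do.call(rbind, lapply(split(out, key), function(g)
    g[which.min(g$depth_ratio), ]))
  out <- out[order(out$midpoint), ]
  rownames(out) <- NULL
  out
}

#' Classify a species' ANI distribution
#'
#' `clonal` when all pairwise values exceed 99.5% (too clonal to call a gap);
#' `gap_99.2_99.8` when a significant valley (dip p < `alpha`) has its
#' midpoint inside the window; `shifted_gap` when significant valleys exist
#' only outside the window; `no_gap` otherwise.
#'
#' @param dist an [ani_distribution()] or numeric vector.
#' @param valleys valley table from [find_valleys()].
#' @param dip_p dip test p-value for the same values.
#' @param window length-2 gap window.
#' @param alpha significance level.
#' @return character scalar classification.
#' @export
classify_species <- function(dist, valleys, dip_p, window = c(99.2, 99.8),
                             alpha = 0.05) {
  v <- if (inherits(dist, "ani_distribution")) dist$values else dist
  if (length(v) == 0L) return("no_gap")
  if (min(v) > 99.5) return("clonal")
  if (is.null(valleys) || nrow(valleys) == 0L || is.na(dip_p) || dip_p >= alpha)
    return("no_gap")
  if (any(valleys$midpoint >= window[1] & valleys$midpoint <= window[2]))
    return("gap_99.2_99.8")
  "shifted_gap"
}

#' Scan one species for intra-species ANI gaps
#'
#' The main fitting-style entry point of the gap analysis: computes the KDE
#' valley table, the dip statistic with its Monte-Carlo p-value, and the
#' species classification, and returns them as a single report with print,
#' summary and plot methods.
#'
#' @param values pairwise ANI percents (or an [ani_distribution()]).
#' @param species_id label for the report.
#' @param floor distribution floor (values at or below are dropped).
#' @param beta valley prominence cutoff, see [find_valleys()].
#' @param bandwidth KDE bandwidth (default 0.1 ANI units, see [find_valleys()]).
#' @param n_boot Monte-Carlo replicates for the dip test.
#' @param seed optional seed for the dip test.
#' @param null_dips optional precomputed [dip_null()] values.
#' @param window,alpha classification window and significance level.
#' @param grid,step KDE grid specification.
#' @return object of class `gap_report`.
#' @export
#' @examples
#' set.seed(1)
#' x <- c(rnorm(150, 99.0, 0.05), rnorm(150, 99.9, 0.02))
#' gap_scan(x, species_id = "demo", seed = 1)
gap_scan <- function(values, species_id = "species", floor = 95, beta = 0.5,
                     bandwidth = 0.1, n_boot = 2000L, seed = NULL,
                     null_dips = NULL, window = c(99.2, 99.8), alpha = 0.05,
                     grid = c(95, 100), step = 0.01) {
  dist <- if (inherits(values, "ani_distribution")) values
          else ani_distribution(values, species_id, floor)
  v <- dist$values
  valleys <- find_valleys(v, bandwidth = bandwidth, grid = grid,
                          step = step, beta = beta)
  D <- p <- NA_real_
  if (length(unique(v)) >= 4L) {
    ht <- dip_test(v, n_boot = n_boot, seed = seed, null_dips = null_dips)
    D <- unname(ht$statistic); p <- ht$p.value
  }
  cls <- classify_species(dist, valleys, p, window, alpha)
  structure(list(species_id = dist$species_id, n = dist$n, values = v,
                 floor = floor, valleys = valleys, dip = D, p_value = p,
                 n_boot = n_boot, classification = cls,
                 bandwidth = if (is.character(bandwidth) && length(v) >= 2) stats::bw.nrd0(v) else if (is.numeric(bandwidth)) bandwidth else NA_real_,
                 beta = beta, window = window, alpha = alpha,
                 grid = grid, step = step),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf("<gap_report> %s: n = %d pairs, classification = %s\n",
              x$species_id, x$n, x$classification))
  if (!is.na(x$dip))
    cat(sprintf("  dip D = %.4f, Monte-Carlo p = %.4g (%d replicates)\n",
                x$dip, x$p_value, x$n_boot))
  if (nrow(x$valleys)) {
    cat(sprintf("  %d valley(s):\n", nrow(x$valleys)))
    print(x$valleys, digits = 4)
  } else cat("  no valleys at beta =", x$beta, "\n")
  invisible(x)
}

#' @export
summary.gap_report <- function(object, ...) {
  cat(sprintf("Species %s: %d intra-species ANI values above %g%%\n",
              object$species_id, object$n, object$floor))
  if (object$n) {
    q <- stats::quantile(object$values, c(0, .25, .5, .75, 1))
    cat(sprintf("  range %.3f-%.3f, median %.3f\n", q[1], q[5], q[3]))
  }
  cat(sprintf("  dip D = %s, p = %s; KDE bandwidth = %s, beta = %g\n",
              format(object$dip, digits = 4), format(object$p_value, digits = 4),
              format(object$bandwidth, digits = 4), object$beta))
  cat(sprintf("  classification: %s\n", object$classification))
  if (nrow(object$valleys)) print(object$valleys, digits = 4)
  invisible(object)
}

#' @export
#' @importFrom graphics hist lines abline rect legend
plot.gap_report <- function(x, ...) {
  if (!length(x$values)) { plot.new(); return(invisible(x)) }
  h <- hist(x$values, breaks = seq(x$grid[1], x$grid[2], by = 0.05),
            plot = FALSE)
  d <- density(x$values, bw = x$bandwidth, from = x$grid[1], to = x$grid[2],
               n = round(diff(x$grid) / x$step) + 1L)
  plot(h, freq = FALSE, col = "grey85", border = "grey70",
       xlab = "ANI (%)", main = sprintf("%s: %s", x$species_id, x$classification),
       ...)
  lines(d, lwd = 2)
  if (nrow(x$valleys)) {
    for (i in seq_len(nrow(x$valleys)))
      rect(x$valleys$left[i], 0, x$valleys$right[i], max(d$y),
           col = grDevices::adjustcolor("firebrick", 0.15), border = NA)
    abline(v = x$valleys$midpoint, col = "firebrick", lty = 2)
  }
  invisible(x)
}

#' Modal gap location across species
#'
#' Pools the valley midpoints of many gap reports into 0.1%-wide bins centred
#' on multiples of 0.1 over `[95, 100]` and returns the centre of the fullest
#' bin; ties break toward higher ANI.
#'
#' @param reports list of `gap_report` objects (or a numeric vector of valley
#'   midpoints).
#' @return the modal midpoint (percent ANI).
#' @export
gap_mode <- function(reports) {
  mids <- if (is.numeric(reports)) reports
          else unlist(lapply(reports, function(r) r$valleys$midpoint))
  if (!length(mids)) stop("no valleys in any report")
  centers <- seq(95, 100, by = 0.1)
  bin <- findInterval(mids, centers - 0.05)
  bin[bin < 1L] <- 1L; bin[bin > length(centers)] <- length(centers)
  counts <- tabulate(bin, nbins = length(centers))
  centers[max(which(counts == max(counts)))]
}

#' Subsample the genomes behind a pair table
#'
#' Uniformly samples `k` genomes without replacement and restricts the pair
#' table to pairs within the sample -- the control showing that a gap is not
#' driven by unevenly sampled species.
#'
#' @param pairs an `ani_pair_table` (or data.frame with query_id/ref_id/ani).
#' @param k genomes to keep.
#' @param seed optional seed.
#' @return pair table restricted to the sampled genomes, or `NULL` (with a
#'   message) when fewer than `k` genomes are present.
#' @export
subsample_pairs <- function(pairs, k = 10L, seed = NULL) {
  ids <- sort(unique(c(pairs$query_id, pairs$ref_id)))
  if (length(ids) < k) {
    message(sprintf("skipping: %d genomes < k = %d", length(ids), k))
    return(NULL)
  }
  if (!is.null(seed)) set.seed(seed)
  keep <- sample(ids, k)
  out <- pairs[pairs$query_id %in% keep & pairs$ref_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Naive divergence-time closed form
#'
#' Years needed to accumulate a divergence fraction `d` at mutation rate `mu`
#' per site per generation and `g` generations per year, across `k` lineages
#' (2 when both lineages diverge from their common ancestor): `d / (k mu g)`.
#' Fixation of mutations is ignored, so this is a lower bound on the true
#' divergence time.
#'
#' @param d divergence fraction (e.g. 0.005 for 99.5% ANI).
#' @param mu per-site per-generation mutation rate.
#' @param g generations per year.
#' @param k number of diverging lineages (1 or 2).
#' @return time in years.
#' @export
#' @examples
#' divergence_time(0.005, 4e-10, 100)  # 62,500 years
divergence_time <- function(d, mu = 4e-10, g = 100, k = 2) {
  if (mu <= 0 || g <= 0) stop("rates must be positive")
  if (!k %in% c(1, 2)) stop("k must be 1 or 2")
  if (any(d < 0)) stop("divergence fraction must be nonnegative")
  d / (k * mu * g)
}
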