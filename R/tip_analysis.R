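# Shape metrics for protofilament traces, from simulations or from
# cryoET-derived point files: LOESS smoothing, curl origin and metrics,
# raggedness, adjacent-PF correlations, and synthetic fixture generation.

#' Protofilament trace
#'
#' An ordered 2D polyline of one PF in its radial plane: `z` axial (nm,
#' minus-to-plus order), `x` radial deviation from the MT wall (nm).
#'
#' @param z,x coordinates, nm.
#' @param mt_id microtubule identifier.
#' @param pf_index azimuthal PF index, 0-12.
#' @return an object of class `pf_trace`.
#' @examples
#' pf_trace(z = c(0, 4, 8), x = c(0, 0, 2))
#' @export
pf_trace <- function(z, x, mt_id = 1L, pf_index = 0L) {
  .check(length(z) == length(x), "z and x must have equal length")
  .check(length(z) >= 2, "a trace needs >= 2 points")
  structure(list(mt_id = mt_id, pf_index = as.integer(pf_index),
                 z = as.numeric(z), x = as.numeric(x)),
            class = "pf_trace")
}

#' @export
print.pf_trace <- function(x, ...) {
  cat(sprintf("pf_trace: mt %s pf %d, %d points, z %.1f..%.1f nm\n",
              x$mt_id, x$pf_index, length(x$z), min(x$z), max(x$z)))
  invisible(x)
}

.arclength <- function(tr) {
  c(0, cumsum(sqrt(diff(tr$z)^2 + diff(tr$x)^2)))
}

#' LOESS-smooth a trace
#'
#' Locally weighted regression of the radial deviation on arc length;
#' endpoints are retained and `z` is unchanged.  Already-smooth traces
#' pass through nearly unchanged.
#'
#' @param trace a [pf_trace()] with >= 4 points.
#' @param span LOESS span.
#' @param degree local polynomial degree.
#' @return the smoothed `pf_trace`.
#' @export
smooth_trace <- function(trace, span = 0.3, degree = 2) {
  .check(length(trace$z) >= 4, "need >= 4 points to smooth")
  s <- .arclength(trace)
  n <- length(s)
  # loess needs enough points in each window
  span <- max(span, (degree + 2) / n + 1e-9)
  fit <- loess(trace$x ~ s, degree = degree, span = span,
               family = "gaussian",
               control = stats::loess.control(surface = "direct"))
  xs <- predict(fit, newdata = data.frame(s = s))
  trace$x <- as.numeric(xs)
  trace
}

#' Curl origin of a trace
#'
#' The most minus-end proximal point from which the radial deviation
#' rises monotonically to the tip and exceeds `wall_tolerance`: walking
#' back from the tip-ward crossing of the tolerance, the origin is where
#' the deviation stops decreasing (the base of the outward excursion).  A
#' trace that never exceeds the tolerance is blunt (origin at the trace
#' end, curl length 0).
#'
#' @param trace a [pf_trace()] (smooth first for noisy data).
#' @param wall_tolerance deviation defining "off the wall", nm.
#' @param rise_tolerance minimum backward decrease per point still counted
#'   as part of the monotone rise, nm.
#' @return list with `origin_z`, `origin_index`, `blunt`.
#' @export
curl_origin <- function(trace, wall_tolerance = 1.5,
                        rise_tolerance = 0.02) {
  x <- trace$x
  n <- length(x)
  if (max(x) < wall_tolerance) {
    return(list(origin_z = trace$z[n], origin_index = n, blunt = TRUE))
  }
  below <- which(x < wall_tolerance)
  j <- if (length(below)) max(below) else 1L
  if (j == n) {  # dips back under tolerance at the very tip
    return(list(origin_z = trace$z[n], origin_index = n, blunt = TRUE))
  }
  while (j > 1 && x[j - 1] <= x[j] - rise_tolerance) j <- j - 1L
  list(origin_z = trace$z[j], origin_index = j, blunt = FALSE)
}

#' Curl length and mean curvature
#'
#' Contour length from the curl origin to the tip, and mean curvature as
#' the magnitude of the net turning angle divided by the contour length.
#'
#' @param trace a [pf_trace()].
#' @param origin result of [curl_origin()] (computed if missing).
#' @param ... passed to [curl_origin()].
#' @return list with `length` (nm) and `curvature` (rad/nm; `NA` for a
#'   blunt trace).
#' @examples
#' th <- seq(0, pi / 2, length.out = 40) # quarter circle, r = 20 nm
#' tr <- pf_trace(z = 20 * sin(th), x = 20 * (1 - cos(th)))
#' curl_metrics(tr, origin = list(origin_index = 1, blunt = FALSE))
#' @export
curl_metrics <- function(trace, origin = NULL, ...) {
  if (is.null(origin)) origin <- curl_origin(trace, ...)
  if (origin$blunt) return(list(length = 0, curvature = NA_real_))
  i <- origin$origin_index
  z <- trace$z[i:length(trace$z)]
  x <- trace$x[i:length(trace$x)]
  if (length(z) < 2) return(list(length = 0, curvature = NA_real_))
  seg <- sqrt(diff(z)^2 + diff(x)^2)
  len <- sum(seg)
  if (len <= 0) return(list(length = 0, curvature = NA_real_))
  ang <- atan2(diff(x), diff(z))
  if (length(ang) > 1) {  # unwrap: curls can turn past +/- pi
    dang <- ((diff(ang) + pi) %% (2 * pi)) - pi
    ang <- ang[1] + cumsum(c(0, dang))
  }
  # mean curvature = mean turning per unit contour length; estimated as
  # the least-squares slope of segment direction angle on mid-arc
  # position, which equals net-turn/length for a uniform arc but is far
  # less sensitive to endpoint noise
  curv <- if (length(ang) < 2) {
    0
  } else {
    smid <- cumsum(seg) - seg / 2
    sc <- smid - mean(smid)
    abs(sum(sc * ang) / sum(sc^2))
  }
  list(length = len, curvature = curv)
}

#' Raggedness of one microtubule tip
#'
#' Sample standard deviation (n - 1 denominator) of the axial positions
#' of the PF curl origins.
#'
#' @param origins numeric vector of curl-origin axial positions, nm
#'   (>= 2 values).
#' @return raggedness in nm.
#' @examples
#' raggedness(c(0, 6, 12)) # 6
#' @export
raggedness <- function(origins) {
  .check(length(origins) >= 2, "raggedness needs >= 2 scored PFs")
  sd(origins)
}

#' Per-PF tip metrics for a set of traces
#'
#' Smooths each trace (when it has enough points), locates the curl
#' origin and computes curl length and mean curvature.
#'
#' @param traces list of [pf_trace()] objects.
#' @param wall_tolerance,span see [curl_origin()] and [smooth_trace()].
#' @param smooth apply LOESS smoothing first.
#' @return data.frame with one row per trace: `mt_id`, `pf_index`,
#'   `origin_z`, `curl_length`, `curvature`, `blunt`.
#' @export
tip_metrics <- function(traces, wall_tolerance = 1.5, span = 0.3,
                        smooth = TRUE) {
  rows <- lapply(traces, function(tr) {
    if (smooth && length(tr$z) >= 4) tr <- smooth_trace(tr, span = span)
    o <- curl_origin(tr, wall_tolerance)
    m <- curl_metrics(tr, o)
    data.frame(mt_id = tr$mt_id, pf_index = tr$pf_index,
               origin_z = o$origin_z, curl_length = m$length,
               curvature = m$curvature, blunt = o$blunt)
  })
  do.call(rbind, rows)
}

#' Raggedness per microtubule from tip metrics
#'
#' @param metrics data.frame from [tip_metrics()].
#' @return data.frame with `mt_id`, `raggedness` (nm), `n_pf`.
#' @export
mt_raggedness <- function(metrics) {
  ids <- unique(metrics$mt_id)
  rows <- lapply(ids, function(id) {
    o <- metrics$origin_z[metrics$mt_id == id]
    data.frame(mt_id = id,
               raggedness = if (length(o) >= 2) raggedness(o)
                            else NA_real_,
               n_pf = length(o))
  })
  do.call(rbind, rows)
}

#' Spearman correlation between adjacent protofilaments
#'
#' Pools all azimuthally adjacent PF pairs (pf_index modulo 13) across
#' MTs and rank-correlates the chosen metric, with mid-ranked ties and
#' the large-sample two-tailed p value.
#'
#' @param metrics data.frame from [tip_metrics()].
#' @param metric `"length"` or `"curvature"`.
#' @param min_pairs minimum number of adjacent pairs required.
#' @return list with `r_s`, `p`, `n_pairs`, and `all_ties` (TRUE when the
#'   correlation is undefined because every value is identical).
#' @export
neighbor_correlation <- function(metrics,
                                 metric = c("length", "curvature"),
                                 min_pairs = 10) {
  metric <- match.arg(metric)
  col <- if (metric == "length") "curl_length" else "curvature"
  xs <- numeric(0)
  ys <- numeric(0)
  for (id in unique(metrics$mt_id)) {
    d <- metrics[metrics$mt_id == id & !is.na(metrics[[col]]), ]
    if (nrow(d) < 2) next
    idx <- d$pf_index
    for (i in seq_len(nrow(d))) {
      j <- which(idx == (idx[i] + 1) %% 13)
      if (length(j) == 1) {
        xs <- c(xs, d[[col]][i])
        ys <- c(ys, d[[col]][j])
      }
    }
  }
  .check(length(xs) >= min_pairs,
         sprintf("need >= %d adjacent pairs, got %d", min_pairs,
                 length(xs)))
  if (var(xs) == 0 || var(ys) == 0) {
    return(list(r_s = NA_real_, p = NA_real_, n_pairs = length(xs),
                all_ties = TRUE))
  }
  ct <- suppressWarnings(cor.test(xs, ys, method = "spearman",
                                  exact = FALSE))
  list(r_s = unname(ct$estimate), p = ct$p.value, n_pairs = length(xs),
       all_ties = FALSE)
}

# --- trace file I/O --------------------------------------------------------

#' Read and write protofilament trace files
#'
#' Plain tab-separated text with a header line and columns `mt_id`,
#' `pf_index`, `point_index`, `z_nm`, `x_nm`.  Partial rings (missing
#' PFs, as with the cryoET missing wedge) are fine: absent PFs are simply
#' absent.
#'
#' @param path file path.
#' @return `read_traces()`: list of [pf_trace()] objects.
#' @export
read_traces <- function(path) {
  .check(file.exists(path), paste("no such file:", path))
  d <- read.table(path, header = TRUE, sep = "\t")
  need <- c("mt_id", "pf_index", "point_index", "z_nm", "x_nm")
  .check(all(need %in% names(d)),
         paste("trace file must have columns:",
               paste(need, collapse = ", ")))
  keys <- unique(d[, c("mt_id", "pf_index")])
  lapply(seq_len(nrow(keys)), function(i) {
    s <- d[d$mt_id == keys$mt_id[i] & d$pf_index == keys$pf_index[i], ]
    s <- s[order(s$point_index), ]
    pf_trace(z = s$z_nm, x = s$x_nm, mt_id = keys$mt_id[i],
             pf_index = keys$pf_index[i])
  })
}

#' @rdname read_traces
#' @param traces list of [pf_trace()] objects.
#' @export
write_traces <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    data.frame(mt_id = tr$mt_id, pf_index = tr$pf_index,
               point_index = seq_along(tr$z) - 1L,
               z_nm = tr$z, x_nm = tr$x)
  })
  d <- do.call(rbind, rows)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate synthetic traces with known ground truth
#'
#' Each synthetic MT gets PF traces built from a straight wall segment
#' followed by a circular-arc curl of specified curvature and contour
#' length; curl origins are scattered with the requested spread and
#' Gaussian point noise is added to the radial deviation.  Useful as a
#' fixture generator for validating the trace metrics.
#'
#' @param n_mt number of MTs.
#' @param n_pf PFs per MT.
#' @param curvature true curl curvature, rad/nm.
#' @param curl_length true curl contour length, nm.
#' @param origin_spread sd of curl-origin axial positions, nm.
#' @param noise_sd Gaussian noise on radial deviation, nm.
#' @param spacing point spacing along the contour, nm.
#' @param wall_length straight wall segment length, nm.
#' @param seed RNG seed (deterministic output).
#' @param file optional path; when given, traces are written with
#'   [write_traces()] and a `<file>.truth.tsv` sidecar records the truth
#'   table.
#' @return list with `traces` and `truth` (data.frame).
#' @export
make_fixture_traces <- function(n_mt = 10, n_pf = 13, curvature = 0.05,
                                curl_length = 30, origin_spread = 6,
                                noise_sd = 0, spacing = 2,
                                wall_length = 40, seed = 1,
                                file = NULL) {
  rng <- .mini_rng(seed)
  norm2 <- function(n) {  # Box-Muller on the mini generator
    u1 <- pmax(rng(n), 1e-12)
    u2 <- rng(n)
    sqrt(-2 * log(u1)) * cos(2 * pi * u2)
  }
  traces <- list()
  truth <- list()
  for (m in seq_len(n_mt)) {
    origins <- wall_length + origin_spread * norm2(n_pf)
    for (p in seq_len(n_pf)) {
      o <- origins[p]
      s_wall <- seq(0, o, length.out = max(2, ceiling(o / spacing) + 1))
      s_curl <- seq(spacing, curl_length, by = spacing)
      th <- curvature * s_curl
      z <- c(s_wall, o + sin(th) / curvature)
      x <- c(rep(0, length(s_wall)), (1 - cos(th)) / curvature)
      if (noise_sd > 0) x <- x + noise_sd * norm2(length(x))
      traces[[length(traces) + 1]] <-
        pf_trace(z = z, x = x, mt_id = m, pf_index = p - 1L)
      truth[[length(truth) + 1]] <-
        data.frame(mt_id = m, pf_index = p - 1L, origin_z = o,
                   curl_length = curl_length, curvature = curvature)
    }
  }
  truth <- do.call(rbind, truth)
  if (!is.null(file)) {
    write_traces(traces, file)
    write.table(truth, paste0(file, ".truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(traces = traces, truth = truth)
}
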