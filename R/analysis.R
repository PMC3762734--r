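#' Conduction velocity from two probe traces
#'
#' CV is the distance between two probe nodes divided by the difference of
#' their upward threshold-crossing times, with linear sub-step interpolation
#' of the crossings.  The second probe never crossing means conduction
#' failure.
#'
#' @param t sample times (ms).
#' @param v1,v2 membrane-potential traces at the near and far probes (mV).
#' @param distance_mm probe separation (mm).
#' @param threshold activation threshold (mV).
#' @return list with `cv_cm_s` (magnitude, cm/s; `NA` on failure),
#'   `failed`, and the two crossing times.
#' @export
measure_cv <- function(t, v1, v2, distance_mm, threshold = -40) {
  t1 <- upstroke_times(v1, t, threshold, slope_thresh = 0)
  t2 <- upstroke_times(v2, t, threshold, slope_thresh = 0)
  if (!length(t1) || !length(t2))
    return(list(cv_cm_s = NA_real_, failed = TRUE,
                t_near = if (length(t1)) t1[1] else NA_real_,
                t_far = NA_real_))
  # mm/ms -> cm/s: x100
  list(cv_cm_s = distance_mm / (t2[1] - t1[1]) * 100, failed = FALSE,
       t_near = t1[1], t_far = t2[1])
}

#' Reference sodium-current strength for tip tracking
#'
#' Operational threshold used by [track_tip()]: the minimum peak |I_Na| that
#' still yields an action potential.  It is found by bisecting the 3-ms
#' stimulus amplitude down to the excitation threshold of the isolated
#' myocyte and recording the peak |I_Na| of the weakest AP.  Cached per
#' parameter set.
#'
#' @param params [tnnp_params()].
#' @param frac fraction of the reference used as the tracking threshold
#'   (the spiral-arm locus is drawn where |I_Na| exceeds `frac` times the
#'   reference; 1 is the strict definition, the default 0.5 keeps the locus
#'   contiguous on coarsely sampled frames).
#' @return threshold in pA/pF (positive number, compared against |I_Na|).
#' @export
ina_reference_threshold <- function(params = tnnp_params(), frac = 0.5) {
  key <- .cache_key("ina-ref", unclass(params))
  ref <- .cache_get(key, function() {
    rest <- myocyte_resting_state(params)
    fires <- function(amp) {
      cfg <- composite_config(N_f = 0, params = params)
      out <- .cpp_run_composite(unname(rest), numeric(0), unclass(params),
                                1, 0, 0, 0, myocyte_capacitance_pF(params),
                                stim_events(5, 3, -amp), 0.02, 60,
                                sample_every = 5L, record_currents = TRUE,
                                rush_larsen = TRUE)
      list(fired = max(out$V_m) > 0, peak_ina = max(abs(out$currents[, 1])))
    }
    lo <- 0; hi <- 52
    if (!fires(hi)$fired) stop("reference stimulus does not excite the cell")
    for (k in 1:20) {
      mid <- (lo + hi) / 2
      if (fires(mid)$fired) hi <- mid else lo <- mid
    }
    fires(hi)$peak_ina
  })
  frac * ref
}

#' Track spiral-wave tips through the sodium-current locus
#'
#' The depolarization front of a wave appears as a thin line of strong
#' inward sodium current; for a spiral this line terminates at the tip,
#' where wave front and wave back meet.  Per frame the tracker thresholds
#' |I_Na|, extracts connected components, finds each component's two
#' geodesically most distant pixels (the line's endpoints), and keeps
#' endpoints that lie in the domain interior -- a plane wave's front line
#' ends on the boundary and yields no tip.  The reported position is the
#' centroid of the component pixels within 2 nodes of the endpoint
#' (sub-node refinement).
#'
#' @param archive an `mf_archive` containing `I_Na` frames.
#' @param threshold |I_Na| threshold (pA/pF); default from
#'   [ina_reference_threshold()].
#' @param params ionic parameters for the default threshold.
#' @param min_pixels components smaller than this are ignored (noise).
#' @param boundary_margin endpoints within this many nodes of the domain
#'   edge are not tips.
#' @param dilate binary dilations applied to the thresholded mask before
#'   component labelling; bridges one-node gaps in the front line.
#' @return a `tip_trajectory` data frame: `t`, `x_mm`, `y_mm` (first tip,
#'   `NA` when none), `n_tips`.
#' @export
track_tip <- function(archive, threshold = NULL, params = tnnp_params(),
                      min_pixels = 6, boundary_margin = 3, dilate = 1) {
  stopifnot(inherits(archive, "mf_archive"))
  if (is.null(threshold)) threshold <- ina_reference_threshold(params)
  last <- c(NA_real_, NA_real_)
  res <- lapply(seq_along(archive$t), function(k) {
    ina <- archive$frames[[k]]$I_Na
    if (is.null(ina)) stop("archive has no I_Na field")
    orig <- abs(ina) > threshold
    mask <- orig
    for (d in seq_len(dilate)) mask <- .dilate(mask)
    tips <- .frame_tips(mask, archive$dx, min_pixels, boundary_margin, orig)
    if (!nrow(tips))
      return(c(t = archive$t[k], x_mm = NA_real_, y_mm = NA_real_,
               n_tips = 0))
    # when the thresholded arm fragments, several endpoints can qualify;
    # follow the one continuous with the previous frame
    pick <- 1L
    if (nrow(tips) > 1 && !is.na(last[1]))
      pick <- which.min((tips[, 1] - last[1])^2 + (tips[, 2] - last[2])^2)
    last <<- tips[pick, ]
    c(t = archive$t[k], x_mm = tips[pick, 1], y_mm = tips[pick, 2],
      n_tips = nrow(tips))
  })
  out <- as.data.frame(do.call(rbind, res))
  class(out) <- c("tip_trajectory", "data.frame")
  out
}

# 4-neighbour binary dilation
.dilate <- function(m) {
  d <- m
  nr <- nrow(m); nc <- ncol(m)
  d[-1, ] <- d[-1, ] | m[-nr, ]
  d[-nr, ] <- d[-nr, ] | m[-1, ]
  d[, -1] <- d[, -1] | m[, -nc]
  d[, -nc] <- d[, -nc] | m[, -1]
  d
}

# endpoints of thresholded front lines in one frame; returns matrix (x,y) mm
# (`orig` = pre-dilation mask used for the sub-node centroid refinement)
.frame_tips <- function(mask, dx, min_pixels, boundary_margin, orig = mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- .label_components(mask)
  tips <- matrix(numeric(0), 0, 2)
  if (lab$n == 0) return(tips)
  for (comp in seq_len(lab$n)) {
    px <- which(lab$label == comp, arr.ind = TRUE)
    if (nrow(px) < min_pixels) next
    # two BFS passes give the geodesic diameter endpoints of the line
    e1 <- .bfs_farthest(px, px[1, ])
    e2 <- .bfs_farthest(px, e1)
    for (e in list(e1, e2)) {
      if (e[1] <= boundary_margin || e[1] > nx - boundary_margin ||
          e[2] <= boundary_margin || e[2] > ny - boundary_margin) next
      po <- which(orig & lab$label == comp, arr.ind = TRUE)
      near <- po[abs(po[, 1] - e[1]) <= 2 & abs(po[, 2] - e[2]) <= 2, ,
                 drop = FALSE]
      if (!nrow(near)) near <- matrix(e, 1, 2)
      tips <- rbind(tips, (colMeans(near) - 1) * dx)
    }
  }
  tips
}

# 8-connected component labelling by BFS (plain R; frames are small)
.label_components <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  n <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    n <- n + 1L
    queue <- start
    lab[start] <- n
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (cur - 1L) %% nx + 1L
      j <- (cur - 1L) %/% nx + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nx || jj < 1 || jj > ny) next
        id <- (jj - 1L) * nx + ii
        if (mask[id] && lab[id] == 0L) {
          lab[id] <- n
          queue <- c(queue, id)
        }
      }
    }
  }
  list(label = lab, n = n)
}

# farthest pixel (geodesic, 8-connectivity within the pixel set) from `from`
.bfs_farthest <- function(px, from) {
  key <- paste(px[, 1], px[, 2])
  dist <- rep(NA_integer_, nrow(px))
  names(dist) <- key
  dist[paste(from[1], from[2])] <- 0L
  frontier <- matrix(from, 1, 2)
  d <- 0L
  last <- from
  while (nrow(frontier)) {
    d <- d + 1L
    cand <- unique(do.call(rbind, lapply(seq_len(nrow(frontier)), function(r) {
      cbind(frontier[r, 1] + rep(-1:1, 3), frontier[r, 2] + rep(-1:1, each = 3))
    })))
    k <- paste(cand[, 1], cand[, 2])
    keep <- k %in% names(dist) & is.na(dist[k])
    if (!any(keep)) break
    cand <- cand[keep, , drop = FALSE]
    dist[paste(cand[, 1], cand[, 2])] <- d
    frontier <- cand
    last <- cand[1, ]
  }
  as.numeric(last)
}

#' Isopotential cross-check tip tracker
#'
#' Independent of the sodium-current tracker: the tip is located where the
#' V = `v_iso` isoline meets the dV/dt = 0 line, approximated on cells of
#' the lattice from two consecutive `V_m` frames.
#'
#' @param vm1,vm2 consecutive `V_m` frames (matrices).
#' @param frame_dt their separation (ms).
#' @param dx lattice spacing (mm).
#' @param v_iso isopotential value (mV).
#' @return matrix of tip positions (x_mm, y_mm), possibly empty.
#' @export
tip_isopotential <- function(vm1, vm2, frame_dt, dx = 0.225, v_iso = -35) {
  a <- vm2 - v_iso
  b <- (vm2 - vm1) / frame_dt
  nx <- nrow(a); ny <- ncol(a)
  # cells whose 4 corners straddle zero in both fields
  sa <- a > 0; sb <- b > 0
  f <- function(s) {
    c00 <- s[-nx, -ny]; c10 <- s[-1, -ny]; c01 <- s[-nx, -1]; c11 <- s[-1, -1]
    n <- c00 + c10 + c01 + c11
    n > 0 & n < 4
  }
  hit <- f(sa) & f(sb)
  idx <- which(hit, arr.ind = TRUE)
  if (!nrow(idx)) return(matrix(numeric(0), 0, 2,
                                dimnames = list(NULL, c("x_mm", "y_mm"))))
  pts <- cbind(x_mm = (idx[, 1] - 0.5) * dx, y_mm = (idx[, 2] - 0.5) * dx)
  # cluster contiguous hit cells and return one centroid per cluster
  lab <- .label_components(hit)
  out <- t(vapply(seq_len(lab$n), function(k) {
    px <- which(lab$label == k, arr.ind = TRUE)
    c((mean(px[, 1]) - 0.5) * dx, (mean(px[, 2]) - 0.5) * dx)
  }, numeric(2)))
  colnames(out) <- c("x_mm", "y_mm")
  out
}

#' Beat statistics at a probe
#'
#' Upstrokes are upward crossings of `v_thresh` with dV/dt above
#' `slope_thresh`; the inter-beat intervals (ibi) are their successive
#' differences.  The power spectrum is the magnitude-squared discrete
#' Fourier transform (plain periodogram, no window) of the mean-removed
#' series; its frequency resolution is `1/(N dt)`.
#'
#' @param v membrane-potential series (mV).
#' @param dt_sample sample spacing (ms).
#' @param v_thresh,slope_thresh upstroke detection thresholds.
#' @return a `beat_series` list: `upstrokes` (ms), `ibi` (ms), `freq` (Hz),
#'   `power`, `df_Hz` (resolution).
#' @export
beat_statistics <- function(v, dt_sample, v_thresh = -40, slope_thresh = 5) {
  t <- (seq_along(v) - 1) * dt_sample
  up <- upstroke_times(v, t, v_thresh, slope_thresh)
  x <- v - mean(v)
  pw <- Mod(fft(x))^2
  n <- length(v)
  df <- 1 / (n * dt_sample * 1e-3)   # Hz
  half <- seq_len(floor(n / 2))
  structure(list(upstrokes = up, ibi = diff(up),
                 freq = (half - 1) * df, power = pw[half], df_Hz = df),
            class = "beat_series")
}

#' Spiral rotation period
#'
#' From a [beat_statistics()] object the period is the mean ibi (with its
#' spread); from a [track_tip()] trajectory it is the mean time per full
#' revolution of the tip about the trajectory centroid (unwrapped angle).
#' The two estimators agree for a rigidly rotating spiral and are
#' cross-checked in the package tests.
#'
#' @param x a `beat_series` or `tip_trajectory`.
#' @return list with `period_ms`, `sd_ms` and `n` (intervals/revolutions).
#' @export
rotation_period <- function(x) {
  if (inherits(x, "beat_series")) {
    if (length(x$ibi) < 1) return(list(period_ms = NA_real_, sd_ms = NA_real_,
                                       n = 0))
    return(list(period_ms = mean(x$ibi),
                sd_ms = if (length(x$ibi) > 1) sd(x$ibi) else 0,
                n = length(x$ibi)))
  }
  if (inherits(x, "tip_trajectory")) {
    ok <- is.finite(x$x_mm) & is.finite(x$y_mm)
    if (sum(ok) < 8) return(list(period_ms = NA_real_, sd_ms = NA_real_, n = 0))
    px <- x$x_mm[ok] - mean(x$x_mm[ok])
    py <- x$y_mm[ok] - mean(x$y_mm[ok])
    th <- atan2(py, px)
    dth <- diff(th)
    dth <- ifelse(dth > pi, dth - 2 * pi, ifelse(dth < -pi, dth + 2 * pi, dth))
    total <- abs(sum(dth))
    if (total < 4 * pi) return(list(period_ms = NA_real_, sd_ms = NA_real_,
                                    n = floor(total / (2 * pi))))
    tt <- x$t[ok]
    return(list(period_ms = (max(tt) - min(tt)) / (total / (2 * pi)),
                sd_ms = NA_real_, n = floor(total / (2 * pi))))
  }
  stop("x must be a beat_series or tip_trajectory")
}

#' Classify wave dynamics inside and outside an inhomogeneity
#'
#' A probe series is periodic when the coefficient of variation of its ibi
#' is below `cv_limit` and its periodogram is dominated by a single line
#' (the fundamental and its harmonics).  A spiral is anchored to the patch
#' when the centroid of its tip trajectory stays inside the patch bounding
#' box over the analysis window.
#'
#' @param beats_inside,beats_outside [beat_statistics()] at probes inside
#'   and outside the patch.
#' @param trajectory optional [track_tip()] trajectory.
#' @param patch_bbox_mm numeric (x0, y0, x1, y1), the patch bounding box.
#' @param cv_limit periodicity limit on cv(ibi) (default 5%).
#' @return list with `inside`, `outside` ("periodic"/"nonperiodic"),
#'   `anchored` (logical or `NA` without a trajectory).
#' @export
classify_inhomogeneity_dynamics <- function(beats_inside, beats_outside,
                                            trajectory = NULL,
                                            patch_bbox_mm = NULL,
                                            cv_limit = 0.05) {
  lab <- function(b) {
    if (length(b$ibi) < 3) return("nonperiodic")
    if (sd(b$ibi) / mean(b$ibi) < cv_limit) "periodic" else "nonperiodic"
  }
  anchored <- NA
  if (!is.null(trajectory) && !is.null(patch_bbox_mm)) {
    ok <- is.finite(trajectory$x_mm)
    cx <- mean(trajectory$x_mm[ok]); cy <- mean(trajectory$y_mm[ok])
    anchored <- isTRUE(cx >= patch_bbox_mm[1] && cx <= patch_bbox_mm[3] &&
                       cy >= patch_bbox_mm[2] && cy <= patch_bbox_mm[4])
  }
  list(inside = lab(beats_inside), outside = lab(beats_outside),
       anchored = anchored)
}
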