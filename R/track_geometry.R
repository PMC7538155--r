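#' Fit the apical surface with second-degree polynomials
#'
#' The apical tissue surface is summarized by least-squares quadratics fitted
#' to contour points in the XY and YZ planes (the way apical contours are
#' drawn on microscopy slices to separate progenitor nuclei from the
#' pigmented epithelium).
#'
#' @param contour_points data frame with columns `x`, `y`, `z` (µm); at
#'   least 6 points, not collinear in the fitted planes.
#' @return An object of class `apical_surface_fit` with `coeffs_xy`
#'   (quadratic `y ~ x`), `coeffs_yz` (quadratic `z ~ y`), and `rmse` (µm,
#'   pooled over both plane fits).
#' @export
fit_apical_surface <- function(contour_points) {
  stopifnot(all(c("x", "y", "z") %in% names(contour_points)))
  if (nrow(contour_points) < 6L) stop("need at least 6 contour points")
  fit_plane <- function(u, v) {
    if (diff(range(u)) < 1e-9) stop("degenerate (collinear) contour points")
    X <- cbind(1, u, u^2)
    qrX <- qr(X)
    if (qrX$rank < 3L) stop("degenerate (collinear) contour points")
    beta <- qr.coef(qrX, v)
    resid <- v - X %*% beta
    list(coeffs = as.numeric(beta), ss = sum(resid^2), n = length(v))
  }
  fxy <- fit_plane(contour_points$x, contour_points$y)
  fyz <- fit_plane(contour_points$y, contour_points$z)
  rmse <- sqrt((fxy$ss + fyz$ss) / (fxy$n + fyz$n))
  structure(
    list(coeffs_xy = fxy$coeffs, coeffs_yz = fyz$coeffs, rmse = rmse),
    class = "apical_surface_fit"
  )
}

#' Local sphere geometry implied by an apical surface fit
#'
#' Near the pole of a sphere of radius `a`, a plane contour through the pole
#' is a parabola with quadratic coefficient `-1/(2a)` (Taylor expansion), so
#' the fitted curvatures estimate `a`.
#'
#' @param fit an [fit_apical_surface()] result.
#' @return Estimated apical radius (µm), averaged over the two planes.
#' @export
apical_radius_from_fit <- function(fit) {
  stopifnot(inherits(fit, "apical_surface_fit"))
  k <- abs(c(2 * fit$coeffs_xy[3], 2 * fit$coeffs_yz[3]))
  if (all(k < 1e-12)) {
    return(Inf)
  }
  mean(1 / k[k > 1e-12])
}

#' Convert Cartesian tracks to apicobasal (radial) coordinates
#'
#' The radial coordinate is `r = a - l_n`, where `l_n` is the distance from
#' the nuclear center to the apical surface. For the spherical-shell
#' idealization with the lens center at the origin, `r` is simply the
#' Euclidean distance to the origin.
#'
#' @param tracks a track data frame (see [tracks]).
#' @param geometry a [shell_geometry()] sharing the track coordinate frame.
#' @param delta_r measurement tolerance (µm) beyond `[b, a]` before a
#'   position is flagged.
#' @return A data frame `track_id`, `parent_id`, `t_min`, `r_um`,
#'   `l_um = a - r`, and logical `flagged` for positions outside
#'   `[b - delta_r, a + delta_r]` (flagged, never clipped). Carries over the
#'   `meta` attribute when present.
#' @export
to_radial <- function(tracks, geometry, delta_r = 3) {
  stopifnot(inherits(geometry, "shell_geometry"))
  r <- sqrt(tracks$x_um^2 + tracks$y_um^2 + tracks$z_um^2)
  out <- data.frame(
    track_id = tracks$track_id, parent_id = tracks$parent_id,
    t_min = tracks$t_min, r_um = r, l_um = geometry$a - r,
    flagged = r < geometry$b - delta_r | r > geometry$a + delta_r
  )
  attr(out, "meta") <- attr(tracks, "meta")
  attr(out, "geometry") <- geometry
  out
}

#' Signed apicobasal speeds and positions over the normalized cell cycle
#'
#' For tracks covering a complete cycle, time is normalized to `[0, 1]`
#' between birth and division, and the signed apicobasal speed is computed
#' by centered finite differences of `r` (one-sided at the endpoints);
#' basalward motion (decreasing `r`) is positive.
#'
#' @param radial_tracks output of [to_radial()], whose `meta` attribute
#'   identifies complete cycles (`fate == "divided"`).
#' @param min_frames tracks shorter than this are excluded (a message
#'   reports the count).
#' @return Data frame `track_id`, `t_min`, `t_norm`, `r_um`, `l_um`,
#'   `speed_um_min`.
#' @export
cycle_normalized_kinematics <- function(radial_tracks, min_frames = 3L) {
  meta <- attr(radial_tracks, "meta")
  if (is.null(meta)) stop("radial_tracks lacks the meta attribute")
  complete <- meta$track_id[meta$fate == "divided"]
  keep <- radial_tracks[radial_tracks$track_id %in% complete, , drop = FALSE]
  pieces <- split(keep, keep$track_id)
  short <- vapply(pieces, function(p) nrow(p) < min_frames, logical(1))
  if (any(short)) {
    message(sum(short), " track(s) shorter than ", min_frames,
            " frames excluded")
    pieces <- pieces[!short]
  }
  out <- lapply(pieces, function(p) {
    p <- p[order(p$t_min), , drop = FALSE]
    n <- nrow(p)
    dt <- diff(p$t_min)
    v <- numeric(n)
    v[1] <- (p$r_um[2] - p$r_um[1]) / dt[1]
    v[n] <- (p$r_um[n] - p$r_um[n - 1]) / dt[n - 1]
    if (n > 2L) {
      v[2:(n - 1)] <- (p$r_um[3:n] - p$r_um[1:(n - 2)]) /
        (p$t_min[3:n] - p$t_min[1:(n - 2)])
    }
    span <- max(p$t_min) - min(p$t_min)
    data.frame(
      track_id = p$track_id, t_min = p$t_min,
      t_norm = if (span > 0) (p$t_min - min(p$t_min)) / span else 0,
      r_um = p$r_um, l_um = p$l_um,
      speed_um_min = -v # basalward (decreasing r) positive
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Correlation between a nucleus' speed and its neighbours' mean speed
#'
#' Neighbours of a focal nucleus at a given frame are nuclei whose centers
#' fall within a cylinder aligned with the local apicobasal (radial)
#' direction: half-height `long_axis` and radius `short_axis` (i.e. height
#' and base diameter twice the nuclear long/short axes). Speeds are signed
#' apicobasal speeds; the neighbour speed may be taken at a lag of -1, 0 or
#' +1 frames. Pearson correlations are reported pooled and within the eight
#' categories (neighbour apical/basal of focal) x (neighbour moving
#' apicalward/basalward) x (same/opposite direction as focal), computed per
#' (nucleus, time point) pair.
#'
#' @param tracks Cartesian track data frame.
#' @param geometry a [shell_geometry()].
#' @param long_axis nuclear long axis (µm); default 5.3.
#' @param short_axis nuclear short axis (µm); default 3.5.
#' @param lag neighbour speed lag in frames (-1, 0, +1).
#' @param min_pairs categories with fewer pairs are reported as `NA`.
#' @return Data frame with `category`, `n_pairs`, `correlation`, `ci_lo`,
#'   `ci_hi`.
#' @export
neighbor_speed_correlation <- function(tracks, geometry,
                                       long_axis = 5.3, short_axis = 3.5,
                                       lag = 0L, min_pairs = 10L) {
  stopifnot(lag %in% c(-1L, 0L, 1L))
  tr <- tracks[order(tracks$track_id, tracks$t_min), , drop = FALSE]
  r <- sqrt(tr$x_um^2 + tr$y_um^2 + tr$z_um^2)
  # per-track centered-difference radial velocity (apicalward positive here)
  v <- rep(NA_real_, nrow(tr))
  idx_by_track <- split(seq_len(nrow(tr)), tr$track_id)
  for (ii in idx_by_track) {
    n <- length(ii)
    if (n < 3L) next
    v[ii[2:(n - 1)]] <- (r[ii[3:n]] - r[ii[1:(n - 2)]]) /
      (tr$t_min[ii[3:n]] - tr$t_min[ii[1:(n - 2)]])
  }
  frame_ids <- paste(tr$track_id, tr$t_min)
  lag_dt <- lag * infer_frame_dt(tr)
  v_lagged <- v[match(paste(tr$track_id, tr$t_min + lag_dt), frame_ids)]

  focal <- numeric(0); nbr <- numeric(0)
  cat_apical <- logical(0); cat_dir <- logical(0); cat_same <- logical(0)
  for (t0 in unique(tr$t_min)) {
    at <- which(tr$t_min == t0 & !is.na(v))
    if (length(at) < 2L) next
    P <- cbind(tr$x_um[at], tr$y_um[at], tr$z_um[at])
    rr <- r[at]
    U <- P / rr # radial unit vectors
    for (a_i in seq_along(at)) {
      d <- t(t(P) - P[a_i, ])
      axial <- drop(d %*% U[a_i, ])
      lat2 <- rowSums(d^2) - axial^2
      is_nb <- abs(axial) <= long_axis & lat2 <= short_axis^2
      is_nb[a_i] <- FALSE
      is_nb <- is_nb & !is.na(v_lagged[at])
      if (!any(is_nb)) next
      vf <- v[at[a_i]]
      vn <- v_lagged[at[is_nb]]
      focal <- c(focal, rep(abs(vf), sum(is_nb)))
      nbr <- c(nbr, abs(vn))
      cat_apical <- c(cat_apical, axial[is_nb] > 0)
      cat_dir <- c(cat_dir, vn > 0)
      cat_same <- c(cat_same, sign(vn) == sign(vf))
    }
  }
  cor_row <- function(mask, label) {
    n <- sum(mask)
    if (n < min_pairs || stats::sd(focal[mask]) == 0 ||
        stats::sd(nbr[mask]) == 0) {
      return(data.frame(category = label, n_pairs = n, correlation = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_))
    }
    ct <- stats::cor.test(focal[mask], nbr[mask])
    data.frame(category = label, n_pairs = n,
               correlation = unname(ct$estimate),
               ci_lo = ct$conf.int[1], ci_hi = ct$conf.int[2])
  }
  rows <- list(cor_row(rep(TRUE, length(focal)), "pooled"))
  for (ap in c(TRUE, FALSE)) {
    for (dir_ap in c(TRUE, FALSE)) {
      for (same in c(TRUE, FALSE)) {
        label <- paste0(
          if (ap) "apical" else "basal", "_",
          if (dir_ap) "movingApical" else "movingBasal", "_",
          if (same) "same" else "opposite"
        )
        rows <- c(rows, list(cor_row(
          cat_apical == ap & cat_dir == dir_ap & cat_same == same, label
        )))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

infer_frame_dt <- function(tracks) {
  dt <- diff(sort(unique(tracks$t_min)))
  if (!length(dt)) {
    return(NA_real_)
  }
  min(dt)
}

#' Experimental-style mean squared displacement of early-born nuclei
#'
#' Mirrors the cohort selection used for tracked data: among tracks with at
#' least `min_len` frames inside the observation `window` (samples beyond
#' the window are clipped), the `n_select` earliest-born are aligned to
#' their birth times, and the MSD of the radial displacement from the birth
#' position is averaged across tracks per cell-cycle lag.
#'
#' @param radial_tracks output of [to_radial()] (needs the `meta`
#'   attribute for birth times).
#' @param n_select cohort size; default 40.
#' @param min_len minimum number of frames per track; default 75.
#' @param window observation window (min) the track must fall inside;
#'   default 200.
#' @return Data frame `lag_min`, `msd_um2`, `n_contributing`.
#' @export
experimental_msd <- function(radial_tracks, n_select = 40L, min_len = 75L,
                             window = 200) {
  meta <- attr(radial_tracks, "meta")
  if (is.null(meta)) stop("radial_tracks lacks the meta attribute")
  clipped <- radial_tracks[radial_tracks$t_min <= window, , drop = FALSE]
  pieces <- split(clipped, clipped$track_id)
  qual <- vapply(pieces, function(p) nrow(p) >= min_len, logical(1))
  pieces <- pieces[qual]
  births <- meta$birth_t[match(
    as.numeric(names(pieces)), meta$track_id
  )]
  if (length(pieces) < n_select) {
    stop("only ", length(pieces), " qualifying tracks; need ", n_select)
  }
  sel <- order(births)[seq_len(n_select)]
  pieces <- pieces[sel]
  disp2 <- lapply(pieces, function(p) {
    p <- p[order(p$t_min), , drop = FALSE]
    lag <- p$t_min - p$t_min[1]
    data.frame(lag_min = lag, d2 = (p$r_um - p$r_um[1])^2)
  })
  all <- do.call(rbind, disp2)
  agg <- stats::aggregate(d2 ~ lag_min, data = all, FUN = mean)
  cnt <- stats::aggregate(d2 ~ lag_min, data = all, FUN = length)
  out <- data.frame(
    lag_min = agg$lag_min, msd_um2 = agg$d2, n_contributing = cnt$d2
  )
  out[order(out$lag_min), , drop = FALSE]
}
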