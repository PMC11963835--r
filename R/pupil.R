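#' Direct least-squares ellipse fit
#'
#' Fits the conic `A x^2 + B xy + C y^2 + D x + E y + F = 0` to a set of
#' points with the ellipse-specific constraint `4AC - B^2 = 1` (direct
#' least-squares fit), then converts to center, semi-axes and orientation.
#'
#' @param x,y Point coordinates (at least 5 points, not collinear).
#' @return A list with `cx`, `cy`, `a` (semi-major), `b` (semi-minor),
#'   `orientation_deg` (angle of the major axis from the x axis, in
#'   `(-90, 90]`), or `NULL` when the fit fails.
#' @keywords internal
fit_ellipse <- function(x, y) {
  if (length(x) < 5) return(NULL)
  # center/scale for conditioning
  mx <- mean(x); my <- mean(y)
  sc <- max(stats::sd(x), stats::sd(y), 1e-9)
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T0 <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T0)) return(NULL)
  M <- S1 + S2 %*% T0
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- tryCatch(eigen(M2), error = function(e) NULL)
  if (is.null(ev)) return(NULL)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  idx <- which(cond > 0)
  if (length(idx) == 0) return(NULL)
  v1 <- V[, idx[1]]
  par <- c(v1, as.vector(T0 %*% v1))  # A B C D E F in scaled coords
  A <- par[1]; B <- par[2]; C <- par[3]; D <- par[4]; E <- par[5]; F0 <- par[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) return(NULL)
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 + F0 * B^2 - B * D * E - 4 * A * C * F0)
  s <- sqrt((A - C)^2 + B^2)
  a2 <- num * (A + C + s) / den^2
  b2 <- num * (A + C - s) / den^2
  if (!is.finite(a2) || !is.finite(b2) || a2 <= 0 || b2 <= 0) return(NULL)
  semi <- sort(sqrt(c(a2, b2)), decreasing = TRUE)
  theta <- 0.5 * atan2(-B, C - A)
  list(cx = cx * sc + mx, cy = cy * sc + my,
       a = semi[1] * sc, b = semi[2] * sc,
       orientation_deg = wrap180(rad2deg(theta)))
}

pupil_failure <- function(reason, threshold = NA_real_) {
  tibble(ok = FALSE, cx = NA_real_, cy = NA_real_, a = NA_real_, b = NA_real_,
         orientation_deg = NA_real_, area_px = NA_real_,
         threshold = threshold, failure_reason = reason)
}

# boundary of a logical mask: pixels with at least one 4-neighbour outside
mask_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  core <- pad[2:(h + 1), 2:(w + 1)]
  interior <- core &
    pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  core & !interior
}

#' Detect the pupil in a single frame
#'
#' Binarizes the frame (automatic minimum-variance threshold by default, or a
#' fixed value), keeps the largest dark connected component above a minimum
#' area fraction, fills its holes (specular highlights), and fits an ellipse
#' to its boundary. Failures never fabricate a center: `ok = FALSE` with a
#' `failure_reason` of `no_dark_region`, `too_small`, `multiple_ambiguous`
#' (two dark components within 20% in size) or `fit_failed`.
#'
#' @param frame A single-channel intensity matrix (dark pupil on a brighter
#'   iris/sclera).
#' @param threshold Fixed binarization threshold; `NULL` for automatic
#'   (Otsu).
#' @param min_area_frac Minimum component area as a fraction of the frame.
#' @param ambiguity_frac Components within this relative size of the largest
#'   make the detection ambiguous.
#' @return A one-row tibble: `ok`, `cx`, `cy` (px), `a`, `b` (semi-axes, px),
#'   `orientation_deg`, `area_px`, `threshold`, `failure_reason`.
#' @export
detect_pupil <- function(frame, threshold = NULL, min_area_frac = 0.005,
                         ambiguity_frac = 0.2) {
  if (!is.matrix(frame) || !is.numeric(frame)) {
    stop_invalid("`frame` must be a numeric matrix.", "povar_invalid_parameter")
  }
  if (diff(range(frame)) < 0.02) return(pupil_failure("no_dark_region"))
  thr <- threshold %||%
    EBImage::otsu(EBImage::Image(frame), range = range(frame))
  mask <- frame < thr
  if (!any(mask)) return(pupil_failure("no_dark_region", thr))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask + 0)))
  sizes <- tabulate(lab[lab > 0])
  largest <- which.max(sizes)
  if (sizes[largest] < min_area_frac * length(frame)) {
    return(pupil_failure("too_small", thr))
  }
  rivals <- which(sizes >= (1 - ambiguity_frac) * sizes[largest])
  if (length(rivals) > 1) return(pupil_failure("multiple_ambiguous", thr))
  comp <- lab == largest
  comp <- EBImage::imageData(EBImage::fillHull(EBImage::Image(comp + 0))) > 0
  bnd <- which(mask_boundary(comp), arr.ind = TRUE)
  fit <- fit_ellipse(x = bnd[, "col"], y = bnd[, "row"])
  if (is.null(fit) ||
      fit$cx < 1 || fit$cx > ncol(frame) || fit$cy < 1 || fit$cy > nrow(frame)) {
    return(pupil_failure("fit_failed", thr))
  }
  tibble(ok = TRUE, cx = fit$cx, cy = fit$cy, a = fit$a, b = fit$b,
         orientation_deg = fit$orientation_deg, area_px = sum(comp),
         threshold = thr, failure_reason = "none")
}

#' Track the pupil across a frame stack and calibrate to degrees
#'
#' Runs [detect_pupil()] on every frame and converts centers to gaze angles
#' with a linear calibration: `h = (cx - origin_x) * scale` and
#' `v = -(cy - origin_y) * scale` (image y grows downward, so up is
#' positive). Failed frames are linearly interpolated when the gap is at most
#' `max_gap` samples, otherwise marked as artifacts.
#'
#' @param frames A list of single-channel matrices (>= 2 frames).
#' @param scale Degrees per pixel (> 0).
#' @param origin Primary gaze position `c(x, y)` in pixels; defaults to the
#'   frame center.
#' @param sampling_rate Frames per second.
#' @param max_gap Longest run of failed frames to bridge by interpolation.
#' @param sign_flip Multiply the horizontal channel by -1 (mirror optics make
#'   the horizontal sign per-camera; it must be configured, never inferred).
#' @inheritParams detect_pupil
#' @return A trace tibble: `time_s`, `h_deg`, `v_deg`, `quality`
#'   (`"ok"`, `"interpolated"` or `"artifact"`).
#' @export
track_frames <- function(frames, scale = 0.2, origin = NULL,
                         sampling_rate = 60, max_gap = 3, threshold = NULL,
                         sign_flip = FALSE, ...) {
  if (!is.list(frames) || length(frames) < 2) {
    stop_invalid("`frames` must be a list of at least 2 frames.",
                 "povar_invalid_parameter")
  }
  if (scale <= 0) stop_invalid("`scale` must be > 0.", "povar_invalid_parameter")
  det <- purrr::map_dfr(frames, detect_pupil, threshold = threshold, ...)
  if (!any(det$ok)) {
    stop_invalid("Pupil detection failed on every frame.", "povar_tracking_failed")
  }
  origin <- origin %||% c((ncol(frames[[1]]) + 1) / 2, (nrow(frames[[1]]) + 1) / 2)
  n <- nrow(det)
  h <- (det$cx - origin[1]) * scale * (if (sign_flip) -1 else 1)
  v <- -(det$cy - origin[2]) * scale
  h_i <- zoo::na.approx(h, na.rm = FALSE, maxgap = max_gap)
  v_i <- zoo::na.approx(v, na.rm = FALSE, maxgap = max_gap)
  quality <- dplyr::case_when(det$ok ~ "ok",
                              !is.na(h_i) ~ "interpolated",
                              TRUE ~ "artifact")
  # artifacts keep a carried value so the series stays numeric and uniform
  h_i <- zoo::na.approx(h_i, na.rm = FALSE, rule = 2)
  v_i <- zoo::na.approx(v_i, na.rm = FALSE, rule = 2)
  tibble(time_s = (seq_len(n) - 1) / sampling_rate,
         h_deg = h_i, v_deg = v_i, quality = quality)
}
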