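# Interpretability: per-lead attention weights, 2-D scalp topomap
# interpolation on the unit disk, and gradient-weighted class activation
# maps.
#
# CAM note: the final convolution output of each per-lead CNN is 32 x 1 x 1,
# so the classic CAM (weights times final conv maps) has no spatial extent.
# The maps here are therefore gradient-weighted CAMs taken at the last
# spatially extended layer, the 4 x 4 stage-2 activation, rectified and
# bilinearly upsampled to the 39 x 11 spectrogram grid.

#' Extract attention weights for a sample
#'
#' Runs the model in inference mode and returns the squeeze-and-excite
#' attention weight of every lead (all ones when the attention module is
#' disabled).
#'
#' @param model a trained `wf_model`.
#' @param sample one `leads x freq x time` tensor (or a batch).
#' @param lead_names optional names to attach.
#' @return named numeric vector in (0,1), one weight per lead (matrix for a
#'   batch).
#' @export
extract_attention <- function(model, sample, lead_names = NULL) {
  fw <- wf_forward(model, sample, training = FALSE, head = "encode")
  pi_w <- fw$pi
  if (nrow(pi_w) == 1L) pi_w <- drop(pi_w)
  if (!is.null(lead_names)) {
    if (is.matrix(pi_w)) colnames(pi_w) <- lead_names else names(pi_w) <- lead_names
  }
  pi_w
}

tps_kernel <- function(r) {
  out <- r
  pos <- r > 0
  out[pos] <- r[pos]^2 * log(r[pos])
  out[!pos] <- 0
  out
}

#' Interpolate per-lead values onto a scalp topomap
#'
#' Interpolates electrode values over a regular grid on the unit disk,
#' masked (NA) outside the scalp. The default interpolant is a thin-plate
#' radial basis spline, exact at the electrode locations, with the surface
#' clipped to the observed value range; `"idw"` (inverse-distance weighting)
#' is available as a strictly range-respecting alternative.
#'
#' @param values per-electrode values (e.g. attention weights).
#' @param montage data.frame with `lead_name`, `x`, `y`; rows are matched to
#'   `names(values)` when present, otherwise taken in order.
#' @param grid_n grid resolution per axis (default 67).
#' @param method "tps" or "idw".
#' @param clip logical; clip the surface to `[min(values), max(values)]`
#'   (default TRUE).
#' @return a list of class `wf_topomap`: `grid` (`grid_n x grid_n`, NA
#'   outside the disk), `xg`, `yg`, `electrodes` (coordinates), `values`.
#' @export
interpolate_topomap <- function(values, montage, grid_n = 67L,
                                method = c("tps", "idw"), clip = TRUE) {
  method <- match.arg(method)
  if (!is.null(names(values))) {
    sel <- match(names(values), montage$lead_name)
    if (anyNA(sel))
      wf_config_error("leads absent from montage: %s",
                      paste(names(values)[is.na(sel)], collapse = ", "))
    pts <- cbind(montage$x[sel], montage$y[sel])
  } else {
    if (length(values) > nrow(montage))
      wf_config_error("more values than montage rows")
    pts <- cbind(montage$x, montage$y)[seq_along(values), , drop = FALSE]
  }
  if (anyDuplicated(pts))
    wf_data_error("duplicate electrode coordinates")
  v <- as.numeric(values)
  np <- nrow(pts)
  xg <- seq(-1, 1, length.out = grid_n)
  yg <- seq(-1, 1, length.out = grid_n)
  gx <- rep(xg, times = grid_n)
  gy <- rep(yg, each = grid_n)
  inside <- gx^2 + gy^2 <= 1
  est <- rep(NA_real_, grid_n^2)
  d_grid <- sqrt(outer(gx[inside], pts[, 1], `-`)^2 +
                 outer(gy[inside], pts[, 2], `-`)^2)
  if (method == "tps") {
    dd <- as.matrix(stats::dist(pts))
    K <- tps_kernel(dd)
    P <- cbind(1, pts)
    A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
    sol <- solve(A + diag(1e-12, np + 3L), c(v, numeric(3)))
    w <- sol[seq_len(np)]
    a <- sol[np + 1:3]
    est[inside] <- tps_kernel(d_grid) %*% w + a[1] + gx[inside] * a[2] +
      gy[inside] * a[3]
  } else {
    wt <- 1 / pmax(d_grid, 1e-12)^2
    est[inside] <- (wt %*% v) / rowSums(wt)
    hit <- apply(d_grid, 1L, which.min)
    exact <- apply(d_grid, 1L, min) < 1e-9
    est[inside][exact] <- v[hit[exact]]
  }
  if (clip) est <- pmin(pmax(est, min(v)), max(v))
  structure(list(grid = matrix(est, grid_n, grid_n), xg = xg, yg = yg,
                 electrodes = pts, values = v, method = method),
            class = "wf_topomap")
}

#' Evaluate a topomap surface at arbitrary points
#'
#' Re-evaluates the interpolant (not the discrete grid) at the given
#' coordinates; at electrode locations this reproduces the electrode values.
#' @param tm a `wf_topomap`.
#' @param x,y coordinates inside the unit disk.
#' @return numeric vector of surface values.
#' @export
topomap_at <- function(tm, x, y) {
  pts <- tm$electrodes
  d <- sqrt(outer(x, pts[, 1], `-`)^2 + outer(y, pts[, 2], `-`)^2)
  v <- if (tm$method == "tps") {
    np <- nrow(pts)
    dd <- as.matrix(stats::dist(pts))
    A <- rbind(cbind(tps_kernel(dd), cbind(1, pts)),
               cbind(t(cbind(1, pts)), matrix(0, 3, 3)))
    sol <- solve(A + diag(1e-12, np + 3L), c(tm$values, numeric(3)))
    as.vector(tps_kernel(d) %*% sol[seq_len(np)] + sol[np + 1] +
              x * sol[np + 2] + y * sol[np + 3])
  } else {
    wt <- 1 / pmax(d, 1e-12)^2
    out <- as.vector((wt %*% tm$values) / rowSums(wt))
    exact <- apply(d, 1L, min) < 1e-9
    out[exact] <- tm$values[apply(d, 1L, which.min)[exact]]
    out
  }
  pmin(pmax(v, min(tm$values)), max(tm$values))
}

bilinear_upsample <- function(m, out_h, out_w) {
  ih <- nrow(m); iw <- ncol(m)
  ry <- if (ih == 1L) rep(1, out_h) else seq(1, ih, length.out = out_h)
  rx <- if (iw == 1L) rep(1, out_w) else seq(1, iw, length.out = out_w)
  y0 <- pmin(floor(ry), ih - 1L); fy <- ry - y0
  x0 <- pmin(floor(rx), iw - 1L); fx <- rx - x0
  if (ih == 1L) { y0 <- rep(1L, out_h); fy <- rep(0, out_h) }
  if (iw == 1L) { x0 <- rep(1L, out_w); fx <- rep(0, out_w) }
  m11 <- m[y0, x0, drop = FALSE]
  m21 <- m[pmin(y0 + 1L, ih), x0, drop = FALSE]
  m12 <- m[y0, pmin(x0 + 1L, iw), drop = FALSE]
  m22 <- m[pmin(y0 + 1L, ih), pmin(x0 + 1L, iw), drop = FALSE]
  fy_m <- matrix(fy, out_h, out_w)
  fx_m <- matrix(fx, out_h, out_w, byrow = TRUE)
  m11 * (1 - fy_m) * (1 - fx_m) + m21 * fy_m * (1 - fx_m) +
    m12 * (1 - fy_m) * fx_m + m22 * fy_m * fx_m
}

#' Gradient-weighted class activation map for one lead
#'
#' Backpropagates the chosen class logit to the lead's stage-2 activation
#' (the last spatially extended feature map), weights each channel by its
#' average gradient, rectifies, bilinearly upsamples to the spectrogram
#' grid, and scales the maximum to 1.
#'
#' @param model a trained `wf_model`.
#' @param sample one `leads x freq x time` tensor.
#' @param lead lead index (or name, if `lead_names` given).
#' @param class class of interest (0 or 1).
#' @param lead_names optional lead names for name lookup.
#' @return `freq x time` matrix in [0, 1] (all zeros, with a message, when
#'   the rectified map is identically zero).
#' @export
class_activation_map <- function(model, sample, lead = 1L, class = 1L,
                                 lead_names = NULL) {
  if (is.character(lead)) {
    if (is.null(lead_names)) wf_config_error("lead_names needed for name lookup")
    lead <- match(lead, lead_names)
  }
  cfg <- model$config
  fw <- wf_forward(model, sample, training = FALSE, head = "classify",
                   keep_cache = TRUE)
  dlogits <- matrix(0, 1, cfg$n_classes)
  dlogits[1, class + 1L] <- 1
  bk <- wf_backward(model, fw$cache, dlogits, want_stage2_grad = TRUE)
  acts <- fw$cache$lead_caches[[lead]]$a2[1, , , ]      # ch x 4 x 4
  grads <- bk$stage2_grads[[lead]][1, , , ]
  alpha <- apply(grads, 1L, mean)
  cam <- matrix(0, dim(acts)[2], dim(acts)[3])
  for (c in seq_along(alpha)) cam <- cam + alpha[c] * acts[c, , ]
  cam <- pmax(cam, 0)
  cam <- bilinear_upsample(cam, cfg$input_h, cfg$input_w)
  mx <- max(cam)
  if (mx <= 0) {
    message("class_activation_map: rectified map is identically zero")
    return(cam * 0)
  }
  cam / mx
}

# ---- figure and numeric export ---------------------------------------------

#' Write attention weights and CAMs as plain-text artifacts
#'
#' @param pi named attention vector.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
export_attention <- function(pi, path) {
  utils::write.csv(data.frame(lead_name = names(pi) %||% seq_along(pi),
                              attention = as.numeric(pi)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_attention
#' @param cam a CAM matrix.
#' @export
export_cam <- function(cam, path) {
  utils::write.csv(as.data.frame(cam), path, row.names = FALSE)
  invisible(path)
}

#' Render a topomap (or CAM) to a raster image
#'
#' Thin base-graphics writers used by the pipeline's explain stage; all
#' quantitative content is also exported numerically, so figures are purely
#' illustrative.
#' @param tm a `wf_topomap`.
#' @param path output PNG path.
#' @param main plot title.
#' @return the path, invisibly (NULL with a warning when no graphics device
#'   is available).
#' @export
plot_topomap <- function(tm, path, main = "attention topomap") {
  ok <- tryCatch({
    grDevices::png(path, width = 640, height = 640)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::image(tm$xg, tm$yg, t(tm$grid),
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    asp = 1, xlab = "", ylab = "", main = main)
    graphics::points(tm$electrodes[, 1], tm$electrodes[, 2], pch = 16)
    TRUE
  }, error = function(e) {
    warning("no graphics device available: ", conditionMessage(e))
    FALSE
  })
  if (ok) invisible(path) else invisible(NULL)
}

#' @rdname plot_topomap
#' @param cam a CAM matrix (frequency x time).
#' @export
plot_cam <- function(cam, path, main = "class activation map") {
  ok <- tryCatch({
    grDevices::png(path, width = 480, height = 640)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::image(seq_len(ncol(cam)), seq_len(nrow(cam)), t(cam),
                    col = grDevices::hcl.colors(64, "viridis"),
                    xlab = "time frame", ylab = "frequency bin", main = main)
    TRUE
  }, error = function(e) {
    warning("no graphics device available: ", conditionMessage(e))
    FALSE
  })
  if (ok) invisible(path) else invisible(NULL)
}
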