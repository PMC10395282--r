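# Robust bad-channel detection, spherical-spline interpolation, and robust
# average referencing.

# Perrin-style spherical spline g-function (order m = 4, 40 Legendre terms)
.spline_g <- function(cosang, m = 4, n_terms = 40) {
  p_nm1 <- rep(1, length(cosang))  # P_0
  p_n <- cosang                    # P_1
  out <- numeric(length(cosang))
  for (n in seq_len(n_terms)) {
    if (n > 1) {
      p_new <- ((2 * n - 1) * cosang * p_n - (n - 1) * p_nm1) / n
      p_nm1 <- p_n; p_n <- p_new
    }
    out <- out + (2 * n + 1) / (n^m * (n + 1)^m) * p_n
  }
  out / (4 * pi)
}

# interpolation weights for target channels from good channels
.spline_weights <- function(pos_good, pos_bad, lambda = 1e-5) {
  ng <- nrow(pos_good)
  G <- .spline_g(tcrossprod(pos_good))     # ng x ng
  Gt <- .spline_g(pos_bad %*% t(pos_good)) # nb x ng
  A <- rbind(cbind(G + diag(lambda, ng), 1), c(rep(1, ng), 0))
  sol <- solve(A, rbind(diag(ng), 0))      # maps data -> [c; d]
  cbind(Gt, 1) %*% sol                     # nb x ng weights
}

#' Detect, repair and robustly re-reference corrupt channels
#'
#' Iteratively (at most `max_iter` passes) flags channels that are flat,
#' have a robust-z of their SD above `z_sd`, or correlate with every other
#' channel below `min_cor`; flagged channels are replaced by spherical-spline
#' interpolation from the good channels and the data are re-referenced to
#' the average of the good channels.
#'
#' @param rec A [new_recording()] object whose channels have known positions.
#' @param z_sd Robust-z threshold on the channel SD (default 5).
#' @param min_cor Minimum of the maximum absolute inter-channel correlation
#'   (default 0.4).
#' @param max_iter Maximum detection/re-reference iterations (default 4).
#' @param max_bad_frac Abort if more than this fraction of channels is bad.
#' @param rereference Apply the robust average reference (default TRUE).
#' @return List with `recording` (repaired, re-referenced) and `repaired`
#'   (character vector of repaired channel names).
#' @export
detect_and_repair_channels <- function(rec, z_sd = 5, min_cor = 0.4,
                                       max_iter = 4, max_bad_frac = 0.25,
                                       rereference = TRUE) {
  stopifnot(inherits(rec, "ContinuousRecording"))
  pos <- electrode_positions(rec$channel_names)
  x <- rec$data
  n_ch <- nrow(x)
  bad <- rep(FALSE, n_ch)
  for (iter in seq_len(max_iter)) {
    good <- which(!bad)
    ref <- colMeans(x[good, , drop = FALSE])
    xr <- sweep(x, 2L, ref)
    # flatness is a property of the raw channel, before referencing
    flat <- apply(x, 1L, sd) < 1e-12
    sds <- apply(xr, 1L, sd)
    z <- (sds - median(sds[!flat])) / max(mad(sds[!flat]), 1e-12)
    noisy <- z > z_sd
    cm <- suppressWarnings(abs(cor(t(xr))))
    diag(cm) <- NA
    lonely <- apply(cm, 1L, max, na.rm = TRUE) < min_cor
    lonely[is.na(lonely)] <- TRUE
    new_bad <- flat | noisy | lonely
    if (mean(new_bad) > max_bad_frac)
      stop("more than ", round(max_bad_frac * 100),
           "% of channels look corrupt (",
           paste(rec$channel_names[new_bad], collapse = ", "),
           "); aborting repair")
    if (all(new_bad == bad) && iter > 1) break
    bad <- bad | new_bad
    if (any(bad)) {
      W <- .spline_weights(pos[!bad, , drop = FALSE],
                           pos[bad, , drop = FALSE])
      x[bad, ] <- W %*% x[!bad, , drop = FALSE]
    }
    if (!any(new_bad)) break
  }
  if (rereference) {
    ref <- colMeans(x[!bad, , drop = FALSE])
    x <- sweep(x, 2L, ref)
  }
  rec$data <- x
  rownames(rec$data) <- rec$channel_names
  list(recording = rec, repaired = rec$channel_names[bad])
}
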