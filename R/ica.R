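# ICA preparation, decomposition (symmetric FastICA with PCA rank
# compression), heuristic component classification, and ocular-IC removal.

#' Prepare a recording for ICA training
#'
#' High-pass filters at 1 Hz, downsamples to 250 Hz, cuts the result into
#' 1-s epochs and drops epochs whose peak-to-peak amplitude exceeds
#' `pp_max_uV` in any channel. The retained epochs (concatenated) form the
#' ICA training data.
#'
#' @param rec A [new_recording()] object (500 Hz typical).
#' @param highpass_hz Training high-pass edge (Hz).
#' @param target_rate Training sample rate (Hz).
#' @param pp_max_uV Peak-to-peak artifact criterion per 1-s epoch.
#' @return List with `train` (channels x samples matrix), `sample_rate`,
#'   `kept_epochs`, `dropped_epochs`, and `recording` (the full downsampled
#'   recording before epoch rejection).
#' @export
prepare_ica_input <- function(rec, highpass_hz = 1, target_rate = 250,
                              pp_max_uV = 500) {
  stopifnot(inherits(rec, "ContinuousRecording"))
  # decimate first: both steps are linear and the 1-Hz high-pass is far
  # below the decimator's band edge, so the order is immaterial but the
  # high-pass then runs on a quarter of the samples
  ds <- downsample_recording(rec, target_rate)
  ds <- highpass_filter(ds, highpass_hz)
  n <- ncol(ds$data)
  ep_len <- as.integer(target_rate)
  n_ep <- n %/% ep_len
  keep <- logical(n_ep)
  for (e in seq_len(n_ep)) {
    idx <- ((e - 1L) * ep_len + 1L):(e * ep_len)
    pp <- apply(ds$data[, idx, drop = FALSE], 1L,
                function(v) diff(range(v)))
    keep[e] <- max(pp) <= pp_max_uV
  }
  if (sum(keep) < 60)
    stop("fewer than 60 s of clean data after artifact rejection; ",
         "ICA would be unreliable")
  cols <- unlist(lapply(which(keep), function(e)
    ((e - 1L) * ep_len + 1L):(e * ep_len)))
  list(train = ds$data[, cols, drop = FALSE], sample_rate = target_rate,
       kept_epochs = sum(keep), dropped_epochs = sum(!keep),
       recording = ds)
}

#' ICA decomposition with PCA rank compression
#'
#' Symmetric FastICA (tanh contrast) on PCA-whitened data compressed to
#' `rank` components — by convention the number of non-corrupt channels
#' minus one. The unmixing matrix maps channel data (any recording with the
#' same montage, e.g. the 0.1-Hz-filtered 500-Hz data) to IC activations;
#' mixing x unmixing is the identity on the retained subspace.
#'
#' @param train Channels x samples training matrix (from
#'   [prepare_ica_input()]).
#' @param rank Number of components (> 1).
#' @param seed Integer seed for the random orthogonal start.
#' @param max_iter,tol FastICA iteration controls.
#' @param max_train_samples Training samples actually used for the
#'   iteration; longer inputs are subsampled on an even deterministic grid
#'   (the estimate is unaffected well before this limit).
#' @return List of class `ICDecomposition`: `mixing` (channels x ICs),
#'   `unmixing` (ICs x channels), `rank`, `channel_names`, `ic_labels`
#'   (filled by [classify_components()]).
#' @export
decompose_ica <- function(train, rank, seed = 1, max_iter = 150,
                          tol = 1e-6, max_train_samples = 30000) {
  if (rank <= 1) stop("rank must exceed 1")
  if (rank > nrow(train)) stop("rank exceeds channel count")
  set.seed(seed)
  if (ncol(train) > max_train_samples) {
    step <- ncol(train) / max_train_samples
    train <- train[, round(seq(1, ncol(train), by = step)), drop = FALSE]
  }
  x <- train - rowMeans(train)
  n <- ncol(x)
  cv <- tcrossprod(x) / n
  eg <- eigen(cv, symmetric = TRUE)
  keep <- seq_len(rank)
  K <- diag(1 / sqrt(eg$values[keep])) %*% t(eg$vectors[, keep])  # whitener
  z <- K %*% x
  # symmetric FastICA, tanh nonlinearity
  W <- matrix(rnorm(rank * rank), rank)
  sym_decor <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decor(W)
  for (it in seq_len(max_iter)) {
    wz <- W %*% z
    g <- tanh(wz)
    gp <- 1 - g^2
    W_new <- (g %*% t(z)) / n - diag(rowMeans(gp)) %*% W
    W_new <- sym_decor(W_new)
    delta <- max(abs(abs(rowSums(W_new * W)) - 1))
    W <- W_new
    if (delta < tol) break
  }
  unmixing <- W %*% K
  mixing <- eg$vectors[, keep] %*% diag(sqrt(eg$values[keep])) %*% t(W)
  # fix sign: each IC's dominant channel weight positive
  for (i in seq_len(rank)) {
    s <- sign(mixing[which.max(abs(mixing[, i])), i])
    mixing[, i] <- mixing[, i] * s
    unmixing[i, ] <- unmixing[i, ] * s
  }
  structure(list(mixing = mixing, unmixing = unmixing, rank = rank,
                 channel_names = rownames(train), ic_labels = NULL,
                 iterations = it),
            class = "ICDecomposition")
}

#' IC activations of a recording
#'
#' Applies the unmixing matrix (weight transfer) to any recording with the
#' decomposition's montage.
#'
#' @param ica An [decompose_ica()] result.
#' @param rec A [new_recording()] object or channels x samples matrix.
#' @return ICs x samples activation matrix.
#' @export
ic_activations <- function(ica, rec) {
  x <- if (inherits(rec, "ContinuousRecording")) rec$data else rec
  if (!is.null(ica$channel_names) && !is.null(rownames(x)) &&
      !identical(rownames(x), ica$channel_names))
    x <- x[ica$channel_names, , drop = FALSE]
  ica$unmixing %*% x
}

# excess kurtosis
.kurtosis <- function(x) {
  x <- x - mean(x)
  mean(x^4) / mean(x^2)^2 - 3
}

# log-log spectral slope over 2-25 Hz, Welch-style on 2-s segments
.spectral_slope <- function(x, rate) {
  seg <- as.integer(2 * rate)
  n_seg <- max(1L, length(x) %/% seg)
  acc <- 0
  for (s in seq_len(n_seg)) {
    v <- x[((s - 1L) * seg + 1L):(s * seg)]
    v <- v * 0.5 * (1 - cos(2 * pi * seq_along(v) / length(v)))
    acc <- acc + Mod(fft(v))^2
  }
  f <- (seq_len(seg) - 1) * rate / seg
  sel <- f >= 2 & f <= 25
  unname(coef(stats::lm(log(acc[sel] + 1e-12) ~ log(f[sel])))[2])
}

#' Heuristic IC classification
#'
#' Deterministic stand-in for a trained IC classifier: each component gets
#' pseudo-probabilities for `brain`, `eye_vertical`, `eye_horizontal` and
#' `other`, from (i) correlation of its scalp pattern with a bilateral
#' frontopolar template (vertical eye) or an F7/F8 antisymmetric template
#' (horizontal eye), (ii) activation kurtosis (blinks are bursty), (iii)
#' low-frequency dominance (saccadic step trains), and (iv) spectral slope.
#' `select_brain()` keeps ICs whose brain score exceeds `threshold`
#' (default 0.30).
#'
#' @param ica An [decompose_ica()] result.
#' @param train Channels x samples matrix the decomposition was fit on.
#' @param sample_rate Sampling rate of `train` (Hz).
#' @return data.frame with `ic`, `label`, and one probability column per
#'   class; also stored in `ica$ic_labels` of the returned attribute.
#' @export
classify_components <- function(ica, train, sample_rate = 250) {
  ch <- ica$channel_names
  tv <- setNames(numeric(length(ch)), ch)
  tv[intersect(c("Fp1", "Fp2"), ch)] <- 1
  tv[intersect(c("F3", "F4", "F7", "F8"), ch)] <- 0.4
  th <- setNames(numeric(length(ch)), ch)
  th[intersect("F7", ch)] <- -1; th[intersect("F8", ch)] <- 1
  th[intersect("Fp1", ch)] <- -0.4; th[intersect("Fp2", ch)] <- 0.4
  act <- ic_activations(ica, train)
  out <- lapply(seq_len(ica$rank), function(i) {
    topo <- ica$mixing[, i]
    cv <- abs(cor(topo, tv))
    chc <- abs(cor(topo, th))
    a <- act[i, ]
    kur <- .kurtosis(a)
    sp <- Mod(fft(a - mean(a)))^2
    f <- (seq_along(sp) - 1) * sample_rate / length(sp)
    lowfrac <- sum(sp[f > 0 & f < 3]) / sum(sp[f > 0 & f <= sample_rate / 2])
    ev <- stats::plogis(12 * (cv - 0.75)) * stats::plogis((kur - 2) / 2)
    eh <- stats::plogis(12 * (chc - 0.75)) * stats::plogis(8 * (lowfrac - 0.4))
    slope <- .spectral_slope(a, sample_rate)
    brain <- (1 - max(ev, eh)) * stats::plogis(-2 * (slope + 0.3))
    otherp <- max(0, 1 - max(ev, eh, brain))
    probs <- c(brain = brain, eye_vertical = ev, eye_horizontal = eh,
               other = otherp)
    data.frame(ic = i, label = names(probs)[which.max(probs)],
               brain = brain, eye_vertical = ev, eye_horizontal = eh,
               other = otherp)
  })
  labels <- do.call(rbind, out)
  if (!any(labels$label == "eye_horizontal"))
    warning("no horizontal-eye IC found; saccade detection will be disabled")
  labels
}

#' Select brain ICs / remove ocular ICs from a recording
#'
#' Keeps components whose brain pseudo-probability exceeds `threshold`
#' (default 0.30, i.e. components at or below 30% brain probability are
#' removed) and reconstructs the recording without the rejected components.
#'
#' @param rec A [new_recording()] object.
#' @param ica An [decompose_ica()] result.
#' @param labels Output of [classify_components()].
#' @param threshold Brain-probability threshold.
#' @return The cleaned recording.
#' @export
select_brain <- function(rec, ica, labels, threshold = 0.30) {
  stopifnot(inherits(rec, "ContinuousRecording"))
  drop_ic <- which(labels$brain <= threshold)
  if (!length(drop_ic)) return(rec)
  x <- rec$data[ica$channel_names, , drop = FALSE]
  art <- ica$mixing[, drop_ic, drop = FALSE] %*%
    (ica$unmixing[drop_ic, , drop = FALSE] %*% x)
  rec$data[ica$channel_names, ] <- x - art
  rec
}
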