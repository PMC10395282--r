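# Saccade-locked ERSPs, contra/ipsi lateralized time-frequency maps,
# pre-saccadic alpha asymmetry, and the one-sample cluster-based
# permutation test.

# Morlet power of one epoch (vector) on a frequency grid
.morlet_epoch <- function(x, sr, freqs, cyc) {
  n <- length(x)
  nf <- nextn(2 * n, 2)
  fgrid <- (seq_len(nf) - 1) / nf * sr
  fgrid[fgrid > sr / 2] <- fgrid[fgrid > sr / 2] - sr
  X <- fft(c(x, numeric(nf - n)))
  out <- matrix(0, length(freqs), n)
  for (j in seq_along(freqs)) {
    H <- exp(-(fgrid - freqs[j])^2 / (2 * (freqs[j] / cyc[j])^2)) * 2
    conv <- fft(X * H, inverse = TRUE) / nf
    out[j, ] <- Mod(conv[seq_len(n)])^2
  }
  out
}

#' Event-related spectral perturbation
#'
#' Complex Morlet power of each epoch on the 29-bin 2–30 Hz grid, averaged
#' within condition cells. No baseline normalization is applied: the
#' lateralized contrasts downstream are self-baselining.
#'
#' @param set An [epoch_events()] result (typically saccade-locked with a
#'   wide window, e.g. -1000..500 ms).
#' @param sample_rate EEG sampling rate (Hz).
#' @param channels Channels to transform.
#' @param f_min,f_max,n_freqs Frequency grid.
#' @param cycles Cycles at `f_min` and `f_max` (linear in between).
#' @param by Metadata columns defining the averaging cells.
#' @return List: `cells`, `power` (cells x channels x freqs x time),
#'   `freqs`, `times`.
#' @export
ersp <- function(set, sample_rate, channels, f_min = 2, f_max = 30,
                 n_freqs = 29, cycles = c(3, 8), by = "sacc_type") {
  freqs <- seq(f_min, f_max, length.out = n_freqs)
  cyc <- seq(cycles[1], cycles[2], length.out = n_freqs)
  min_len <- 3 * cyc[1] / (2 * pi * f_min) * 2 * sample_rate
  if (dim(set$data)[3] < min_len)
    stop("epochs too short for the lowest frequency; need at least ",
         ceiling(min_len), " samples")
  chi <- match(channels, dimnames(set$data)[[2]])
  if (anyNA(chi)) stop("missing channel(s)")
  key <- interaction(set$meta[by], drop = FALSE, sep = "|", lex.order = TRUE)
  levs <- levels(key)
  nt <- dim(set$data)[3]
  pw <- array(0, dim = c(length(levs), length(channels), n_freqs, nt),
              dimnames = list(levs, channels, NULL, NULL))
  n_ev <- integer(length(levs))
  for (e in seq_len(dim(set$data)[1])) {
    i <- match(as.character(key[e]), levs)
    n_ev[i] <- n_ev[i] + 1L
    for (k in seq_along(chi))
      pw[i, k, , ] <- pw[i, k, , ] +
        .morlet_epoch(set$data[e, chi[k], ], sample_rate, freqs, cyc)
  }
  for (i in seq_along(levs)) if (n_ev[i] > 0) pw[i, , , ] <- pw[i, , , ] / n_ev[i]
  parts <- do.call(rbind, strsplit(levs, "|", fixed = TRUE))
  cells <- data.frame(parts, stringsAsFactors = FALSE)
  names(cells) <- by
  cells$n_events <- n_ev
  list(cells = cells, power = pw, freqs = freqs, times = set$times)
}

#' Lateralized (contra - ipsi) time-frequency maps
#'
#' Computes single-epoch Morlet power at the members of each electrode pair,
#' assigns contra/ipsi by the event's direction, and averages within cells.
#'
#' @param set Saccade- or fixation-locked [epoch_events()] set with
#'   direction labels.
#' @param sample_rate Hz.
#' @param pairs List of c(left, right) pairs (default PO9/PO10 and O1/O2).
#' @param by Cell-defining metadata columns.
#' @inheritParams ersp
#' @return List: `cells`, `contra`, `ipsi`, `diff` (cells x freqs x time,
#'   averaged over pairs), `freqs`, `times`.
#' @export
lateralize_tf <- function(set, sample_rate,
                          pairs = list(c("PO9", "PO10"), c("O1", "O2")),
                          f_min = 2, f_max = 30, n_freqs = 29,
                          cycles = c(3, 8), by = "sacc_type") {
  freqs <- seq(f_min, f_max, length.out = n_freqs)
  cyc <- seq(cycles[1], cycles[2], length.out = n_freqs)
  chs <- dimnames(set$data)[[2]]
  li <- match(vapply(pairs, `[`, "", 1L), chs)
  ri <- match(vapply(pairs, `[`, "", 2L), chs)
  if (anyNA(li) || anyNA(ri)) stop("missing pair channel(s)")
  keep <- which(set$meta$direction %in% c("left", "right"))
  meta <- set$meta[keep, , drop = FALSE]
  key <- interaction(meta[by], drop = FALSE, sep = "|", lex.order = TRUE)
  levs <- levels(key)
  nt <- dim(set$data)[3]
  con <- array(0, dim = c(length(levs), n_freqs, nt))
  ips <- array(0, dim = c(length(levs), n_freqs, nt))
  n_ev <- integer(length(levs))
  for (j in seq_along(keep)) {
    e <- keep[j]
    i <- match(as.character(key[j]), levs)
    n_ev[i] <- n_ev[i] + 1L
    right_ev <- meta$direction[j] == "right"
    ci <- if (right_ev) li else ri
    ii <- if (right_ev) ri else li
    for (p in seq_along(pairs)) {
      con[i, , ] <- con[i, , ] +
        .morlet_epoch(set$data[e, ci[p], ], sample_rate, freqs, cyc) /
        length(pairs)
      ips[i, , ] <- ips[i, , ] +
        .morlet_epoch(set$data[e, ii[p], ], sample_rate, freqs, cyc) /
        length(pairs)
    }
  }
  for (i in seq_along(levs)) if (n_ev[i] > 0) {
    con[i, , ] <- con[i, , ] / n_ev[i]
    ips[i, , ] <- ips[i, , ] / n_ev[i]
  }
  parts <- do.call(rbind, strsplit(levs, "|", fixed = TRUE))
  cells <- data.frame(parts, stringsAsFactors = FALSE)
  names(cells) <- by
  cells$n_events <- n_ev
  list(cells = cells, contra = con, ipsi = ips, diff = con - ips,
       freqs = freqs, times = set$times)
}

# 4-connected component labelling of a logical matrix; returns a list of
# integer index vectors (cells of each cluster)
.label_clusters <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(list())
  nr <- nrow(mask)
  n_cell <- length(mask)
  inmask <- integer(n_cell)       # 0 = not supra; else position in idx
  inmask[idx] <- seq_along(idx)
  lab <- integer(length(idx))
  clusters <- list()
  nxt <- 0L
  stack <- integer(length(idx))
  for (s in seq_along(idx)) {
    if (lab[s]) next
    nxt <- nxt + 1L
    top <- 1L; stack[1L] <- idx[s]; lab[s] <- nxt
    members <- integer(0)
    while (top > 0L) {
      c0 <- stack[top]; top <- top - 1L
      members <- c(members, c0)
      r <- (c0 - 1L) %% nr + 1L
      nb <- c(if (r > 1L) c0 - 1L, if (r < nr) c0 + 1L, c0 - nr, c0 + nr)
      for (b in nb) {
        if (b >= 1L && b <= n_cell) {
          p <- inmask[b]
          if (p > 0L && !lab[p]) {
            lab[p] <- nxt; top <- top + 1L; stack[top] <- b
          }
        }
      }
    }
    clusters[[nxt]] <- members
  }
  clusters
}

# max cluster mass (sum of t) over positive and negative supra-threshold
# cells of a t-map
.max_cluster_mass <- function(tmap, tcrit) {
  best <- 0
  for (sgn in c(1, -1)) {
    m <- sgn * tmap > tcrit
    if (!any(m)) next
    for (cl in .label_clusters(m))
      best <- max(best, abs(sum(tmap[cl])))
  }
  best
}

#' One-sample cluster-based permutation test on time-frequency maps
#'
#' Mass-univariate one-sample t-tests per (frequency, time) cell;
#' supra-threshold cells (two-sided, |t| above the t quantile of
#' `cluster_forming_p`) are joined by 4-connectivity, cluster mass is the
#' sum of t-values, and the null distribution of the maximum |mass| is built
#' by random sign flips of subjects. Cluster p-values use the +1 convention,
#' so their resolution is 1/(n_perm + 1).
#'
#' @param maps Array subjects x freqs x times (e.g. contra - ipsi maps
#'   averaged across task-load conditions).
#' @param n_perm Number of sign-flip permutations (default 1000).
#' @param cluster_forming_p Two-sided cell-level threshold (default .01).
#' @param alpha Cluster-level significance level (default .05).
#' @param seed Integer seed for the permutation draws.
#' @return List of class `ClusterResult`: `clusters` (list of `cells`
#'   (indices into the freq x time plane), `mass`, `p`), `significant`
#'   (logical freq x time mask), `tmap`, `tcrit`, `n_perm`.
#' @export
cluster_permutation_test <- function(maps, n_perm = 1000,
                                     cluster_forming_p = 0.01,
                                     alpha = 0.05, seed = 1) {
  stopifnot(length(dim(maps)) == 3)
  S <- dim(maps)[1]
  if (S < 5) stop("need at least 5 subjects")
  set.seed(seed)
  nf <- dim(maps)[2]; nt <- dim(maps)[3]
  X <- matrix(maps, nrow = S)  # subjects x cells
  ss <- colSums(X^2)
  sdv <- apply(X, 2L, sd)
  zero_var <- sdv < 1e-300
  if (any(zero_var))
    warning(sum(zero_var), " zero-variance cells excluded from clustering")
  tcrit <- qt(1 - cluster_forming_p / 2, df = S - 1)
  t_of <- function(m) {
    denom <- sqrt(pmax(ss - S * m^2, 0) / (S - 1) / S)
    tv <- m / denom
    tv[zero_var | !is.finite(tv)] <- 0
    tv
  }
  t_obs <- t_of(colMeans(X))
  tmap <- matrix(t_obs, nf, nt)
  obs_clusters <- list()
  for (sgn in c(1, -1)) {
    m <- sgn * tmap > tcrit
    if (!any(m)) next
    for (cl in .label_clusters(m))
      obs_clusters[[length(obs_clusters) + 1L]] <-
        list(cells = cl, mass = sum(tmap[cl]))
  }
  signs <- matrix(sample(c(-1, 1), n_perm * S, replace = TRUE), n_perm, S)
  pm <- (signs %*% X) / S
  # sign flips leave per-cell sums of squares unchanged: the whole
  # permutation t-matrix comes from one vectorized expression
  denom_all <- sqrt(pmax(rep(ss, each = n_perm) - S * pm^2, 0) /
                      (S - 1) / S)
  tm_all <- pm / denom_all
  tm_all[, zero_var] <- 0
  tm_all[!is.finite(tm_all)] <- 0
  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm))
    null_max[p] <- .max_cluster_mass(matrix(tm_all[p, ], nf, nt), tcrit)
  for (i in seq_along(obs_clusters)) {
    m <- abs(obs_clusters[[i]]$mass)
    obs_clusters[[i]]$p <- (1 + sum(null_max >= m)) / (n_perm + 1)
  }
  sig <- matrix(FALSE, nf, nt)
  for (cl in obs_clusters) if (cl$p <= alpha) sig[cl$cells] <- TRUE
  structure(list(clusters = obs_clusters, significant = sig, tmap = tmap,
                 tcrit = tcrit, n_perm = n_perm, alpha = alpha),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("<ClusterResult> %d cluster(s), %d significant at p <= %.3g\n",
              length(x$clusters),
              sum(vapply(x$clusters, function(c) c$p <= x$alpha, TRUE)),
              x$alpha))
  invisible(x)
}

#' Pre-saccadic alpha asymmetry
#'
#' Mean of the contra - ipsi time-frequency difference over the alpha band
#' (8–12 Hz) and -800..-50 ms at a single posterior pair (PO9/PO10 in this
#' montage).
#'
#' @param lat A [lateralize_tf()] result computed on the alpha pair.
#' @param alpha_band Hz limits (inclusive).
#' @param window ms limits.
#' @return The `cells` data.frame with a `value` column.
#' @export
alpha_asymmetry <- function(lat, alpha_band = c(8, 12),
                            window = c(-800, -50)) {
  if (window[1] < min(lat$times) || window[2] > max(lat$times))
    stop("alpha-asymmetry window outside the epoch")
  fs <- which(lat$freqs >= alpha_band[1] & lat$freqs <= alpha_band[2])
  ts <- which(lat$times >= window[1] & lat$times <= window[2])
  out <- lat$cells
  out$value <- vapply(seq_len(nrow(out)), function(i)
    mean(lat$diff[i, fs, ts]), 1.0)
  out
}
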