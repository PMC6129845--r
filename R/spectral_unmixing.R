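# Non-negative factorization of the 3x3 excitation/emission reference stack
# into fluorophore spectra and abundance maps, plus per-ROI marker flags.
#
# With 3 fluorophores observed through 9 channels, the multi-way problem
# flattens without loss to matrix NMF on the channels x pixels unfolding,
# which is what is implemented here (multiplicative updates, Frobenius
# objective, multi-restart).

#' Multiplicative-update NMF (Frobenius objective)
#'
#' Lee-Seung updates with a small epsilon guard; iterates until the relative
#' change of the reconstruction error drops below `tol` or `max_iter` is
#' reached. The objective is non-increasing across updates.
#'
#' @param V nonnegative matrix (m x n)
#' @param k rank
#' @param seed RNG seed for the random initialization
#' @param max_iter,tol stopping rule
#' @param trace if TRUE, also return the per-iteration error path
#' @return list of W, H, error, iters (and error_path when traced); error is the relative
#'   Frobenius residual ||V - WH|| / ||V||
#' @export
nmf_multiplicative <- function(V, k, seed = 1L, max_iter = 2000L, tol = 1e-9,
                               trace = FALSE, W0 = NULL, H0 = NULL) {
  stopifnot(all(V >= 0))
  m <- nrow(V); n <- ncol(V)
  set.seed(seed)
  W <- if (is.null(W0)) matrix(runif(m * k, 0.1, 1), m, k) else pmax(W0, 1e-6)
  H <- if (is.null(H0)) matrix(runif(k * n, 0.1, 1), k, n) else pmax(H0, 1e-6)
  eps <- .Machine$double.eps
  nv <- sqrt(sum(V^2))
  err_prev <- Inf
  path <- numeric(0)
  it <- 0L
  repeat {
    it <- it + 1L
    H <- H * (crossprod(W, V) / (crossprod(W) %*% H + eps))
    W <- W * (tcrossprod(V, H) / (W %*% tcrossprod(H) + eps))
    err <- sqrt(sum((V - W %*% H)^2)) / nv
    if (trace) path <- c(path, err)
    if (it >= max_iter || (is.finite(err_prev) && err_prev - err < tol * max(err_prev, eps))) {
      break
    }
    err_prev <- err
  }
  out <- list(W = W, H = H, error = err, iters = it)
  if (trace) out$error_path <- path
  out
}

#' Expected fluorophore signatures used for component assignment
#'
#' NMF components are permutation-ambiguous; recovered spectra are matched to
#' these expected channel signatures (default: the generator's mixing matrix,
#' which doubles as a sensible prior for real acquisitions with the same
#' filter configuration) by greedy cosine similarity.
#'
#' @return 9 x 3 matrix, columns OGB1, EGFP, tdTomato
#' @export
default_spectral_signatures <- function() default_mixing_matrix()

#' Unmix a spectral reference stack into fluorophore abundance maps
#'
#' Per-channel dark-level subtraction (the `dark_quantile` of each channel,
#' clamped at zero) removes the detector noise floor, which a sparse
#' component would otherwise be forced to absorb. The channels x pixels
#' unfolding is then factorized with [nmf_multiplicative()] (several seeded
#' restarts, lowest error kept), each spectral column is rescaled to unit
#' sum (with the compensating scale moved into the abundances), and
#' components are assigned to fluorophores by greedy cosine matching against
#' `signatures`.
#'
#' @param stack a [spectral_stack()] object
#' @param n_components number of fluorophores (default 3)
#' @param seed base RNG seed; restart r uses seed + r - 1
#' @param max_iter,tol NMF stopping rule
#' @param n_restarts random restarts (default 5)
#' @param signatures expected channel signatures for component naming
#' @param dark_quantile per-channel background quantile subtracted before
#'   factorization (default 0.5, the channel median; 0 disables). Appropriate
#'   while cellular structures cover well under half of the field.
#' @return object of class `pbs_unmix`: abundance_maps (named list of
#'   height x width matrices), spectra (channels x fluorophores, unit-sum
#'   columns), reconstruction_error, assignment
#' @export
unmix <- function(stack, n_components = 3L, seed = 1L, max_iter = 2000L,
                  tol = 1e-9, n_restarts = 5L,
                  signatures = default_spectral_signatures(),
                  dark_quantile = 0.5) {
  stopifnot(inherits(stack, "pbs_stack"))
  d <- dim(stack$data)
  n_chan <- d[1L] * d[2L]
  if (n_components > n_chan) stop("n_components exceeds the number of channels")
  V <- matrix(0, n_chan, d[3L] * d[4L])
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) {
    V[(i - 1L) * d[2L] + j, ] <- as.vector(stack$data[i, j, , ])
  }
  if (all(V == 0)) stop("all-zero stack")
  if (dark_quantile > 0) {
    V <- pmax(sweep(V, 1L, apply(V, 1L, quantile, dark_quantile)), 0)
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    # first restart warm-starts at the expected signatures (nonnegative
    # least-squares abundances), the rest are random
    W0 <- H0 <- NULL
    if (r == 1L && ncol(signatures) == n_components &&
        nrow(signatures) == n_chan) {
      W0 <- signatures
      H0 <- pmax(solve(crossprod(W0) + 1e-9 * diag(n_components),
                       crossprod(W0, V)), 0)
    }
    fit <- nmf_multiplicative(V, n_components, seed = seed + r - 1L,
                              max_iter = max_iter, tol = tol, W0 = W0, H0 = H0)
    if (is.null(best) || fit$error < best$error) best <- fit
  }
  W <- best$W
  H <- best$H
  sc <- colSums(W)
  sc[sc == 0] <- 1
  W <- sweep(W, 2L, sc, "/")
  H <- sweep(H, 1L, sc, "*")
  # greedy cosine assignment of components to expected signatures
  n_sig <- ncol(signatures)
  sim <- matrix(0, n_components, n_sig)
  for (i in seq_len(n_components)) for (j in seq_len(n_sig)) {
    sim[i, j] <- cosine_sim(W[, i], signatures[, j])
  }
  assign_to <- rep(NA_integer_, n_components)
  simw <- sim
  for (step in seq_len(min(n_components, n_sig))) {
    mx <- which(simw == max(simw), arr.ind = TRUE)[1L, ]
    assign_to[mx[1L]] <- mx[2L]
    simw[mx[1L], ] <- -Inf
    simw[, mx[2L]] <- -Inf
  }
  nm <- colnames(signatures) %||% paste0("component", seq_len(n_sig))
  maps <- vector("list", n_components)
  names_out <- character(n_components)
  for (i in seq_len(n_components)) {
    names_out[i] <- if (is.na(assign_to[i])) paste0("extra", i) else nm[assign_to[i]]
    maps[[i]] <- matrix(H[i, ], d[3L], d[4L])
  }
  names(maps) <- names_out
  ord <- order(match(names_out, nm, nomatch = length(nm) + 1L))
  structure(
    list(abundance_maps = maps[ord],
         spectra = W[, ord, drop = FALSE],
         reconstruction_error = best$error,
         assignment = names_out[ord]),
    class = "pbs_unmix"
  )
}

#' Marker flags (GlyT2/EGFP, GAD65/tdTomato) for ROIs
#'
#' A flag is positive when the mean abundance of that fluorophore inside the
#' ROI's (2*half+1)^2 window exceeds the background mean + 2 x background SD,
#' where background pixels are those farther than `half` (Chebyshev) from
#' every supplied ROI center.
#'
#' @param result a [unmix()] result with EGFP and tdTomato maps
#' @param roi_centers data.frame or matrix of 0-based (row, col) centers;
#'   a single center may be given as a length-2 vector
#' @param half ROI half-width (default 3)
#' @return data.frame with logical columns glyt2_pos, gad65_pos (one row per center)
#' @export
fluorophore_flags <- function(result, roi_centers, half = 3L) {
  stopifnot(inherits(result, "pbs_unmix"))
  if (is.null(dim(roi_centers))) roi_centers <- matrix(roi_centers, 1L)
  roi_centers <- as.matrix(as.data.frame(roi_centers)[, 1:2])
  egfp <- result$abundance_maps[["EGFP"]]
  tdt <- result$abundance_maps[["tdTomato"]]
  if (is.null(egfp) || is.null(tdt)) stop("result lacks EGFP/tdTomato maps")
  h <- nrow(egfp); w <- ncol(egfp)
  if (any(roi_centers[, 1L] < half | roi_centers[, 1L] > h - 1L - half |
          roi_centers[, 2L] < half | roi_centers[, 2L] > w - 1L - half)) {
    stop("ROI window touches the image border")
  }
  in_roi <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(roi_centers))) {
    rr <- (roi_centers[i, 1L] - half):(roi_centers[i, 1L] + half) + 1L
    cc <- (roi_centers[i, 2L] - half):(roi_centers[i, 2L] + half) + 1L
    in_roi[rr, cc] <- TRUE
  }
  flag_one <- function(map) {
    bg <- map[!in_roi]
    thr <- mean(bg) + 2 * sd(bg)
    vapply(seq_len(nrow(roi_centers)), function(i) {
      rr <- (roi_centers[i, 1L] - half):(roi_centers[i, 1L] + half) + 1L
      cc <- (roi_centers[i, 2L] - half):(roi_centers[i, 2L] + half) + 1L
      mean(map[rr, cc]) > thr
    }, logical(1))
  }
  data.frame(glyt2_pos = flag_one(egfp), gad65_pos = flag_one(tdt))
}
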