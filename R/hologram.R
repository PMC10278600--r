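#' Reconstruct a phase map from an off-axis hologram
#'
#' Standard Fourier sideband demodulation: the hologram is multiplied by the
#' conjugate carrier wave, low-pass filtered with a raised-cosine circular
#' mask of radius half the carrier magnitude (isolating the +1 sideband), and
#' the argument of the resulting analytic signal is unwrapped with a
#' least-squares 2-D unwrapper. The result is offset so the median phase on
#' the field border is 0 rad.
#'
#' @param hologram intensity matrix, e.g. from [simulate_hologram()].
#' @param carrier carrier frequency in cycles/pixel (`c(fx, fy)` or scalar
#'   along x). If `NULL`, taken from the `carrier` attribute when present,
#'   otherwise estimated from the Fourier sideband peak.
#' @param filter_radius low-pass radius as a fraction of the carrier
#'   magnitude (default 0.5).
#' @return Phase matrix in radians.
#' @seealso [simulate_hologram()], [detrend_background()]
#' @export
reconstruct_phase <- function(hologram, carrier = NULL, filter_radius = 0.5) {
  I <- unclass(hologram)
  stopifnot(is.matrix(I), all(is.finite(I)))
  if (any(I < 0)) stop("reconstruct_phase: negative intensities")
  if (is.null(carrier)) carrier <- attr(hologram, "carrier")
  if (is.null(carrier)) carrier <- estimate_carrier(I)
  f <- if (length(carrier) == 1) c(carrier, 0) else carrier
  fm <- sqrt(sum(f^2))
  if (fm < 0.05) {
    stop("reconstruct_phase: carrier ", signif(fm, 3), " cycles/pixel is too low; ",
         "the sideband overlaps the DC term - record with a higher carrier")
  }
  H <- nrow(I); W <- ncol(I)
  # select the +1 sideband in the Fourier plane first (the DC term is an
  # exact delta at bin 0 there and is excluded cleanly even for carriers
  # that are not integer cycles per field), then remove the carrier
  # pointwise in the space domain
  Z <- stats::fft(I)
  kx <- (0:(W - 1)) / W; kx[kx >= 0.5] <- kx[kx >= 0.5] - 1
  ky <- (0:(H - 1)) / H; ky[ky >= 0.5] <- ky[ky >= 0.5] - 1
  dkx <- ((kx - f[1] + 0.5) %% 1) - 0.5   # torus distance to the carrier
  dky <- ((ky - f[2] + 0.5) %% 1) - 0.5
  KR <- sqrt(outer(dky^2, dkx^2, `+`))
  r_lo <- filter_radius * fm
  edge <- 0.2 * r_lo
  msk <- ifelse(KR <= r_lo - edge, 1,
                ifelse(KR >= r_lo + edge, 0,
                       0.5 * (1 + cos(pi * (KR - (r_lo - edge)) / (2 * edge)))))
  zf <- stats::fft(Z * msk, inverse = TRUE) / (H * W)
  X <- matrix(0:(W - 1), H, W, byrow = TRUE)
  Y <- matrix(0:(H - 1), H, W)
  zf <- zf * exp(-2i * pi * (f[1] * X + f[2] * Y))
  wrapped <- Arg(zf)
  phi <- unwrap_phase(wrapped)
  border <- c(phi[1:2, ], phi[(H - 1):H, ], phi[, 1:2], phi[, (W - 1):W])
  phi - median(border)
}

#' Estimate the off-axis carrier frequency from a hologram
#'
#' Locates the +1 sideband peak of the Fourier magnitude (excluding a small
#' region around DC and the negative-x half-plane) and refines it by a local
#' centroid. Good to a fraction of a frequency bin for clean fringes.
#'
#' @param I intensity matrix.
#' @return `c(fx, fy)` in cycles/pixel.
#' @export
estimate_carrier <- function(I) {
  H <- nrow(I); W <- ncol(I)
  M <- Mod(stats::fft(I - mean(I)))
  kx <- (0:(W - 1)) / W; kx[kx >= 0.5] <- kx[kx >= 0.5] - 1
  ky <- (0:(H - 1)) / H; ky[ky >= 0.5] <- ky[ky >= 0.5] - 1
  KXm <- matrix(kx, H, W, byrow = TRUE)
  KYm <- matrix(ky, H, W)
  M[KXm < 0.02] <- 0                       # keep +x half-plane only
  M[sqrt(KXm^2 + KYm^2) < 0.03] <- 0       # drop DC neighbourhood
  pk <- which.max(M)
  pr <- (pk - 1) %% H + 1; pc <- (pk - 1) %/% H + 1
  # centroid over a 3x3 neighbourhood (wrapping at the edges)
  rr <- ((pr - 2):(pr)) %% H + 1
  cc <- ((pc - 2):(pc)) %% W + 1
  wts <- M[rr, cc]
  fx <- sum(wts * matrix(kx[cc], 3, 3, byrow = TRUE)) / sum(wts)
  fy <- sum(wts * matrix(ky[rr], 3, 3)) / sum(wts)
  c(fx, fy)
}

#' Least-squares 2-D phase unwrapping
#'
#' Ghiglia-Romero unweighted least-squares unwrapping: the wrapped phase
#' gradients define a Poisson equation with Neumann boundary conditions,
#' solved spectrally on an even-symmetric (mirrored) extension of the field.
#' Exact for phases whose true gradients stay below pi per pixel, which the
#' sideband low-pass guarantees for smooth specimens.
#'
#' @param psi wrapped phase matrix, radians (values in `(-pi, pi]`).
#' @return Unwrapped phase (defined up to an additive constant; the input's
#'   mean is preserved).
#' @export
unwrap_phase <- function(psi) {
  wrap <- function(x) (x + pi) %% (2 * pi) - pi
  H <- nrow(psi); W <- ncol(psi)
  dx <- cbind(wrap(psi[, -1] - psi[, -W]), 0)       # d/dcol
  dy <- rbind(wrap(psi[-1, ] - psi[-H, ]), 0)       # d/drow
  rho <- dx - cbind(0, dx[, -W]) + dy - rbind(0, dy[-H, ])
  # mirror to enforce Neumann BC, solve Poisson by FFT
  re <- rbind(cbind(rho, rho[, W:1]), cbind(rho[H:1, ], rho[H:1, W:1]))
  Fr <- stats::fft(re)
  wx <- 2 * cos(2 * pi * (0:(2 * W - 1)) / (2 * W)) - 2
  wy <- 2 * cos(2 * pi * (0:(2 * H - 1)) / (2 * H)) - 2
  den <- outer(wy, wx, `+`)
  den[1, 1] <- 1
  Fr <- Fr / den
  Fr[1, 1] <- 0
  sol <- Re(stats::fft(Fr, inverse = TRUE)) / (4 * H * W)
  out <- sol[1:H, 1:W]
  out - mean(out) + mean(psi)
}

#' Flatten the phase background
#'
#' Fits a 2-D polynomial (default degree 2) to cell-free pixels and subtracts
#' it, then shifts so the background median is 0 rad. QPI dry-mass
#' quantification assumes a flat zero background; residual tilt or curvature
#' from the reference arm otherwise biases every mass estimate. If fewer than
#' 10% of pixels are background, a warning is issued and only the global
#' median is subtracted.
#'
#' @param phase phase matrix, radians.
#' @param bg_mask logical matrix marking cell-free pixels.
#' @param degree polynomial degree (default 2).
#' @return Corrected phase matrix.
#' @export
detrend_background <- function(phase, bg_mask, degree = 2) {
  stopifnot(identical(dim(phase), dim(bg_mask)))
  H <- nrow(phase); W <- ncol(phase)
  if (sum(bg_mask) < 0.1 * length(bg_mask)) {
    warning("detrend_background: fewer than 10% background pixels; ",
            "subtracting global median only")
    return(phase - median(phase))
  }
  idx <- which(bg_mask, arr.ind = TRUE)
  if (nrow(idx) > 20000) idx <- idx[seq(1, nrow(idx), length.out = 20000), ]
  # centre/scale coordinates for conditioning
  xs <- (idx[, 2] - 1) / (W - 1) - 0.5
  ys <- (idx[, 1] - 1) / (H - 1) - 0.5
  dat <- data.frame(z = phase[cbind(idx[, 1], idx[, 2])], x = xs, y = ys)
  fit <- lm(z ~ polym(x, y, degree = degree, raw = TRUE), data = dat)
  gx <- (matrix(0:(W - 1), H, W, byrow = TRUE)) / (W - 1) - 0.5
  gy <- (matrix(0:(H - 1), H, W)) / (H - 1) - 0.5
  surf <- predict(fit, newdata = data.frame(x = as.vector(gx), y = as.vector(gy)))
  out <- phase - matrix(surf, H, W)
  out - median(out[bg_mask])
}
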