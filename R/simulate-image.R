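#' Render a TraceSet as a two-channel image stack
#'
#' Builds a small synthetic two-photon field: each cell is a Gaussian disc at
#' a random non-overlapping position whose channel-1 intensity follows its
#' raw trace; astrocytes are additionally bright in channel 2 (the SR101
#' channel). Gaussian shot-like noise is added per pixel. Pixel-true ROI
#' masks are returned, so [extractRoiTraces()] can be validated as a
#' round trip.
#'
#' @param traceset a [TraceSet-class].
#' @param field_px side length of the square field (pixels).
#' @param cell_radius_px cell mask radius (pixels).
#' @param noise_sd pixel noise SD (fraction of the baseline fluorescence).
#' @param seed RNG seed for placement and noise.
#' @return list with `ch1`, `ch2` (rows x cols x frames arrays), `masks`
#'   (rows x cols x cells logical array), and `centers`.
#' @export
simulateImageStack <- function(traceset, field_px = 64, cell_radius_px = 3,
                               noise_sd = 0.02, seed = 1) {
  set.seed(as.integer(seed))
  raw <- rawTraces(traceset)
  nc <- nrow(raw); nf <- ncol(raw)
  types <- unname(cellTypes(traceset))
  r <- cell_radius_px
  minDist <- 2 * r + 2
  if (field_px < minDist + 2 * r)
    stop("field too small to place any cell")
  centers <- matrix(NA_real_, nc, 2)
  tries <- 0
  for (i in seq_len(nc)) {
    repeat {
      tries <- tries + 1
      if (tries > 2000 * nc)
        stop("cannot place all cells without mask overlap")
      cand <- stats::runif(2, r + 1, field_px - r)
      if (i == 1 || all(sqrt(rowSums(
        (centers[seq_len(i - 1), , drop = FALSE] -
           matrix(cand, i - 1, 2, byrow = TRUE))^2)) >= minDist)) {
        centers[i, ] <- cand
        break
      }
    }
  }
  gx <- matrix(seq_len(field_px), field_px, field_px)
  gy <- t(gx)
  masks <- array(FALSE, c(field_px, field_px, nc))
  prof <- vector("list", nc)
  for (i in seq_len(nc)) {
    d2 <- (gx - centers[i, 1])^2 + (gy - centers[i, 2])^2
    masks[, , i] <- d2 <= r^2
    prof[[i]] <- exp(-d2 / (2 * (r / 1.5)^2))
  }
  bgLevel <- 5
  f0 <- mean(raw)
  ch1 <- array(stats::rnorm(field_px^2 * nf, bgLevel, noise_sd * f0),
               c(field_px, field_px, nf))
  ch2 <- array(stats::rnorm(field_px^2 * nf, bgLevel, noise_sd * f0),
               c(field_px, field_px, nf))
  for (i in seq_len(nc)) {
    idx <- which(prof[[i]] > 1e-4)
    w <- prof[[i]][idx]
    for (f in seq_len(nf)) {
      frame <- ch1[, , f]
      frame[idx] <- frame[idx] + w * raw[i, f]
      ch1[, , f] <- frame
    }
    if (types[i] == "astrocyte") {
      sr <- sr101Traces(traceset)
      lvl <- if (!is.null(sr) && !all(is.na(sr[i, ]))) sr[i, ] else rep(50, nf)
      for (f in seq_len(nf)) {
        frame <- ch2[, , f]
        frame[idx] <- frame[idx] + w * lvl[f]
        ch2[, , f] <- frame
      }
    }
  }
  list(ch1 = ch1, ch2 = ch2, masks = masks, centers = centers)
}
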