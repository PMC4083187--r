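#' Simulate a single-comet fluorescence image
#'
#' Renders one comet on a dark field with known ground truth. The head is
#' an isotropic 2-D Gaussian; the tail is a band extending from the head
#' centre toward increasing column index (the anode side, by convention)
#' with an exponentially decaying column profile and a Gaussian row
#' profile. A fraction `tail_fraction` of `total_signal` is placed in the
#' tail and the remainder in the head; both kernels are normalised over
#' the frame so the rendered totals are exact. Noise, if any, is applied
#' last.
#'
#' Pixel coordinates follow the TIFF raster convention: row-major, origin
#' at the top-left; reported centres use R's 1-based matrix indices.
#'
#' @param tail_fraction Fraction of total signal in the tail, in `[0, 1]`.
#' @param head_sigma Head Gaussian SD in pixels.
#' @param tail_length Exponential decay length of the tail along +x, in
#'   pixels; must fit between the head centre and the right frame edge.
#' @param total_signal Total expected counts in the frame; 0 gives a blank
#'   frame (unscorable downstream).
#' @param noise_model `"none"`, `"poisson"` (counts drawn per pixel), or
#'   `"gaussian"` (additive, SD `noise_sd`, clipped at 0).
#' @param noise_sd SD for the Gaussian noise model.
#' @param size `c(rows, cols)` of the frame.
#' @param head_centre `c(row, col)` of the head; default centre row,
#'   column 96.
#' @param tail_width Row-profile SD of the tail band in pixels.
#' @param seed Optional RNG seed (used only by the noise models).
#' @return An object of class `"comet_image"`: list with `pixels`
#'   (rows x cols matrix, counts), `pixel_size`, `truth_tail_fraction`,
#'   `head_centre`, `head_sigma`, `tail_length` and `seed`.
#' @examples
#' img <- simulate_comet_image(0.4)
#' score_comet(img)$tail_intensity
#' @export
simulate_comet_image <- function(tail_fraction, head_sigma = 2,
                                 tail_length = 450, total_signal = 1e5,
                                 noise_model = c("none", "poisson",
                                                 "gaussian"),
                                 noise_sd = 10, size = c(128L, 1024L),
                                 head_centre = NULL, tail_width = 2,
                                 seed = NULL) {
  noise_model <- match.arg(noise_model)
  if (!is.numeric(tail_fraction) || tail_fraction < 0 || tail_fraction > 1)
    stop("'tail_fraction' must lie in [0, 1]", call. = FALSE)
  if (total_signal < 0) stop("'total_signal' must be non-negative",
                             call. = FALSE)
  nr <- as.integer(size[1L]); nc <- as.integer(size[2L])
  if (is.null(head_centre)) head_centre <- c(round(nr / 2), 96L)
  r0 <- head_centre[1L]; c0 <- head_centre[2L]
  if (r0 < 1 || r0 > nr || c0 < 1 || c0 > nc)
    stop("head centre outside the frame", call. = FALSE)
  if (c0 + tail_length > nc)
    stop("tail decay length does not fit inside the frame", call. = FALSE)

  rows <- seq_len(nr); cols <- seq_len(nc)
  gy_head <- exp(-((rows - r0)^2) / (2 * head_sigma^2))
  gx_head <- exp(-((cols - c0)^2) / (2 * head_sigma^2))
  head_k <- outer(gy_head, gx_head)
  gy_tail <- exp(-((rows - r0)^2) / (2 * tail_width^2))
  gx_tail <- ifelse(cols >= c0, exp(-(cols - c0) / tail_length), 0)
  tail_k <- outer(gy_tail, gx_tail)

  px <- matrix(0, nr, nc)
  if (total_signal > 0) {
    if (tail_fraction < 1)
      px <- px + head_k * (total_signal * (1 - tail_fraction) / sum(head_k))
    if (tail_fraction > 0)
      px <- px + tail_k * (total_signal * tail_fraction / sum(tail_k))
  }
  px <- with_seed(seed, switch(noise_model,
    none = px,
    poisson = matrix(stats::rpois(length(px), px), nr, nc),
    gaussian = pmax(px + matrix(stats::rnorm(length(px), 0, noise_sd),
                                nr, nc), 0)
  ))
  structure(list(pixels = px, pixel_size = 1,
                 truth_tail_fraction = tail_fraction,
                 head_centre = c(row = r0, col = c0),
                 head_sigma = head_sigma, tail_length = tail_length,
                 seed = seed),
            class = "comet_image")
}

#' @export
print.comet_image <- function(x, ...) {
  cat(sprintf("Comet image %d x %d px, total signal %.3g%s\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              if (is.null(x$truth_tail_fraction) ||
                  is.na(x$truth_tail_fraction)) "" else
                sprintf(", truth tail fraction %.3f",
                        x$truth_tail_fraction)))
  invisible(x)
}

corner_pixels <- function(px, k = 8L) {
  nr <- nrow(px); nc <- ncol(px)
  k <- min(k, nr, nc)
  c(px[1:k, 1:k], px[1:k, (nc - k + 1):nc],
    px[(nr - k + 1):nr, 1:k], px[(nr - k + 1):nr, (nc - k + 1):nc])
}

# Intensity-weighted row SD of the head, estimated from columns strictly
# left of the head centre (the tail extends right only, so the left half
# is pure head signal).
head_sigma_estimate <- function(I, c0) {
  left <- I[, seq_len(max(c0 - 1L, 1L)), drop = FALSE]
  w <- pmax(left, 0)
  if (sum(w) <= 0) return(NA_real_)
  rows <- seq_len(nrow(I))
  wr <- rowSums(w)
  mu <- sum(rows * wr) / sum(wr)
  sqrt(sum(wr * (rows - mu)^2) / sum(wr))
}

fit_gaussian_head <- function(I, r0, c0, sigma0) {
  # symmetric 2-D Gaussian fit on the head-only (left) side of the peak
  win <- ceiling(4 * max(sigma0, 1))
  rr <- max(1L, r0 - win):min(nrow(I), r0 + win)
  cc <- max(1L, c0 - win):c0
  sub <- I[rr, cc, drop = FALSE]
  obj <- function(p) {
    a <- exp(p[1L]); mr <- p[2L]; mc <- p[3L]; s <- exp(p[4L])
    mdl <- a * outer(exp(-((rr - mr)^2) / (2 * s^2)),
                     exp(-((cc - mc)^2) / (2 * s^2)))
    sum((mdl - sub)^2)
  }
  fit <- stats::optim(c(log(max(sub)), r0, c0, log(max(sigma0, 1))), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 500))
  list(r0 = fit$par[2L], c0 = fit$par[3L], sigma = exp(fit$par[4L]))
}

#' Score a comet image into a tail-intensity percentage
#'
#' Desk-scale replacement for a commercial comet scorer. The image is
#' background-subtracted, the comet is segmented as the largest connected
#' above-background component, the head is located and sized, and the
#' tail intensity is the percentage of comet signal lying beyond the head
#' disk on the anode (+x) side:
#' `100 * signal(outside head disk, col > head centre) / total comet
#' signal`. Head and tail percentages sum to 100 by construction. The
#' scorer is deterministic.
#'
#' @param image A [simulate_comet_image()] object, or a numeric matrix of
#'   non-negative pixel intensities.
#' @param background_policy `"corner-median"` (median of the four 8x8
#'   corner patches) or a single number giving a fixed background level.
#' @param head_policy `"brightest-disk"` (head centre at the brightest
#'   smoothed pixel) or `"fit-gaussian"` (symmetric 2-D Gaussian fit
#'   around the peak); either way the head region is a disk of radius
#'   `k * FWHM` of the head Gaussian.
#' @param k Head-disk radius multiplier on the head FWHM.
#' @return An object of class `"comet_score"`: list with
#'   `tail_intensity`, `head_pct`, `background`, `head_centre`,
#'   `head_sigma`, `head_radius`, `truth_tail_fraction` (if known) and
#'   logical `masks` (`comet`, `head`, `tail`).
#' @export
score_comet <- function(image, background_policy = "corner-median",
                        head_policy = c("brightest-disk", "fit-gaussian"),
                        k = 1.5) {
  head_policy <- match.arg(head_policy)
  truth <- NA_real_
  if (inherits(image, "comet_image")) {
    truth <- image$truth_tail_fraction
    px <- image$pixels
  } else if (is.matrix(image) && is.numeric(image)) {
    px <- image
  } else stop("'image' must be a comet_image or a numeric matrix",
              call. = FALSE)
  if (any(px < 0)) stop("pixel intensities must be non-negative",
                        call. = FALSE)

  if (identical(background_policy, "corner-median")) {
    corners <- corner_pixels(px)
    bg <- stats::median(corners)
    noise_sd <- stats::mad(corners)
  } else if (is.numeric(background_policy) &&
             length(background_policy) == 1L) {
    bg <- background_policy
    noise_sd <- 0
  } else stop("unknown background policy", call. = FALSE)

  peak <- max(px)
  if (peak <= bg)
    stop("image unscorable: no signal above background", call. = FALSE)
  thr <- bg + max(3 * noise_sd, 1e-6 * (peak - bg))
  mask0 <- px > thr
  if (!any(mask0))
    stop("image unscorable: no pixels above background", call. = FALSE)

  lab <- EBImage::bwlabel(mask0 * 1)
  sizes <- tabulate(lab[lab > 0])
  main <- which.max(sizes)
  if (length(sizes) > 1L && sort(sizes, decreasing = TRUE)[2L] >=
      0.5 * sizes[main])
    warning("multiple comparable objects found; scoring the largest",
            call. = FALSE)
  comet_mask <- lab == main
  # recapture the sub-threshold fringe around the component
  comet_mask <- EBImage::dilate(comet_mask * 1,
                                EBImage::makeBrush(5, "disc")) > 0

  I <- pmax(px - bg, 0)
  I[!comet_mask] <- 0
  total <- sum(I)
  if (total <= 0) stop("image unscorable: empty component", call. = FALSE)

  sm <- EBImage::filter2(px, matrix(1 / 9, 3, 3))
  sm[!comet_mask] <- -Inf
  pk <- which(sm == max(sm), arr.ind = TRUE)[1L, ]
  r0 <- as.integer(pk[1L]); c0 <- as.integer(pk[2L])
  sigma <- head_sigma_estimate(I, c0)
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  if (head_policy == "fit-gaussian") {
    fg <- fit_gaussian_head(I, r0, c0, sigma)
    r0c <- fg$r0; c0c <- fg$c0; sigma <- fg$sigma
  } else {
    r0c <- r0; c0c <- c0
  }
  fwhm <- 2 * sqrt(2 * log(2)) * sigma
  r_head <- k * fwhm

  rows <- seq_len(nrow(px)); cols <- seq_len(ncol(px))
  dist2 <- outer((rows - r0c)^2, (cols - c0c)^2, `+`)
  head_disk <- dist2 <= r_head^2
  tail_mask <- comet_mask & !head_disk &
    matrix(cols > c0c, nrow(px), ncol(px), byrow = TRUE)
  head_mask <- comet_mask & !tail_mask

  tail_pct <- 100 * sum(I[tail_mask]) / total
  structure(list(tail_intensity = tail_pct, head_pct = 100 - tail_pct,
                 background = bg,
                 head_centre = c(row = r0c, col = c0c),
                 head_sigma = sigma, head_radius = r_head,
                 truth_tail_fraction = truth,
                 masks = list(comet = comet_mask, head = head_mask,
                              tail = tail_mask)),
            class = "comet_score")
}

#' @export
print.comet_score <- function(x, digits = 2, ...) {
  cat(sprintf("Comet score: tail %.2f%%, head %.2f%% (background %.3g)\n",
              x$tail_intensity, x$head_pct, x$background))
  if (!is.na(x$truth_tail_fraction))
    cat(sprintf("  ground truth tail: %.2f%%\n",
                100 * x$truth_tail_fraction))
  invisible(x)
}

TIFF_MAX <- 65535

#' Write a comet image as a 16-bit grayscale TIFF
#'
#' The image is scaled to the full 16-bit dynamic range (the convention of
#' microscopy acquisitions; scoring is ratio-based, so the absolute scale
#' is immaterial). If the image carries a ground-truth tail fraction it is
#' written to a `<path>.truth` sidecar.
#'
#' @param image A `comet_image`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_comet_tiff <- function(image, path) {
  stopifnot(inherits(image, "comet_image"))
  peak <- max(image$pixels)
  scaled <- if (peak > 0) image$pixels / peak else image$pixels
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L,
                  compression = "none")
  if (!is.null(image$truth_tail_fraction) &&
      !is.na(image$truth_tail_fraction))
    writeLines(sprintf("truth_tail_fraction=%.17g",
                       image$truth_tail_fraction),
               paste0(path, ".truth"))
  invisible(path)
}

#' Read a grayscale comet TIFF
#'
#' @param path TIFF path; a `<path>.truth` sidecar, if present, restores
#'   the ground-truth tail fraction.
#' @return A `comet_image` (head geometry fields unset).
#' @export
read_comet_tiff <- function(path) {
  px <- tiff::readTIFF(path) * TIFF_MAX
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  truth <- NA_real_
  sidecar <- paste0(path, ".truth")
  if (file.exists(sidecar)) {
    kv <- read_truth_sidecar(sidecar)
    if (!is.null(kv$truth_tail_fraction)) truth <- kv$truth_tail_fraction
  }
  structure(list(pixels = px, pixel_size = 1,
                 truth_tail_fraction = truth, head_centre = NULL,
                 head_sigma = NA_real_, tail_length = NA_real_,
                 seed = NULL),
            class = "comet_image")
}

#' Score every comet TIFF in a directory
#'
#' @param dir Directory containing single-comet TIFF files.
#' @param pattern Filename regular expression.
#' @param ... Passed to [score_comet()].
#' @return A `data.frame` with `file`, `tail_intensity` and
#'   `truth_tail_pct` (NA when no sidecar is present); unscorable images
#'   are skipped with a warning.
#' @export
score_comet_dir <- function(dir, pattern = "\\.tiff?$", ...) {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  rows <- lapply(files, function(f) {
    img <- read_comet_tiff(f)
    sc <- tryCatch(score_comet(img, ...), error = function(e) {
      warning(sprintf("%s: %s", basename(f), conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(sc)) return(NULL)
    data.frame(file = basename(f), tail_intensity = sc$tail_intensity,
               truth_tail_pct = 100 * img$truth_tail_fraction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))],
                   list(make.row.names = FALSE)))
}
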