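#' Sierpinski-type carpet masks
#'
#' Exact monofractal fixtures for the box-counting estimator. The
#' deterministic variant iterates a fixed `b` x `b` retention mask (default:
#' the classical Sierpinski carpet, base 3 with the centre removed); the
#' random variant retains `m` cells uniformly at random within every
#' occupied cell at every level. Both have analytic box-counting dimension
#' `ln(m) / ln(b)`, and for the deterministic variant the occupied-box
#' counts at the construction scales `b^j` are exactly `m^(levels - j)`.
#'
#' @param b Subdivision base (mask side).
#' @param levels Construction depth; the mask is `b^levels` pixels per side
#'   (capped at 2048).
#' @param keep Optional `b` x `b` 0/1 retention mask for the deterministic
#'   variant. Default: base-3 centre-removed (m = 8).
#' @param m Number of retained cells for the random variant (1 to `b^2`);
#'   ignored when `keep` is given.
#' @param seed RNG seed for the random variant.
#' @return An integer 0/1 matrix of side `b^levels`, with attribute
#'   `analytic_df = ln(m)/ln(b)`.
#' @examples
#' sum(make_carpet(levels = 4)) # 8^4 = 4096 foreground pixels
#' @export
make_carpet <- function(b = 3, levels = 4, keep = NULL, m = NULL,
                        seed = NULL) {
  b <- as.integer(b)
  if (b^levels > 2048) {
    stop("b^levels exceeds 2048 pixels per side", call. = FALSE)
  }
  random <- is.null(keep) && !is.null(m)
  if (is.null(keep) && is.null(m)) {
    keep <- matrix(1L, b, b)
    keep[ceiling(b / 2), ceiling(b / 2)] <- 0L
  }
  if (!random) {
    if (!is.matrix(keep) || any(dim(keep) != b) || !all(keep %in% 0:1)) {
      stop("keep must be a b x b 0/1 matrix", call. = FALSE)
    }
    m_eff <- sum(keep)
    if (m_eff < 1) stop("keep must retain at least one cell", call. = FALSE)
    cur <- matrix(1L, 1, 1)
    for (lev in seq_len(levels)) cur <- kronecker(cur, keep)
  } else {
    m_eff <- as.integer(m)
    if (m_eff < 1 || m_eff > b^2) {
      stop("m must lie in [1, b^2]", call. = FALSE)
    }
    if (!is.null(seed)) set.seed(seed)
    cur <- matrix(1L, 1, 1)
    for (lev in seq_len(levels)) {
      n <- nrow(cur)
      nxt <- matrix(0L, n * b, n * b)
      occ <- which(cur == 1L, arr.ind = TRUE)
      for (k in seq_len(nrow(occ))) {
        block <- integer(b * b)
        block[sample.int(b * b, m_eff)] <- 1L
        i <- occ[k, 1]
        j <- occ[k, 2]
        nxt[((i - 1L) * b + 1L):(i * b), ((j - 1L) * b + 1L):(j * b)] <-
          matrix(block, b, b)
      }
      cur <- nxt
    }
  }
  attr(cur, "analytic_df") <- log(m_eff) / log(b)
  cur
}

#' Binomial multiplicative cascade measures
#'
#' Exact multifractal fixtures: a unit mass is split recursively over a
#' `b` x `b` subdivision with fixed weights, so every box at construction
#' scale `b^-j` carries an exact product of weights. The analytic spectrum
#' is `tau(Q) = -log_b sum(w_i^Q)`,
#' `alpha(Q) = -sum(w_i^Q log w_i) / (log(b) sum(w_i^Q))`,
#' `f(Q) = Q alpha(Q) - tau(Q)`; equal weights give a uniform measure
#' (point spectrum). An optional shuffle randomizes the placement of the
#' weights independently in every cell; it rearranges the measure without
#' changing the spectrum. The raw float measure is returned (8-bit
#' quantization would destroy deep-level mass ratios); use
#' [measure_to_gray()] for an image export.
#'
#' @param weights Non-negative weights of length `b^2`, summing to 1.
#'   Default `c(0.4, 0.3, 0.2, 0.1)` (b = 2).
#' @param levels Construction depth; output side is `b^levels` (<= 2048).
#' @param shuffle If `TRUE`, permute the weight placement per cell.
#' @param seed RNG seed for the shuffle.
#' @return A numeric matrix summing to 1, with attribute `weights`.
#' @examples
#' m <- make_cascade(levels = 5)
#' sum(m) # 1
#' @export
make_cascade <- function(weights = c(0.4, 0.3, 0.2, 0.1), levels = 6,
                         shuffle = FALSE, seed = NULL) {
  b <- as.integer(round(sqrt(length(weights))))
  if (b^2 != length(weights)) {
    stop("weights must have length b^2 for integer b", call. = FALSE)
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  if (b^levels > 2048) {
    stop("b^levels exceeds 2048 pixels per side", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  wmat <- matrix(weights, b, b)
  cur <- matrix(1, 1, 1)
  for (lev in seq_len(levels)) {
    if (!shuffle) {
      cur <- kronecker(cur, wmat)
    } else {
      n <- nrow(cur)
      nxt <- matrix(0, n * b, n * b)
      for (j in seq_len(n)) {
        for (i in seq_len(n)) {
          wm <- matrix(sample(weights), b, b)
          nxt[((i - 1L) * b + 1L):(i * b), ((j - 1L) * b + 1L):(j * b)] <-
            cur[i, j] * wm
        }
      }
      cur <- nxt
    }
  }
  attr(cur, "weights") <- weights
  cur
}

#' Analytic spectrum of a binomial cascade
#'
#' Closed-form `alpha(Q)` and `f(Q)` of the cascade measure defined by
#' `weights`, for validating the [mf_spectrum()] estimator.
#'
#' @param weights Cascade weights (length `b^2`, summing to 1).
#' @param q_grid Moment orders.
#' @return A tibble: `q`, `alpha`, `f_alpha`, `tau`.
#' @export
cascade_spectrum <- function(weights, q_grid = seq(-10, 10, by = 0.5)) {
  b <- as.integer(round(sqrt(length(weights))))
  w <- weights[weights > 0]
  purrr::map_dfr(q_grid, function(q) {
    s <- sum(w^q)
    tau <- -log(s) / log(b)
    alpha <- -sum(w^q * log(w)) / (log(b) * s)
    tibble::tibble(q = q, alpha = alpha, f_alpha = q * alpha - tau,
                   tau = tau)
  })
}

#' Rescale a raw measure to an 8-bit grayscale image
#'
#' @param measure Non-negative matrix (e.g. from [make_cascade()]).
#' @return Integer matrix, max mapped to 255.
#' @export
measure_to_gray <- function(measure) {
  stopifnot(max(measure) > 0)
  matrix(as.integer(round(255 * measure / max(measure))),
         nrow(measure), ncol(measure))
}

#' Pseudo-tissue micrograph generator
#'
#' Emulates the intensity landscape of a bright-field transmission
#' micrograph of a thin tissue section, where transmitted intensity tracks
#' local mass density. Three layers compose the image: a constant
#' transmission floor (the minimum optical signal of the mounted section),
#' a diffuse spatially correlated matrix (spectral synthesis with a
#' power-law spectrum, one-sided so mass only adds signal), and
#' Poisson-scattered Gaussian deposits with long-tailed lognormal
#' amplitudes — the mass-accumulation hot-spots.
#'
#' The `severity` knob (0 = control-like, 1 = disease-like) emulates
#' progressive, focal mass accumulation: deposits become more numerous
#' (+90% at severity 1), slightly brighter and more variable in amplitude,
#' more compact (aggregate-like), speckled at pixel scale (nanoscale
#' mass-density granularity), and — crucially — spatially clustered into
#' image-scale hot zones, leaving cold zones control-like. Together these
#' drive the framework's trajectory and localization metrics in the
#' disease direction: higher MeanDf and Mean(lnDtf) at every threshold
#' above the floor, higher STDDf and STD(lnDtf) at the optimal contrast
#' thresholds, and higher mean IPR at every window size. Thresholds at or
#' below the floor give exactly full masks (Df = 2) in both groups, so
#' the sweep's informative range starts above the floor. The severity
#' knob does not reliably widen the image-level multifractal bandwidth at
#' the default box scales; see the methods vignette for why, and use
#' [make_cascade()] for bandwidth ground truth.
#'
#' @param size Image side in pixels.
#' @param floor_intensity Transmission floor (grayscale units); every
#'   pixel is at least this bright.
#' @param matrix_scale Amplitude of the diffuse correlated matrix.
#' @param corr_exponent Power-law exponent of the matrix field's power
#'   spectrum (larger = smoother, longer-ranged correlation).
#' @param clump_density Expected deposits per pixel at severity 0; grows
#'   by a factor `1 + 0.9 * severity`.
#' @param clump_sigma Deposit radius (Gaussian sigma, pixels) at severity
#'   0; shrinks by `0.6 * severity` (compact aggregates).
#' @param clump_meanlog Log-mean of lognormal deposit amplitudes at
#'   severity 0; grows by `0.1 * severity`.
#' @param clump_sdlog Log-sd of deposit amplitudes at severity 0; grows by
#'   `0.2 * severity`.
#' @param cluster_strength Severity-scaled log-weight of the deposit
#'   placement density on the hot-zone field (an image-scale correlated
#'   field, exponent 3.5): 0 scatters deposits uniformly, larger values
#'   concentrate them into focal zones.
#' @param noise_eta Pixel-level lognormal speckle sd on the deposits
#'   (applied scaled by severity); emulates the granularity of disease
#'   aggregates.
#' @param severity Disease-severity knob in `[0, 1]`.
#' @param seed RNG seed; the generator is deterministic given
#'   `(parameters, seed)`.
#' @return An integer grayscale matrix in `[0, 255]`.
#' @examples
#' img <- make_pseudo_tissue(size = 64, severity = 1, seed = 7)
#' @export
make_pseudo_tissue <- function(size = 480, floor_intensity = 40,
                               matrix_scale = 25, corr_exponent = 3,
                               clump_density = 1.2e-2, clump_sigma = 2.5,
                               clump_meanlog = log(90), clump_sdlog = 0.25,
                               cluster_strength = 0.8, noise_eta = 0.6,
                               severity = 0, seed = NULL) {
  stopifnot(severity >= 0, severity <= 1, size >= 8)
  if (!is.null(seed)) set.seed(seed)
  struct <- matrix_scale * pmax(correlated_field(size, corr_exponent), 0)
  zones <- correlated_field(size, 3.5)
  n_clumps <- stats::rpois(1, clump_density * (1 + 0.9 * severity) * size^2)
  sigma <- clump_sigma - 0.6 * severity
  if (n_clumps > 0) {
    weights <- exp(cluster_strength * severity * zones)
    pos <- sample.int(size^2, n_clumps, replace = TRUE,
                      prob = as.vector(weights))
    cy <- (pos - 1L) %% size + 1L
    cx <- (pos - 1L) %/% size + 1L
    amp <- stats::rlnorm(n_clumps, clump_meanlog + 0.1 * severity,
                         clump_sdlog + 0.2 * severity)
    half <- ceiling(3 * sigma)
    offs <- seq(-half, half)
    kernel <- exp(-outer(offs^2, offs^2, "+") / (2 * sigma^2))
    for (k in seq_len(n_clumps)) {
      i0 <- cy[k]
      j0 <- cx[k]
      ii <- max(1, i0 - half):min(size, i0 + half)
      jj <- max(1, j0 - half):min(size, j0 + half)
      patch <- amp[k] * kernel[ii - i0 + half + 1L, jj - j0 + half + 1L]
      if (noise_eta > 0 && severity > 0) {
        patch <- patch * exp(noise_eta * severity *
                               matrix(stats::rnorm(length(patch)),
                                      nrow(patch), ncol(patch)))
      }
      struct[ii, jj] <- struct[ii, jj] + patch
    }
  }
  matrix(as.integer(pmin(255, round(floor_intensity + struct))), size, size)
}

# Zero-mean, unit-variance spatially correlated field via spectral
# synthesis: white noise filtered by |k|^(-corr_exponent/2).
correlated_field <- function(size, corr_exponent) {
  noise <- matrix(stats::rnorm(size^2), size, size)
  freq <- c(0:(size %/% 2), -((size - size %/% 2 - 1):1)) / size
  k2 <- outer(freq^2, freq^2, "+")
  amp <- k2^(-corr_exponent / 4)
  amp[1, 1] <- 0 # kill the DC mode; the floor supplies the mean
  filtered <- Re(stats::fft(stats::fft(noise) * amp, inverse = TRUE))
  (filtered - mean(filtered)) / stats::sd(filtered)
}

#' Anderson lattice with i.i.d. uniform site disorder
#'
#' The textbook disordered tight-binding fixture: site potentials drawn
#' i.i.d. from `Uniform(-W/2, W/2)` in units of the hopping. The mean IPR
#' grows monotonically with the disorder width `W` (Anderson
#' localization), which anchors the IPR estimator's simulation tests.
#'
#' @param l Sites per side (>= 2).
#' @param w Disorder width W (>= 0); `w = 0` is the ordered lattice.
#' @param seed RNG seed.
#' @return An `optical_lattice`.
#' @examples
#' ipr_of_lattice(make_anderson(8, w = 10, seed = 1))$mean_ipr
#' @export
make_anderson <- function(l, w, seed = NULL) {
  stopifnot(l >= 2, w >= 0)
  if (!is.null(seed)) set.seed(seed)
  eps <- matrix(stats::runif(l * l, -w / 2, w / 2), l, l)
  new_lattice(l, eps)
}
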