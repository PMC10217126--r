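# Stochastic 2D breast phantoms: random outer ellipse, layered tissue
# geometry (adipose shell, transitional band, fibro-glandular blobs),
# optional tumors grown inside fibro-glandular regions, and per-pixel
# dielectric maps.

# star-shaped random blob: radius as a truncated Fourier series of angle
sample_blob_shape <- function(base_radius, harmonics, amplitude) {
  a <- rnorm(harmonics, 0, amplitude / seq_len(harmonics))
  b <- rnorm(harmonics, 0, amplitude / seq_len(harmonics))
  # bound total perturbation so the radius stays positive and star-shaped
  tot <- sum(abs(a)) + sum(abs(b))
  if (tot > 0.6) { a <- a * 0.6 / tot; b <- b * 0.6 / tot }
  list(base = base_radius, a = a, b = b)
}

blob_radius <- function(shape, theta) {
  r <- rep(1, length(theta))
  for (h in seq_along(shape$a))
    r <- r + shape$a[h] * cos(h * theta) + shape$b[h] * sin(h * theta)
  shape$base * r
}

# TRUE for pixels (px, py) inside the star blob centred at (cx, cy)
blob_mask <- function(px, py, cx, cy, shape, scale = 1) {
  dx <- px - cx; dy <- py - cy
  sqrt(dx^2 + dy^2) <= scale * blob_radius(shape, atan2(dy, dx))
}

#' Draw the breast outer outline
#'
#' Samples an ellipse with both full axis lengths uniform in the configured
#' range (default \[6.5, 12\] cm) and orientation uniform in \[0, 2 pi).
#' The centre defaults to the domain origin; with `center_jitter > 0` it is
#' resampled until the ellipse fits entirely inside the imaging domain.
#'
#' @param config an [generator_config()].
#' @param seed optional integer seed.
#' @return list with `semi_a`, `semi_b` (cm), `phi` (radians), `cx`, `cy`.
#' @export
sample_outer_shape <- function(config, seed = NULL) {
  with_seed(seed, {
    ax <- runif(1, config$ellipse_axis_range[1], config$ellipse_axis_range[2])
    bx <- runif(1, config$ellipse_axis_range[1], config$ellipse_axis_range[2])
    phi <- runif(1, config$orientation_range[1], config$orientation_range[2])
    half <- config$grid$side_length / 2
    for (try in seq_len(config$max_retries)) {
      cx <- if (config$center_jitter > 0) runif(1, -config$center_jitter, config$center_jitter) else 0
      cy <- if (config$center_jitter > 0) runif(1, -config$center_jitter, config$center_jitter) else 0
      # bounding half-extents of a rotated ellipse
      ex <- sqrt((ax / 2 * cos(phi))^2 + (bx / 2 * sin(phi))^2)
      ey <- sqrt((ax / 2 * sin(phi))^2 + (bx / 2 * cos(phi))^2)
      if (abs(cx) + ex <= half && abs(cy) + ey <= half)
        return(list(semi_a = ax / 2, semi_b = bx / 2, phi = phi, cx = cx, cy = cy))
    }
    abort("could not place the outer ellipse inside the imaging domain.",
          class = "mwtomo_placement_failure")
  })
}

# normalised elliptical radius: 1 on the outline, < 1 inside
elliptical_radius <- function(ellipse, x, y) {
  dx <- x - ellipse$cx; dy <- y - ellipse$cy
  xr <- cos(ellipse$phi) * dx + sin(ellipse$phi) * dy
  yr <- -sin(ellipse$phi) * dx + cos(ellipse$phi) * dy
  sqrt((xr / ellipse$semi_a)^2 + (yr / ellipse$semi_b)^2)
}

# binary dilation of a mask by a disc of physical radius w (cm)
dilate_mask <- function(mask, w, pixel_size) {
  r <- floor(w / pixel_size)
  if (r < 1) return(mask)
  n <- nrow(mask)
  out <- mask
  for (di in -r:r) for (dj in -r:r) {
    if (di == 0 && dj == 0) next
    if ((di^2 + dj^2) * pixel_size^2 > w^2) next
    si <- max(1, 1 - di):min(n, n - di)
    sj <- max(1, 1 - dj):min(n, n - dj)
    out[si + di, sj + dj] <- out[si + di, sj + dj] | mask[si, sj]
  }
  out
}

#' Generate the healthy tissue label map
#'
#' Fills the breast interior with adipose tissue, grows random star-shaped
#' fibro-glandular blobs (truncated Fourier-series boundary perturbations of
#' circles, rasterised on pixel centres) whose overall scale is bisected so
#' the fibro-glandular area fraction lands inside the target density-class
#' bin, and surrounds them with a transitional band. Pixels outside the
#' ellipse carry the background label.
#'
#' @param ellipse from [sample_outer_shape()].
#' @param target_class one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param config an [generator_config()].
#' @param seed optional integer seed.
#' @return integer label matrix (`n_pixels` x `n_pixels`); codes
#'   0 background, 1 adipose, 2 transitional, 3 fibroglandular.
#' @export
generate_tissue_map <- function(ellipse, target_class, config, seed = NULL) {
  stopifnot(target_class %in% names(config$class_bins))
  with_seed(seed, {
    grid <- config$grid
    co <- grid_coords(grid)
    u <- elliptical_radius(ellipse, co$x, co$y)
    interior <- u <= 1
    n_int <- sum(interior)
    if (n_int < 1) abort("ellipse contains no pixels.", class = "mwtomo_placement_failure")
    bin <- config$class_bins[[target_class]]

    for (attempt in seq_len(config$max_retries)) {
      f_target <- runif(1, bin[1], bin[2])
      nb <- sample(config$fg_blob_count[1]:config$fg_blob_count[2], 1)
      # blob centres well inside the outline; base radii relative to breast size
      mean_semi <- (ellipse$semi_a + ellipse$semi_b) / 2
      shapes <- vector("list", nb)
      centers <- matrix(0, nb, 2)
      for (k in seq_len(nb)) {
        # uniform over the central part of the ellipse (normalised radius <= 0.55)
        th <- runif(1, 0, 2 * pi); rr <- sqrt(runif(1)) * 0.55
        xr <- rr * ellipse$semi_a * cos(th); yr <- rr * ellipse$semi_b * sin(th)
        centers[k, ] <- c(
          ellipse$cx + cos(ellipse$phi) * xr - sin(ellipse$phi) * yr,
          ellipse$cy + sin(ellipse$phi) * xr + cos(ellipse$phi) * yr)
        shapes[[k]] <- sample_blob_shape(mean_semi * runif(1, 0.25, 0.5),
                                         config$fg_harmonics, config$fg_amplitude)
      }
      core <- interior & (u <= 0.92)  # keep a margin of non-FG tissue at the rim

      fg_fraction <- function(s) {
        fg <- matrix(FALSE, grid$n_pixels, grid$n_pixels)
        for (k in seq_len(nb)) {
          cand <- core & !fg
          if (!any(cand)) break
          fg[cand] <- blob_mask(co$x[cand], co$y[cand],
                                centers[k, 1], centers[k, 2], shapes[[k]], s)
        }
        fg
      }
      # bisection on the common blob scale to hit the target fraction
      lo <- 0; hi <- 4; fg <- NULL
      if (sum(fg_fraction(hi)) / n_int < f_target) next  # unreachable; redraw blobs
      for (it in 1:18) {
        mid <- (lo + hi) / 2
        fg <- fg_fraction(mid)
        fr <- sum(fg) / n_int
        if (fr < f_target) lo <- mid else hi <- mid
      }
      fg <- fg_fraction(hi)
      fr <- sum(fg) / n_int
      in_bin <- fr >= bin[1] && (fr < bin[2] || (target_class == "D" && fr <= bin[2]))
      if (!in_bin) next

      w <- runif(1, config$transition_width_range[1], config$transition_width_range[2])
      trans <- dilate_mask(fg, w, grid$pixel_size) & !fg & interior

      lab <- matrix(.LBL[["background"]], grid$n_pixels, grid$n_pixels)
      lab[interior] <- .LBL[["adipose"]]
      lab[trans] <- .LBL[["transitional"]]
      lab[fg] <- .LBL[["fibroglandular"]]
      return(lab)
    }
    abort(sprintf("failed to reach class-%s fibro-glandular fraction in %d attempts.",
                  target_class, config$max_retries),
          class = "mwtomo_class_targeting_failure")
  })
}

#' Density class of a label map
#'
#' Returns the density class whose fibro-glandular fraction bin (fraction of
#' breast-interior pixels labelled fibro-glandular) contains the map's
#' fraction. Bins are half-open `[lo, hi)` except class D, closed at 65%.
#'
#' @param label_map integer label matrix.
#' @param config an [generator_config()] (for the bin edges).
#' @return `"A"`, `"B"`, `"C"` or `"D"`.
#' @export
assign_density_class <- function(label_map, config = generator_config()) {
  interior <- label_map != .LBL[["background"]]
  if (!any(interior)) abort("label map has no interior pixels.", class = "mwtomo_bad_input")
  fg <- label_map == .LBL[["fibroglandular"]] | label_map == .LBL[["tumor"]]
  # tumors replace fibro-glandular pixels; count them towards the dense fraction
  fr <- sum(fg) / sum(interior)
  bins <- config$class_bins
  last <- names(bins)[length(bins)]
  for (cl in names(bins)) {
    b <- bins[[cl]]
    if (fr >= b[1] && (fr < b[2] || (cl == last && fr <= b[2]))) return(cl)
  }
  abort(sprintf("fibro-glandular fraction %.3f lies outside every density-class bin.", fr),
        class = "mwtomo_class_out_of_range")
}

# grow a connected tumor of exactly n_px pixels inside fibro-glandular
# tissue, shaped by a star blob: pixels are added in increasing order of
# anisotropic distance dist/R(theta) from the seed, restricted to FG.
grow_tumor <- function(fg_idx_mask, center_ij, shape, n_px, grid) {
  n <- grid$n_pixels
  score <- function(i, j) {
    dx <- grid$x[j] - grid$x[center_ij[2]]
    dy <- grid$y[i] - grid$y[center_ij[1]]
    sqrt(dx^2 + dy^2) / max(blob_radius(shape, atan2(dy, dx)), 1e-6)
  }
  sel <- matrix(FALSE, n, n)
  frontier_i <- center_ij[1]; frontier_j <- center_ij[2]
  frontier_s <- 0
  taken <- 0L
  while (taken < n_px && length(frontier_i) > 0) {
    k <- which.min(frontier_s)
    i <- frontier_i[k]; j <- frontier_j[k]
    frontier_i <- frontier_i[-k]; frontier_j <- frontier_j[-k]; frontier_s <- frontier_s[-k]
    if (sel[i, j]) next
    sel[i, j] <- TRUE; taken <- taken + 1L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii < 1 || ii > n || jj < 1 || jj > n) next
      if (!fg_idx_mask[ii, jj] || sel[ii, jj]) next
      frontier_i <- c(frontier_i, ii); frontier_j <- c(frontier_j, jj)
      frontier_s <- c(frontier_s, score(ii, jj))
    }
  }
  if (taken < n_px) return(NULL)
  sel
}

#' Insert tumors into fibro-glandular tissue
#'
#' Draws the tumor count (default 1/2/3 with probabilities 0.7/0.2/0.1) and,
#' for each tumor, a target area uniform in the configured range (default
#' \[0.2, 9\] cm^2), then grows a connected star-blob-shaped region of
#' exactly `round(area / pixel_area)` pixels strictly inside (remaining)
#' fibro-glandular tissue. The realised pixel area is therefore within half
#' a pixel area of the drawn target. Areas that cannot fit the available
#' fibro-glandular tissue are redrawn from a reduced range.
#'
#' @param label_map integer label matrix (healthy).
#' @param config an [generator_config()].
#' @param pathological if `FALSE` the map is returned unchanged with an
#'   empty descriptor list.
#' @param seed optional integer seed.
#' @return list with `label_map` (tumor pixels recoded to 4) and `tumors`,
#'   a list of descriptors (`area_cm2`, `target_area_cm2`, `n_pixels`,
#'   `centroid` in cm).
#' @export
insert_tumors <- function(label_map, config, pathological = TRUE, seed = NULL) {
  if (!pathological) return(list(label_map = label_map, tumors = list()))
  with_seed(seed, {
    grid <- config$grid
    dA <- grid$pixel_size^2
    lab <- label_map
    tumors <- list()
    n_t <- sample(seq_along(config$tumor_count_probs), 1, prob = config$tumor_count_probs)
    for (t in seq_len(n_t)) {
      fg_mask <- lab == .LBL[["fibroglandular"]]
      avail <- sum(fg_mask) * dA
      if (avail < config$tumor_area_range[1])
        if (t == 1L) abort("fibro-glandular area too small for the smallest tumor.",
                           class = "mwtomo_placement_failure") else break
      placed <- FALSE
      for (attempt in seq_len(config$max_retries)) {
        hi <- min(config$tumor_area_range[2], 0.8 * avail)
        if (hi < config$tumor_area_range[1]) hi <- config$tumor_area_range[1]
        area <- runif(1, config$tumor_area_range[1], hi)
        n_px <- max(1L, as.integer(round(area / dA)))
        if (n_px > sum(fg_mask)) next
        cand <- which(fg_mask, arr.ind = TRUE)
        c_ij <- cand[sample.int(nrow(cand), 1), ]
        shape <- sample_blob_shape(sqrt(area / pi), config$fg_harmonics, config$fg_amplitude)
        sel <- grow_tumor(fg_mask, c_ij, shape, n_px, grid)
        if (is.null(sel)) next
        lab[sel] <- .LBL[["tumor"]]
        idx <- which(sel, arr.ind = TRUE)
        tumors[[length(tumors) + 1L]] <- list(
          area_cm2 = n_px * dA, target_area_cm2 = area, n_pixels = n_px,
          centroid = c(x = mean(grid$x[idx[, 2]]), y = mean(grid$y[idx[, 1]])))
        placed <- TRUE
        break
      }
      if (!placed && t == 1L)
        abort("could not place a tumor inside fibro-glandular tissue.",
              class = "mwtomo_placement_failure")
    }
    list(label_map = lab, tumors = tumors)
  })
}

#' Sample dielectric maps for a label map
#'
#' Assigns every pixel a relative permittivity and conductivity drawn from
#' its tissue's interval (see [tissue_table()]). The default is an
#' independent uniform draw per pixel (maximum-entropy choice given interval
#' constraints); `"correlated"` texture instead maps a spatially smooth
#' Gaussian field through its probability transform into each interval.
#' Background pixels are exactly (15, 0).
#'
#' @param label_map integer label matrix.
#' @param config an [generator_config()].
#' @param seed optional integer seed.
#' @return list of matrices `eps_map`, `sigma_map`.
#' @export
sample_dielectric_maps <- function(label_map, config = generator_config(), seed = NULL) {
  with_seed(seed, {
    tt <- tissue_table()
    if (!all(label_map %in% tt$label))
      abort("label map contains unknown tissue codes.", class = "mwtomo_bad_input")
    n <- nrow(label_map)
    eps <- matrix(0, n, n); sig <- matrix(0, n, n)
    if (config$dielectric_texture == "uniform") {
      u1 <- matrix(runif(n * n), n, n); u2 <- matrix(runif(n * n), n, n)
    } else {
      u1 <- smooth_uniform_field(n, config$texture_scale / config$grid$pixel_size)
      u2 <- smooth_uniform_field(n, config$texture_scale / config$grid$pixel_size)
    }
    for (k in seq_len(nrow(tt))) {
      m <- label_map == tt$label[k]
      if (!any(m)) next
      eps[m] <- tt$eps_min[k] + (tt$eps_max[k] - tt$eps_min[k]) * u1[m]
      sig[m] <- tt$sigma_min[k] + (tt$sigma_max[k] - tt$sigma_min[k]) * u2[m]
    }
    bg <- label_map == .LBL[["background"]]
    eps[bg] <- 15; sig[bg] <- 0
    list(eps_map = eps, sigma_map = sig)
  })
}

# smooth field with ~`scale_px` correlation length, mapped to U(0,1) margins
smooth_uniform_field <- function(n, scale_px) {
  z <- matrix(rnorm(n * n), n, n)
  r <- max(1, round(scale_px))
  k <- outer(seq(-2 * r, 2 * r), seq(-2 * r, 2 * r),
             function(a, b) exp(-(a^2 + b^2) / (2 * r^2)))
  # FFT convolution with wrap-around (texture only; periodicity is harmless)
  np <- n + nrow(k)
  zp <- matrix(0, np, np); zp[1:n, 1:n] <- z
  kp <- matrix(0, np, np); kp[1:nrow(k), 1:ncol(k)] <- k
  s <- Re(stats::fft(stats::fft(zp) * stats::fft(kp), inverse = TRUE)) / np^2
  s <- s[(1:n) + 2 * r, (1:n) + 2 * r]
  matrix(stats::pnorm(scale(as.vector(s))), n, n)
}

#' Generate one breast phantom
#'
#' Composes outline sampling, tissue-map generation, tumor insertion and
#' dielectric sampling into a complete phantom. Fully reproducible from
#' `seed`.
#'
#' @param config an [generator_config()].
#' @param class target density class (`"A"`..`"D"`).
#' @param pathological logical; insert tumors?
#' @param seed integer seed (stored in the phantom).
#' @return an object of class `mwt_phantom` with fields `eps_map`,
#'   `sigma_map`, `label_map`, `density_class`, `is_pathological`, `tumors`,
#'   `grid`, `rng_seed`.
#' @export
generate_phantom <- function(config = generator_config(), class = "B",
                             pathological = FALSE, seed = NULL) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1)
  with_seed(seed, {
    ellipse <- sample_outer_shape(config)
    lab <- generate_tissue_map(ellipse, class, config)
    ins <- insert_tumors(lab, config, pathological)
    maps <- sample_dielectric_maps(ins$label_map, config)
    tumors <- ins$tumors
    # record the realised dielectric summary of each tumor
    if (length(tumors)) {
      tm <- ins$label_map == .LBL[["tumor"]]
      for (k in seq_along(tumors)) {
        tumors[[k]]$eps_mean <- mean(maps$eps_map[tm])
        tumors[[k]]$sigma_mean <- mean(maps$sigma_map[tm])
      }
    }
    structure(
      list(eps_map = maps$eps_map, sigma_map = maps$sigma_map,
           label_map = ins$label_map,
           density_class = assign_density_class(ins$label_map, config),
           is_pathological = pathological, tumors = tumors,
           ellipse = ellipse, grid = config$grid, rng_seed = seed),
      class = "mwt_phantom"
    )
  })
}

#' @export
print.mwt_phantom <- function(x, ...) {
  cat(sprintf("<mwt_phantom> class %s, %s, %d tumor(s), %d x %d grid (seed %d)\n",
              x$density_class,
              if (x$is_pathological) "pathological" else "healthy",
              length(x$tumors), x$grid$n_pixels, x$grid$n_pixels, x$rng_seed))
  invisible(x)
}

#' Plot a phantom's dielectric maps
#'
#' @param object an `mwt_phantom`.
#' @param which `"eps"` or `"sigma"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mwt_phantom <- function(object, which = c("eps", "sigma"), ...) {
  which <- match.arg(which)
  m <- if (which == "eps") object$eps_map else object$sigma_map
  g <- object$grid
  df <- tibble::tibble(
    x = rep(g$x, each = g$n_pixels), y = rep(g$y, times = g$n_pixels),
    value = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = if (which == "eps") "eps'" else "sigma [S/m]") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [cm]", y = "y [cm]")
}
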