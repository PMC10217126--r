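# Amplitude/phase encoding of scattering matrices into the detector's
# n x n x 2 input tensor.

#' Encoding statistics from a training set
#'
#' Mean and standard deviation of the amplitude channel over a list of
#' scattering matrices, frozen at training time and reused verbatim at
#' inference (the validation/test splits never contribute). `by =
#' "element"` standardises each matrix entry separately; `by = "diagonal"`
#' pools entries with equal transmitter-receiver separation `(t - r) mod n`
#' — the statistically homogeneous direction of a circular array — which
#' makes the encoding equivariant under the ring's rotation/reflection
#' symmetry (required when training with [train_detector()]'s symmetry
#' augmentation).
#'
#' @param S_list list of `mwt_scattering` or complex matrices.
#' @param by `"element"` or `"diagonal"`.
#' @return an `mwt_encoding_stats` object (`amp_mean`, `amp_sd` matrices).
#' @export
encoding_stats <- function(S_list, by = c("element", "diagonal")) {
  by <- match.arg(by)
  n <- smat_dim(S_list[[1]])
  amps <- vapply(S_list, function(s) abs(if (inherits(s, "mwt_scattering")) s$S else s),
                 matrix(0, n, n))
  if (by == "element") {
    mu <- apply(amps, c(1, 2), mean)
    sdv <- apply(amps, c(1, 2), sd)
  } else {
    d <- (col(matrix(0, n, n)) - row(matrix(0, n, n))) %% n
    flat <- matrix(amps, n * n, length(S_list))
    mu_d <- vapply(0:(n - 1), function(k) mean(flat[d == k, ]), 0)
    sd_d <- vapply(0:(n - 1), function(k) sd(flat[d == k, ]), 0)
    mu <- matrix(mu_d[d + 1], n, n)
    sdv <- matrix(sd_d[d + 1], n, n)
  }
  sdv[sdv < 1e-12] <- 1e-12
  structure(list(amp_mean = mu, amp_sd = sdv, by = by),
            class = "mwt_encoding_stats")
}

#' Permute a scattering matrix under the array's dihedral symmetry
#'
#' Rotating the imaged scene by `shift` antenna spacings (`2 pi shift / n`)
#' permutes the multistatic matrix by a simultaneous cyclic shift of rows
#' and columns; mirror reflection about the axis through antenna 1 reverses
#' the antenna order. Both are exact symmetries of the continuous
#' acquisition and form the dihedral group used for training augmentation.
#'
#' @param S an `mwt_scattering` or complex matrix.
#' @param shift integer cyclic shift (antenna spacings).
#' @param flip logical; apply the reflection.
#' @return object of the same type as `S`.
#' @export
permute_antennas <- function(S, shift = 0L, flip = FALSE) {
  mat <- if (inherits(S, "mwt_scattering")) S$S else S
  n <- nrow(mat)
  idx <- if (flip) (shift - (0:(n - 1))) %% n + 1L else ((0:(n - 1)) + shift) %% n + 1L
  out <- mat[idx, idx]
  if (inherits(S, "mwt_scattering")) { S$S <- out; S } else out
}

smat_dim <- function(s) nrow(if (inherits(s, "mwt_scattering")) s$S else s)

#' Encode a scattering matrix for the detector
#'
#' Channel 1: amplitude `|S|`, standardised with the frozen training-set
#' per-element mean/sd. Channel 2: phase `Arg(S) / pi` (range (-1, 1];
#' the phase of an exactly zero entry is defined as 0). Deterministic.
#'
#' @param S an `mwt_scattering` or complex matrix.
#' @param stats an [encoding_stats()] object; required.
#' @return numeric array `n x n x 2`.
#' @export
encode_scattering <- function(S, stats) {
  if (missing(stats) || !inherits(stats, "mwt_encoding_stats"))
    abort("encoding `stats` (frozen at training time) are required.",
          class = "mwtomo_missing_stats")
  mat <- if (inherits(S, "mwt_scattering")) S$S else S
  if (!all(is.finite(Re(mat)) & is.finite(Im(mat))))
    abort("scattering matrix contains non-finite entries.", class = "mwtomo_bad_input")
  amp <- abs(mat)
  ph <- Arg(mat) / pi
  ph[amp == 0] <- 0
  out <- array(0, c(nrow(mat), ncol(mat), 2L))
  out[, , 1] <- (amp - stats$amp_mean) / stats$amp_sd
  out[, , 2] <- ph
  out
}

# stack a list of encoded inputs into the (channels, pixels, n) layout the
# C++ network consumes
encode_batch <- function(S_list, stats) {
  n <- smat_dim(S_list[[1]])
  X <- array(0, c(2L, n * n, length(S_list)))
  for (i in seq_along(S_list)) {
    e <- encode_scattering(S_list[[i]], stats)
    X[, , i] <- rbind(as.vector(e[, , 1]), as.vector(e[, , 2]))
  }
  X
}
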