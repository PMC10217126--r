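#' Corrupt a scattering matrix with additive white Gaussian noise
#'
#' Adds i.i.d. circularly-symmetric complex Gaussian noise at a prescribed
#' matrix-level SNR: the per-element complex variance is
#' `||S||_F^2 / (n_elem * 10^(snr_db / 10))`, so that the expected realised
#' SNR `10 log10(||S||^2 / ||N||^2)` equals the request. `snr_db = Inf`
#' returns the input unchanged.
#'
#' @param S an `mwt_scattering` or a complex matrix.
#' @param snr_db signal-to-noise ratio in dB (`Inf` = noise-free).
#' @param seed optional integer seed.
#' @return same type as `S`.
#' @export
add_awgn <- function(S, snr_db, seed = NULL) {
  mat <- if (inherits(S, "mwt_scattering")) S$S else S
  if (!all(is.finite(Re(mat)) & is.finite(Im(mat))))
    abort("scattering matrix contains non-finite entries.", class = "mwtomo_bad_input")
  if (is.infinite(snr_db)) return(S)
  with_seed(seed, {
    n_el <- length(mat)
    p_sig <- sum(abs(mat)^2)
    v <- p_sig / (n_el * 10^(snr_db / 10))   # complex variance per element
    noise <- matrix(complex(real = rnorm(n_el, 0, sqrt(v / 2)),
                            imaginary = rnorm(n_el, 0, sqrt(v / 2))),
                    nrow(mat), ncol(mat))
    out <- mat + noise
    if (inherits(S, "mwt_scattering")) { S$S <- out; S$snr_db <- snr_db; S }
    else out
  })
}

#' Corrupt a list of scattering matrices reproducibly
#'
#' Applies [add_awgn()] to each matrix with an independent sub-seed derived
#' from `seed`, so the full corruption pass is reproducible and the draws
#' for different profiles are independent.
#'
#' @param S_list list of `mwt_scattering` (or matrices).
#' @param snr_db SNR in dB (`Inf` = no-op).
#' @param seed master seed for the pass.
#' @return list, same shape as `S_list`.
#' @export
corrupt_dataset <- function(S_list, snr_db, seed = 1L) {
  if (is.infinite(snr_db)) return(S_list)
  lapply(seq_along(S_list), function(i)
    add_awgn(S_list[[i]], snr_db, seed = derive_seed(seed, "awgn", i)))
}
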