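# Detection-performance metrics: confusion counts at a threshold, the
# rates TPR/FPR/FNR/TNR, ROC sweep with trapezoidal area and equal error
# rate, and the tumor-size-stratified evaluation recipe.

#' Confusion counts at a threshold
#'
#' A profile is called suspicious iff its score is `>= threshold`. `tp`
#' counts correct suspicious assignments, `tn` correct healthy ones, `fp`
#' wrong suspicious, `fn` wrong healthy.
#'
#' @param scores numeric in `[0, 1]`.
#' @param labels binary (1/TRUE = pathological), same length.
#' @param threshold decision threshold.
#' @return an `mwt_confusion` list: `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels))
    abort("`scores` and `labels` lengths differ.", class = "mwtomo_bad_input")
  if (length(scores) < 1L) abort("empty input.", class = "mwtomo_bad_input")
  y <- as.logical(labels)
  pos <- scores >= threshold
  structure(list(tp = sum(pos & y), tn = sum(!pos & !y),
                 fp = sum(pos & !y), fn = sum(!pos & y)),
            class = "mwt_confusion")
}

#' Classification rates from confusion counts
#'
#' `TPR = tp / (tp + fn)`, `FPR = fp / (fp + tn)`, with complements
#' `FNR = 1 - TPR` and `TNR = 1 - FPR`. TPR and TNR are the sensitivity
#' and specificity.
#'
#' @param counts an [confusion_counts()] result.
#' @return tibble with `tpr`, `fpr`, `fnr`, `tnr`.
#' @export
classification_rates <- function(counts) {
  with(counts, {
    if (tp + fn == 0L || fp + tn == 0L)
      abort("a class is absent; rates are undefined.",
            class = "mwtomo_degenerate_class")
    tibble::tibble(tpr = tp / (tp + fn), fpr = fp / (fp + tn),
                   fnr = fn / (tp + fn), tnr = tn / (fp + tn))
  })
}

#' ROC curve, area under ROC, and equal error rate
#'
#' Sweeps the decision threshold over every distinct score (tied scores
#' cross together) plus the two degenerate endpoints, yielding a monotone
#' (FPR, TPR) staircase from (0, 0) to (1, 1). The area under the ROC
#' (AUR) is computed by trapezoidal integration — equivalently the
#' Mann-Whitney probability that a random pathological profile outscores a
#' random healthy one. The equal error rate (EER) is the common error rate
#' at the FPR = FNR crossing, located by linear interpolation along the
#' curve; the crossing threshold is reported alongside.
#'
#' @param scores numeric scores.
#' @param labels binary labels (1 = pathological).
#' @return an `mwt_roc` object: `points` (tibble `threshold`, `fpr`,
#'   `tpr`), `aur`, `eer`, `eer_threshold`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  y <- as.logical(labels)
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L)
    abort("both classes are required for a ROC curve.",
          class = "mwtomo_degenerate_class")
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  grp <- !duplicated(ss)
  tp_cum <- cumsum(ys); fp_cum <- cumsum(!ys)
  last <- c(which(grp[-1]) , length(ss)) # last index of each tie group
  thr <- ss[grp]
  tpr <- c(0, tp_cum[last] / n_pos)
  fpr <- c(0, fp_cum[last] / n_neg)
  pts <- tibble::tibble(threshold = c(Inf, thr), fpr = fpr, tpr = tpr)
  aur <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  # FPR = FNR crossing along the polyline
  fnr <- 1 - tpr
  d <- fpr - fnr             # monotone nondecreasing along the sweep
  k <- which(d >= 0)[1]
  if (k == 1L) {
    eer <- fpr[1]; eth <- pts$threshold[1]
  } else {
    w <- d[k - 1] / (d[k - 1] - d[k]) # in [0,1]
    eer <- (1 - w) * fpr[k - 1] + w * fpr[k]
    eth <- (1 - w) * min(pts$threshold[k - 1], 1) + w * pts$threshold[k]
  }
  structure(list(points = pts, aur = aur, eer = eer, eer_threshold = eth,
                 n_pos = n_pos, n_neg = n_neg),
            class = "mwt_roc")
}

#' @export
print.mwt_roc <- function(x, ...) {
  cat(sprintf("<mwt_roc> %d+/%d- profiles, AUR %.4f, EER %.4f\n",
              x$n_pos, x$n_neg, x$aur, x$eer))
  invisible(x)
}

#' @export
tidy.mwt_roc <- function(x, ...) x$points

#' @export
glance.mwt_roc <- function(x, ...) {
  tibble::tibble(aur = x$aur, eer = x$eer, eer_threshold = x$eer_threshold,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @export
autoplot.mwt_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUR %.3f, EER %.3f", object$aur, object$eer))
}

#' Accuracy, sensitivity and specificity at a fixed threshold
#'
#' @param scores,labels as in [confusion_counts()].
#' @param threshold decision threshold Th (reference setting 0.5).
#' @return tibble: `threshold`, `accuracy`, `sensitivity`, `specificity`.
#' @export
threshold_metrics <- function(scores, labels, threshold = 0.5) {
  cc <- confusion_counts(scores, labels, threshold)
  r <- classification_rates(cc)
  tibble::tibble(threshold = threshold,
                 accuracy = (cc$tp + cc$tn) / (cc$tp + cc$tn + cc$fp + cc$fn),
                 sensitivity = r$tpr, specificity = r$tnr)
}

#' Tumor-size-stratified detection performance
#'
#' Rebuilds the small-tumor evaluation: class-B profiles with exactly one
#' tumor whose area falls in `[0.2, 2.8]` cm^2, divided into `n_bins`
#' equal-width area bins. Each bin's pathological profiles are scored
#' against one shared healthy class-B comparison set, and per-bin AUR/EER
#' are reported.
#'
#' @param model a trained `mwt_detector`.
#' @param config an [generator_config()] (its tumor settings are overridden
#'   per bin: single tumor, area uniform in the bin).
#' @param geometry an [acquisition_geometry()].
#' @param n_per_bin pathological profiles per bin (>= 2).
#' @param n_healthy healthy class-B comparison profiles (>= 2).
#' @param area_range stratified area interval (cm^2).
#' @param n_bins number of equal-width bins.
#' @param snr_db SNR applied to every matrix (Inf = noise-free).
#' @param seed master seed.
#' @param tol,solver forward-solver settings.
#' @return tibble: `bin`, `area_lo`, `area_hi`, `n_pathological`,
#'   `n_healthy`, `aur`, `eer`.
#' @export
size_stratified_eval <- function(model, config, geometry = acquisition_geometry(),
                                 n_per_bin = 10L, n_healthy = 40L,
                                 area_range = c(0.2, 2.8), n_bins = 7L,
                                 snr_db = Inf, seed = 1L, tol = 1e-6,
                                 solver = "direct") {
  if (n_per_bin < 2L || n_healthy < 2L)
    abort("need at least 2 profiles per class per bin.", class = "mwtomo_bad_input")
  edges <- seq(area_range[1], area_range[2], length.out = n_bins + 1L)
  op <- forward_operator(config$grid, geometry)
  single <- config
  single$tumor_count_probs <- c(1, 0, 0)

  simulate_scores <- function(cfg, pathological, n, tag) {
    S <- vector("list", n)
    for (i in seq_len(n)) {
      ph <- generate_phantom(cfg, "B", pathological,
                             seed = derive_seed(seed, tag, i))
      s <- assemble_scattering_matrix(ph, geometry, tol = tol, solver = solver, op = op)
      S[[i]] <- add_awgn(s, snr_db, seed = derive_seed(seed, paste0(tag, "/noise"), i))
    }
    predict(model, S)$score
  }

  healthy_scores <- simulate_scores(single, FALSE, n_healthy, "strat/healthy")
  out <- vector("list", n_bins)
  for (b in seq_len(n_bins)) {
    cfg <- single
    cfg$tumor_area_range <- c(edges[b], edges[b + 1])
    path_scores <- simulate_scores(cfg, TRUE, n_per_bin, paste0("strat/bin", b))
    roc <- roc_curve(c(path_scores, healthy_scores),
                     c(rep(1, n_per_bin), rep(0, n_healthy)))
    out[[b]] <- tibble::tibble(bin = b, area_lo = edges[b], area_hi = edges[b + 1],
                               n_pathological = n_per_bin, n_healthy = n_healthy,
                               aur = roc$aur, eer = roc$eer)
  }
  dplyr::bind_rows(out)
}
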