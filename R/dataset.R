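# Database orchestration: balanced (class x pathology) cells, stratified
# 80/10/10 splits, reproducible per-profile seeds.

# Integer split of `n` into quotas proportional to `frac`, with the
# leftover slots of each cell handed to whichever split is globally
# furthest below its target share (so totals also respect the fractions).
stratified_split_counts <- function(n_cells, n, frac) {
  k <- length(frac)
  counts <- matrix(0L, n_cells, k)
  assigned <- rep(0, k)
  for (cell in seq_len(n_cells)) {
    base <- floor(n * frac)
    rem <- n - sum(base)
    counts[cell, ] <- as.integer(base)
    assigned <- assigned + base
    while (rem > 0) {
      total <- sum(assigned) + 1
      deficit <- frac - assigned / total
      j <- which.max(deficit)
      counts[cell, j] <- counts[cell, j] + 1L
      assigned[j] <- assigned[j] + 1
      rem <- rem - 1
    }
  }
  counts
}

#' Generate a balanced phantom database
#'
#' Builds `n_per_cell` phantoms for every (density class, pathology) cell —
#' 8 cells: classes A-D, healthy and pathological — and assigns
#' train/validation/test membership stratified by cell (default 80/10/10).
#' Every profile's seed derives deterministically from `seed`, so the whole
#' database is reproducible from the manifest. The reference database of
#' the study this package emulates used 20,000 profiles per cell (160,000
#' total); desk-scale runs use far fewer.
#'
#' @param config an [generator_config()].
#' @param n_per_cell profiles per (class, pathology) cell (>= 1).
#' @param split named fractions for `train`, `val`, `test` (sum to 1).
#' @param seed master seed.
#' @return an object of class `mwt_dataset`: list with `phantoms` (list) and
#'   `manifest` (tibble: `id`, `class`, `pathological`, `split`, `seed`,
#'   `n_tumors`, `tumor_area_cm2`).
#' @export
generate_dataset <- function(config = generator_config(), n_per_cell = 25,
                             split = c(train = 0.8, val = 0.1, test = 0.1),
                             seed = 1L) {
  n_per_cell <- as.integer(n_per_cell)
  if (n_per_cell < 1L) abort("`n_per_cell` must be >= 1.", class = "mwtomo_bad_config")
  if (abs(sum(split) - 1) > 1e-8) abort("`split` fractions must sum to 1.",
                                        class = "mwtomo_bad_config")
  cells <- expand.grid(class = c("A", "B", "C", "D"),
                       pathological = c(FALSE, TRUE),
                       stringsAsFactors = FALSE)
  counts <- stratified_split_counts(nrow(cells), n_per_cell, split)
  phantoms <- vector("list", nrow(cells) * n_per_cell)
  rows <- vector("list", length(phantoms))
  id <- 0L
  for (cell in seq_len(nrow(cells))) {
    membership <- rep(names(split), counts[cell, ])
    for (r in seq_len(n_per_cell)) {
      id <- id + 1L
      pseed <- derive_seed(seed, paste0("phantom/", cells$class[cell], "/",
                                        cells$pathological[cell]), r)
      ph <- generate_phantom(config, cells$class[cell], cells$pathological[cell],
                             seed = pseed)
      phantoms[[id]] <- ph
      rows[[id]] <- tibble::tibble(
        id = id, class = cells$class[cell], pathological = cells$pathological[cell],
        split = membership[r], seed = pseed, n_tumors = length(ph$tumors),
        tumor_area_cm2 = if (length(ph$tumors)) sum(vapply(ph$tumors, `[[`, 0, "area_cm2")) else 0)
    }
  }
  structure(list(phantoms = phantoms, manifest = dplyr::bind_rows(rows),
                 config = config, seed = seed),
            class = "mwt_dataset")
}

#' @export
print.mwt_dataset <- function(x, ...) {
  cat(sprintf("<mwt_dataset> %d profiles (%s)\n", length(x$phantoms),
              paste(sprintf("%s: %d", names(table(x$manifest$split)),
                            table(x$manifest$split)), collapse = ", ")))
  invisible(x)
}
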