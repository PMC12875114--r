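#' Split dual-color localizations by spectral ratio
#'
#' Each localization carries two spectral-detector counts; the ratio
#' `ch1 / (ch1 + ch2)` assigns it to the DNA-probe channel when strictly
#' above the threshold and to the antibody-label channel otherwise.
#' Records with `ch1 + ch2 = 0` carry no spectral information and are
#' dropped (their count is reported).
#'
#' @param table Localization table with `ch1` and `ch2` columns.
#' @param threshold Ratio threshold; default 0.415.
#' @return List of class `channel_split`: `dna` and `label` tibbles (each
#'   with a `ratio` column), `n_dropped`, `threshold`.
#' @export
split_channels <- function(table, threshold = 0.415) {
  if (!all(c("ch1", "ch2") %in% names(table))) {
    abort("configuration error: `ch1` and `ch2` columns are required")
  }
  if (any(is.na(table$ch1)) || any(is.na(table$ch2))) {
    abort("configuration error: `ch1`/`ch2` contain missing values")
  }
  tot <- table$ch1 + table$ch2
  usable <- tot > 0
  ratio <- rep(NA_real_, nrow(table))
  ratio[usable] <- table$ch1[usable] / tot[usable]
  out <- tibble::as_tibble(as.data.frame(table))
  out$ratio <- ratio
  dna <- out[usable & ratio > threshold, , drop = FALSE]
  label <- out[usable & ratio <= threshold, , drop = FALSE]
  n_dropped <- sum(!usable)
  if (n_dropped > 0) {
    message(sprintf("split_channels: dropped %d record(s) with zero spectral counts",
                    n_dropped))
  }
  structure(list(dna = dna, label = label, n_dropped = n_dropped,
                 threshold = threshold),
            class = "channel_split")
}

#' Cross-channel proximity of DNA and label localizations
#'
#' Exact nearest-neighbor distance from every DNA-channel localization to
#' the label channel, and the fraction of DNA localizations with a label
#' within the given radius. The default 50-nm radius accommodates the
#' physical size of a primary antibody relative to a nucleosome.
#'
#' @param dna,label Non-empty localization tables.
#' @param radius Co-localization radius in nm.
#' @return List of class `channel_proximity`: `per_dna` (tibble
#'   `uid, nn_dist_nm`), `fraction_within`, `radius_nm`.
#' @export
channel_proximity <- function(dna, label, radius = 50) {
  if (nrow(dna) == 0 || nrow(label) == 0) {
    return(structure(list(
      per_dna = tibble::tibble(uid = integer(), nn_dist_nm = numeric()),
      fraction_within = NA_real_, radius_nm = radius
    ), class = "channel_proximity"))
  }
  a <- as_xyz(dna)
  b <- as_xyz(label)
  uid <- if ("uid" %in% names(dna)) dna$uid else seq_len(nrow(a))
  nn <- numeric(nrow(a))
  chunk <- max(1L, floor(5e6 / nrow(b)))
  for (s in seq(1, nrow(a), by = chunk)) {
    e <- min(s + chunk - 1, nrow(a))
    block <- a[s:e, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rowSums(b^2), `+`) -
      2 * tcrossprod(block, b)
    nn[s:e] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  structure(list(
    per_dna = tibble::tibble(uid = uid, nn_dist_nm = nn),
    fraction_within = mean(nn <= radius), radius_nm = radius
  ), class = "channel_proximity")
}
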