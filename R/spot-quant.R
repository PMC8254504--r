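#' Find intensity maxima with prominence-based noise tolerance
#'
#' Detects single-molecule spots as local intensity maxima using the
#' flood-based semantics of ImageJ's "Find Maxima": candidate local maxima
#' are processed in order of decreasing intensity; from each candidate a
#' region grows over connected pixels with intensity above
#' `peak - noise_tolerance`; a candidate whose region reaches territory
#' already claimed by a higher maximum is absorbed into it (it does not
#' stand out by more than the tolerance) and is not counted. A plateau of
#' equal-valued pixels yields a single maximum at the plateau centroid
#' (rounded toward the top-left on exact halves). A plateau whose tolerance
#' region covers the entire image has no prominence at all and is not
#' counted, so a constant image yields no maxima.
#'
#' With `exclude_border`, maxima whose reported position lies on the
#' outermost pixel row or column are discarded.
#'
#' @param image Numeric or integer matrix (16-bit grayscale intensities).
#' @param noise_tolerance Minimum intensity drop separating a counted
#'   maximum from a higher neighbouring peak.
#' @param exclude_border Drop maxima on the 1-pixel outer frame?
#' @return A tibble of class `maxima_set` with columns `row`, `col`,
#'   `value`, and attributes `noise_tolerance` and `exclude_border`; the
#'   spot count is `nrow()` of the result.
#' @export
#' @examples
#' img <- matrix(0, 9, 9); img[5, 5] <- 10000
#' find_maxima(img, noise_tolerance = 6000)
find_maxima <- function(image, noise_tolerance = 6000,
                        exclude_border = TRUE) {
  if (!is.matrix(image) || length(image) == 0) {
    abort("`image` must be a non-empty matrix")
  }
  if (noise_tolerance < 0) abort("`noise_tolerance` must be >= 0")
  nr <- nrow(image); nc <- ncol(image)
  v <- as.numeric(image)
  npix <- nr * nc

  # local maxima: pixels >= all existing 8-neighbours
  shifted_ge <- function(dr, dc) {
    m <- matrix(TRUE, nr, nc)
    rs <- seq_len(nr); cs <- seq_len(nc)
    rsrc <- rs + dr; csrc <- cs + dc
    rok <- rsrc >= 1 & rsrc <= nr; cok <- csrc >= 1 & csrc <= nc
    m[rok, cok] <- image[rok, cok] >= image[rsrc[rok], csrc[cok]]
    m
  }
  is_max <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & shifted_ge(dr, dc)
  }
  cand <- which(is_max)
  cand <- cand[order(v[cand], decreasing = TRUE)]

  label <- integer(npix)
  next_id <- 0L
  peaks <- list()

  flood <- function(start, thresh, restrict_value = NULL) {
    # BFS over connected pixels with value > thresh (or == restrict_value);
    # returns visited indices and whether a previously labelled pixel
    # (another region) was touched
    visited <- integer(0)
    absorbed_into <- 0L
    frontier <- start
    local_mark <- logical(npix)
    local_mark[start] <- TRUE
    while (length(frontier)) {
      visited <- c(visited, frontier)
      r <- ((frontier - 1L) %% nr) + 1L
      cc <- ((frontier - 1L) %/% nr) + 1L
      nbrs <- integer(0)
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- cc + dc
        ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
        if (any(ok)) nbrs <- c(nbrs, (c2[ok] - 1L) * nr + r2[ok])
      }
      nbrs <- unique(nbrs[!local_mark[nbrs]])
      if (is.null(restrict_value)) {
        inreg <- v[nbrs] > thresh
      } else {
        inreg <- v[nbrs] == restrict_value
      }
      nbrs <- nbrs[inreg]
      lab <- label[nbrs]
      if (is.null(restrict_value) && any(lab > 0L)) {
        absorbed_into <- lab[lab > 0L][1]
        nbrs <- nbrs[lab == 0L]
      }
      local_mark[nbrs] <- TRUE
      frontier <- nbrs
    }
    list(visited = visited, absorbed_into = absorbed_into)
  }

  for (ci in cand) {
    if (label[ci] != 0L) next  # already claimed by a higher maximum
    peak_v <- v[ci]
    fl <- flood(ci, peak_v - noise_tolerance)
    if (fl$absorbed_into > 0L) {
      label[fl$visited] <- fl$absorbed_into
      next
    }
    next_id <- next_id + 1L
    label[fl$visited] <- next_id
    if (length(fl$visited) == npix) next  # no prominence anywhere: flat top
    plat <- flood(ci, NA, restrict_value = peak_v)$visited
    label[plat] <- next_id  # a plateau yields a single maximum
    pr <- ((plat - 1L) %% nr) + 1L
    pc <- ((plat - 1L) %/% nr) + 1L
    peaks[[length(peaks) + 1L]] <- c(
      row = as.integer(ceiling(mean(pr) - 0.5)),
      col = as.integer(ceiling(mean(pc) - 0.5)),
      value = peak_v)
  }

  out <- if (length(peaks)) {
    as_tibble(do.call(rbind, peaks))
  } else {
    tibble(row = integer(), col = integer(), value = numeric())
  }
  if (exclude_border && nrow(out)) {
    out <- out[out$row > 1 & out$row < nr & out$col > 1 & out$col < nc, ]
  }
  attr(out, "noise_tolerance") <- noise_tolerance
  attr(out, "exclude_border") <- exclude_border
  class(out) <- c("maxima_set", class(out))
  out
}

#' Volume-normalized oligo/protein fraction
#'
#' The fraction of catalytically engaged molecules is estimated per genotype
#' as the summed oligo-channel maxima divided by the summed total-protein
#' maxima, each first normalized by the lysate volume it was derived from:
#' `fraction = (sum(oligo)/oligo_volume) / (sum(protein)/protein_volume)`.
#'
#' @param oligo_maxima Integer vector of per-image oligo-channel spot counts.
#' @param protein_maxima Integer vector of per-image protein-channel counts.
#' @param oligo_volume,protein_volume Lysate volumes behind each channel
#'   (same arbitrary unit).
#' @return The volume-normalized fraction (0 when no oligo maxima); `NA`
#'   with a warning when no protein maxima were counted.
#' @export
#' @examples
#' oligo_fraction(c(100, 100), c(200, 200))       # 0.5
#' oligo_fraction(200, 400, oligo_volume = 2)     # 0.25
oligo_fraction <- function(oligo_maxima, protein_maxima,
                           oligo_volume = 1, protein_volume = 1) {
  if (oligo_volume <= 0 || protein_volume <= 0) {
    abort("lysate volumes must be > 0")
  }
  prot <- sum(protein_maxima)
  if (prot == 0) {
    warn("no protein maxima: oligo fraction undefined")
    return(NA_real_)
  }
  (sum(oligo_maxima) / oligo_volume) / (prot / protein_volume)
}

#' Per-genotype fractions from a batch manifest
#'
#' @param manifest Tibble with columns `genotype`, `channel` (`"oligo"` or
#'   `"protein"`), `n_maxima` (per-image spot count) and `lysate_volume`
#'   (constant within genotype x channel).
#' @return Tibble `genotype`, `fraction`.
#' @export
genotype_fractions <- function(manifest) {
  stopifnot(all(c("genotype", "channel", "n_maxima", "lysate_volume")
                %in% names(manifest)))
  manifest %>%
    group_by(genotype) %>%
    summarise(fraction = {
      ol <- channel == "oligo"
      oligo_fraction(n_maxima[ol], n_maxima[!ol],
                     oligo_volume = unique(lysate_volume[ol]),
                     protein_volume = unique(lysate_volume[!ol]))
    }, .groups = "drop")
}

#' Fold change of oligo fractions between genotypes
#'
#' Ratio of a mutant's volume-normalized oligo fraction to the wild type's.
#' When per-replicate fractions are supplied (equal-length vectors, paired
#' by replicate), the per-replicate ratios and their mean and standard
#' deviation are also returned.
#'
#' @param mutant,wildtype Oligo fractions (scalars, or equal-length
#'   per-replicate vectors).
#' @return A list of class `fold_change`: `fold_change` (ratio of means),
#'   and for replicated input `ratios`, `mean`, `sd`.
#' @export
#' @examples
#' fold_change(0.4, 0.2)$fold_change  # 2
fold_change <- function(mutant, wildtype) {
  if (length(mutant) != length(wildtype)) {
    abort("`mutant` and `wildtype` must have equal length")
  }
  if (any(wildtype <= 0)) abort("wild-type fraction must be > 0")
  out <- list(fold_change = mean(mutant) / mean(wildtype))
  if (length(mutant) > 1) {
    out$ratios <- mutant / wildtype
    out$mean <- mean(out$ratios)
    out$sd <- sd(out$ratios)
  }
  structure(out, class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat("fold change:", format(x$fold_change, digits = 4))
  if (!is.null(x$ratios)) {
    cat("  (", length(x$ratios), " replicates: mean ",
        format(x$mean, digits = 4), " +/- ", format(x$sd, digits = 4),
        ")", sep = "")
  }
  cat("\n")
  invisible(x)
}
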