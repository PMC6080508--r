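# Chromosome-integrity checks from per-base depth tracks: mean depth in
# tiling windows (10 kb by default) and the window-wise depth ratio between
# an allopolyploid sample and the corresponding parent. Windows are 0-based
# half-open internally; depth tracks are 1-based on disk (samtools-depth
# dialect) and converted at the boundary.

check_depth_track <- function(depth) {
  if (!all(c("chrom", "pos", "depth") %in% names(depth))) {
    abort("depth track needs columns chrom, pos, depth.")
  }
  if (any(depth$pos < 1) || any(depth$depth < 0)) {
    abort("positions must be >= 1 and depths >= 0.")
  }
  invisible(depth)
}

#' Mean depth in tiling windows
#'
#' Tiles each chromosome with half-open windows `[0, w), [w, 2w), ...` and
#' averages per-base depth within each window. Bases absent from the track
#' count as depth 0; the final partial window is averaged over its actual
#' width. Chromosome lengths default to the highest observed position; a
#' lengths vector extends (or defines, for chromosomes with no rows) the
#' tiling.
#'
#' @param depth Depth track tibble: `chrom`, `pos` (1-based), `depth`.
#' @param window_size Window width in bp, > 0 (default 10000).
#' @param chrom_lengths Optional named vector of chromosome lengths; when
#'   supplied, windows are emitted for every chromosome in it, including
#'   chromosomes absent from the track.
#' @return Tibble: `chrom`, `start` (0-based), `end`, `mean_depth`.
#' @export
window_means <- function(depth, window_size = 10000, chrom_lengths = NULL) {
  check_depth_track(depth)
  if (!is.numeric(window_size) || window_size <= 0) {
    abort("`window_size` must be > 0.")
  }
  chroms <- if (is.null(chrom_lengths)) {
    unique(depth$chrom)
  } else {
    names(chrom_lengths)
  }
  purrr::map_dfr(chroms, function(ch) {
    d <- depth[depth$chrom == ch, ]
    if (nrow(d) > 0 && is.unsorted(d$pos)) {
      abort(paste0("positions are not sorted on chromosome ", ch, "."))
    }
    len <- if (!is.null(chrom_lengths)) {
      chrom_lengths[[ch]]
    } else {
      max(d$pos)
    }
    if (nrow(d) > 0 && max(d$pos) > len) {
      abort(paste0("position beyond declared length on chromosome ", ch, "."))
    }
    n_win <- ceiling(len / window_size)
    start <- (seq_len(n_win) - 1) * window_size
    end <- pmin(start + window_size, len)
    sums <- numeric(n_win)
    if (nrow(d) > 0) {
      idx <- (d$pos - 1) %/% window_size + 1
      agg <- rowsum(d$depth, idx)
      sums[as.integer(rownames(agg))] <- agg[, 1]
    }
    tibble(chrom = ch, start = start, end = end,
           mean_depth = sums / (end - start))
  })
}

#' Window-wise depth ratio between two tracks
#'
#' Computes per-window mean depths for both tracks over a common tiling and
#' reports their ratio, the chromosome-integrity statistic: for an intact
#' chromosome the allopolyploid-to-parent ratio fluctuates around a
#' constant, while a lost chromosome or segment drops toward zero. Windows
#' are flagged `missing_den` when the denominator mean is 0, `missing_num`
#' when the numerator mean is 0, `low` when the ratio falls below
#' `low_cutoff`, and `ok` otherwise. A chromosome present in only one track
#' is reported window-by-window as entirely missing, not as an error.
#'
#' @param num,den Depth tracks (numerator and denominator), tibbles with
#'   `chrom`, `pos`, `depth`.
#' @param window_size Window width in bp (default 10000).
#' @param scale_normalize When `TRUE`, each track's window means are first
#'   divided by that track's genome-wide mean depth, removing library-size
#'   differences; off by default (a plain ratio).
#' @param low_cutoff Ratio below which a window is flagged `low`
#'   (default 0.25).
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return Tibble: `chrom`, `start`, `end`, `mean_depth_num`,
#'   `mean_depth_den`, `ratio` (`NA` where the denominator is 0), `status`.
#' @export
depth_ratio <- function(num, den, window_size = 10000,
                        scale_normalize = FALSE, low_cutoff = 0.25,
                        chrom_lengths = NULL) {
  check_depth_track(num)
  check_depth_track(den)
  if (is.null(chrom_lengths)) {
    len_of <- function(d) {
      vapply(split(d$pos, d$chrom), max, numeric(1))
    }
    ln <- len_of(num)
    ld <- len_of(den)
    chroms <- union(names(ln), names(ld))
    chrom_lengths <- setNames(
      pmax(ln[chroms], ld[chroms], na.rm = TRUE), chroms
    )
  }
  wm_num <- window_means(num, window_size, chrom_lengths)
  wm_den <- window_means(den, window_size, chrom_lengths)
  if (scale_normalize) {
    genome_mean <- function(w) {
      sum(w$mean_depth * (w$end - w$start)) / sum(w$end - w$start)
    }
    wm_num$mean_depth <- wm_num$mean_depth / genome_mean(wm_num)
    wm_den$mean_depth <- wm_den$mean_depth / genome_mean(wm_den)
  }
  out <- tibble(
    chrom = wm_num$chrom, start = wm_num$start, end = wm_num$end,
    mean_depth_num = wm_num$mean_depth,
    mean_depth_den = wm_den$mean_depth
  )
  out$ratio <- ifelse(out$mean_depth_den > 0,
                      out$mean_depth_num / out$mean_depth_den, NA_real_)
  out$status <- dplyr::case_when(
    out$mean_depth_num == 0 & out$mean_depth_den > 0 ~ "missing_num",
    out$mean_depth_den == 0 ~ "missing_den",
    out$ratio < low_cutoff ~ "low",
    TRUE ~ "ok"
  )
  out
}

#' Per-chromosome integrity verdict
#'
#' @param ratios Result of [depth_ratio()].
#' @param min_ok Minimum fraction of `ok` windows for a chromosome to be
#'   called intact (default 0.9).
#' @return Tibble: `chrom`, `n_windows`, `frac_ok`, `intact`.
#' @export
coverage_verdict <- function(ratios, min_ok = 0.9) {
  if (nrow(ratios) == 0) abort("`ratios` is empty.")
  ratios |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(
      n_windows = dplyr::n(),
      frac_ok = mean(.data$status == "ok"),
      .groups = "drop"
    ) |>
    dplyr::mutate(intact = .data$frac_ok >= min_ok)
}
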