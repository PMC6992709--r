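#' Windowed coverage profile
#'
#' Container for per-window read counts of one sample.  Windows are
#' 0-based half-open, must be sorted, non-overlapping, and tile each
#' chromosome.
#'
#' @param sample_id sample identifier.
#' @param windows data.frame with columns `chrom`, `start`, `end`,
#'   `count`.
#' @return an object of class `coverage_profile` with fields `sample_id`,
#'   `windows` and `total` (total mapped reads).
#' @export
coverage_profile <- function(sample_id, windows) {
  assert_that(all(c("chrom", "start", "end", "count") %in% names(windows)),
              "windows needs columns chrom, start, end, count")
  assert_that(all(windows$count >= 0), "window counts must be >= 0")
  assert_that(all(windows$end > windows$start), "windows must be non-empty")
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, ]
    assert_that(!is.unsorted(w$start, strictly = TRUE) &&
                  all(w$start[-1] == w$end[-nrow(w)]),
                "windows must be sorted and tile chromosome ", ch)
  }
  structure(list(sample_id = sample_id, windows = windows,
                 total = sum(windows$count)),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("coverage_profile:", x$sample_id, "-", nrow(x$windows), "windows,",
      x$total, "reads\n")
  invisible(x)
}

#' Normalize sample coverage to wild type
#'
#' Computes, per window, the ratio of library-size normalized counts,
#' `ratio(w) = (c_s(w)/T_s) / (c_wt(w)/T_wt)`, where `T` is the total
#' mapped read count of the sample.  Windows with a zero wild-type count
#' are masked (`NA`), as are windows overlapping regions flagged as
#' masked in the annotation (e.g. rDNA-like repeats).
#'
#' @param sample,wt [coverage_profile()] objects on identical window
#'   grids; the wild type must have a nonzero count in at least 99% of
#'   windows.
#' @param masked optional data.frame (`chrom`, `start`, `end`) of regions
#'   to exclude from segmentation.
#' @return a `ratio_track`: the window grid plus `ratio`, `log2ratio`
#'   and a logical `masked` column.
#' @export
normalize_coverage <- function(sample, wt, masked = NULL) {
  assert_that(inherits(sample, "coverage_profile") &&
                inherits(wt, "coverage_profile"),
              "inputs must be coverage_profile objects")
  ws <- sample$windows; ww <- wt$windows
  assert_that(nrow(ws) == nrow(ww) &&
                all(ws$chrom == ww$chrom) && all(ws$start == ww$start) &&
                all(ws$end == ww$end),
              "window grids differ between sample and wild type")
  assert_that(sample$total > 0, "all-zero sample coverage")
  assert_that(mean(ww$count > 0) >= 0.99,
              "wild type has zero coverage in more than 1% of windows")
  ratio <- (ws$count / sample$total) / (ww$count / wt$total)
  mask <- ww$count == 0
  if (!is.null(masked) && nrow(masked)) {
    q <- GenomicRanges::GRanges(ws$chrom,
                                IRanges::IRanges(ws$start + 1L, ws$end))
    m <- GenomicRanges::GRanges(masked$chrom,
                                IRanges::IRanges(masked$start + 1L, masked$end))
    mask <- mask | IRanges::overlapsAny(q, m)
  }
  ratio[mask] <- NA_real_
  out <- data.frame(chrom = ws$chrom, start = ws$start, end = ws$end,
                    ratio = ratio, log2ratio = log2(ratio), masked = mask)
  structure(list(sample_id = sample$sample_id, track = out),
            class = "ratio_track")
}

#' Segment a coverage ratio track into copy-number segments
#'
#' Per chromosome, recursive binary segmentation of the log2 ratio: the
#' candidate split maximizes the reduction in within-segment sum of
#' squares and is accepted iff the reduction exceeds
#' `penalty * sigma2`, where `sigma2` is a robust chromosome-wide noise
#' variance estimated from successive differences
#' (`mad(diff(x))^2 / 2`).  Accepted splits are recursed into; adjacent
#' segments with equal called copy number (mean ratio >= `cn_threshold`
#' maps to 2, else 1) are merged.  Masked windows are excluded from all
#' statistics.  Deterministic.
#'
#' @param track a [normalize_coverage()] ratio track.
#' @param penalty positive; BIC-style acceptance penalty (default 10).
#' @param cn_threshold ratio above which a segment is called copy
#'   number 2 (default 1.5, the midpoint between 1 and 2 copies).
#' @param merge merge adjacent segments with equal called copy number
#'   (default TRUE; FALSE exposes the raw accepted breakpoints, which
#'   are nested across decreasing penalties).
#' @return data.frame of segments: `chrom`, `start`, `end` (0-based
#'   half-open, covering each chromosome fully), `n_windows`,
#'   `mean_ratio`, `cn`.
#' @export
segment_ratio <- function(track, penalty = 10, cn_threshold = 1.5,
                          merge = TRUE) {
  assert_that(inherits(track, "ratio_track"), "track must be a ratio_track")
  assert_that(is.numeric(penalty) && penalty > 0, "penalty must be positive")
  tr <- track$track
  out <- lapply(unique(tr$chrom), function(ch) {
    w <- tr[tr$chrom == ch, ]
    assert_that(nrow(w) >= 2, "need >= 2 windows on chromosome ", ch)
    x <- w$log2ratio
    ok <- is.finite(x)
    sigma2 <- robust_sigma2(x[ok])
    cuts <- sort(binseg(x, ok, 1L, length(x), penalty * sigma2))
    bounds <- c(0L, cuts, length(x))
    seg <- do.call(rbind, lapply(seq_len(length(bounds) - 1), function(i) {
      idx <- (bounds[i] + 1L):bounds[i + 1L]
      data.frame(chrom = ch, start = w$start[idx[1]], end = w$end[idx[length(idx)]],
                 n_windows = length(idx),
                 mean_ratio = mean(w$ratio[idx], na.rm = TRUE))
    }))
    seg$cn <- ifelse(!is.nan(seg$mean_ratio) & seg$mean_ratio >= cn_threshold,
                     2L, 1L)
    if (merge) merge_segments(seg) else seg
  })
  do.call(rbind, out)
}

robust_sigma2 <- function(x) {
  if (length(x) < 3) return(0)
  d <- diff(x)
  (mad(d) ^ 2) / 2
}

# Recursive binary segmentation on x[lo..hi]; returns accepted cut
# positions (absolute indices, cut after that index). `ok` marks windows
# that enter the statistics.
binseg <- function(x, ok, lo, hi, threshold) {
  idx <- lo:hi
  use <- idx[ok[idx]]
  n <- length(use)
  if (n < 2) return(integer())
  y <- x[use]
  # candidate cuts between consecutive usable windows
  cs <- cumsum(y); css <- cumsum(y^2)
  tot_ss <- css[n] - cs[n]^2 / n
  k <- seq_len(n - 1)
  left_ss <- css[k] - cs[k]^2 / k
  right_ss <- (css[n] - css[k]) - (cs[n] - cs[k])^2 / (n - k)
  gain <- tot_ss - (left_ss + right_ss)
  best <- which.max(gain)
  # epsilon guard: never split on pure floating-point residue
  if (!is.finite(gain[best]) || gain[best] <= threshold + 1e-9)
    return(integer())
  cut <- use[best]                      # cut after this window
  c(binseg(x, ok, lo, cut, threshold),
    cut,
    binseg(x, ok, cut + 1L, hi, threshold))
}

merge_segments <- function(seg) {
  if (nrow(seg) <= 1) return(seg)
  keep <- list(seg[1, ])
  for (i in 2:nrow(seg)) {
    last <- keep[[length(keep)]]
    if (seg$cn[i] == last$cn) {
      tot <- last$n_windows + seg$n_windows[i]
      last$mean_ratio <- (last$mean_ratio * last$n_windows +
                            seg$mean_ratio[i] * seg$n_windows[i]) / tot
      last$end <- seg$end[i]
      last$n_windows <- tot
      keep[[length(keep)]] <- last
    } else keep[[length(keep) + 1]] <- seg[i, ]
  }
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  out
}

#' Call the karyotype and changes relative to the ancestor
#'
#' A chromosome is `disomic` when at least `disomic_fraction` of its
#' length is at copy number 2, `euploid` when at most
#' `1 - disomic_fraction` of it is (symmetric tolerance), and `partial`
#' otherwise.  Change events against the ancestor call:
#' `whole_loss` (ancestor disomic, evolved euploid), `partial_loss`
#' (ancestor disomic, evolved partial), `segmental_amplification`
#' (ancestor euploid, evolved partial or disomic), else `retained`.
#'
#' @param segments segment table from [segment_ratio()].
#' @param ancestor either an ancestor `karyotype_call` or the name of the
#'   chromosome disomic in the ancestor (`NA` for a euploid ancestor).
#' @param disomic_fraction length fraction at copy number 2 required to
#'   call a whole chromosome disomic (default 0.95).
#' @return a `karyotype_call`: per-chromosome `status` table, the input
#'   segments, and a `changes` table listing non-`retained` events with
#'   the copy-number-change breakpoint coordinates.
#' @export
call_karyotype <- function(segments, ancestor = NA, disomic_fraction = 0.95) {
  status <- do.call(rbind, lapply(unique(segments$chrom), function(ch) {
    s <- segments[segments$chrom == ch, ]
    len <- sum(s$end - s$start)
    f2 <- sum((s$end - s$start)[s$cn == 2L]) / len
    data.frame(chrom = ch, cn2_fraction = f2,
               status = if (f2 >= disomic_fraction) "disomic"
                        else if (f2 <= 1 - disomic_fraction) "euploid"
                        else "partial")
  }))
  anc_status <- if (inherits(ancestor, "karyotype_call")) {
    setNames(ancestor$status$status, ancestor$status$chrom)
  } else {
    setNames(ifelse(status$chrom %in% ancestor, "disomic", "euploid"),
             status$chrom)
  }
  changes <- do.call(rbind, lapply(seq_len(nrow(status)), function(i) {
    ch <- status$chrom[i]
    a <- anc_status[[ch]] %||% "euploid"
    e <- status$status[i]
    ev <- if (a == "disomic" && e == "euploid") "whole_loss"
      else if (a == "disomic" && e == "partial") "partial_loss"
      else if (a == "euploid" && e %in% c("partial", "disomic"))
        "segmental_amplification"
      else "retained"
    if (ev == "retained") return(NULL)
    s <- segments[segments$chrom == ch, ]
    bp <- s$start[-1][diff(s$cn) != 0]
    data.frame(chrom = ch, event = ev,
               breakpoints = paste(bp, collapse = ";"))
  }))
  structure(list(status = status, segments = segments,
                 changes = changes %||%
                   data.frame(chrom = character(), event = character(),
                              breakpoints = character()),
                 disomic_fraction = disomic_fraction),
            class = "karyotype_call")
}

#' @export
print.karyotype_call <- function(x, ...) {
  cat("karyotype_call:\n")
  print(x$status, row.names = FALSE)
  if (nrow(x$changes)) {
    cat("changes vs ancestor:\n")
    print(x$changes, row.names = FALSE)
  }
  invisible(x)
}
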