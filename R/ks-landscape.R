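# Ks-distribution construction, modal-peak detection and per-class
# comparison of tandem-duplicate divergence.

#' Filter Ks values for histogramming
#'
#' Drops undefined (NA), non-finite and saturated values above `ksCap`.
#' NG86 estimates saturate beyond Ks ~ 3, so the default cap of 3.5 keeps
#' the analysable range while admitting the ~2.5 peak region.
#'
#' @param ks numeric vector of Ks estimates (or a [computeKaKs()] frame,
#'   whose `ks` column is used).
#' @param ksCap upper retention bound (default 3.5; `Inf` keeps all finite
#'   values).
#' @return numeric vector of retained values.
#' @export
filterKs <- function(ks, ksCap = 3.5) {
  if (is.data.frame(ks)) ks <- ks$ks
  ks <- as.numeric(ks)
  ks[is.finite(ks) & ks >= 0 & ks <= ksCap]
}

#' Histogram a Ks sample and call modal peaks
#'
#' Values are binned into fixed-width intervals `[k*w, (k+1)*w)` from zero.
#' The primary peak is the modal bin, reported as its interval. Secondary
#' peaks are local maxima whose count reaches `secondaryFrac` of the modal
#' count and which lie at least `minSeparation` bins away from any
#' previously accepted peak. With fewer than `minValues` retained values
#' the histogram is still returned but no peak is called.
#'
#' @param values numeric Ks values (already filtered; see [filterKs()]).
#' @param binWidth bin width (default 0.1, matching peak reporting such as
#'   "0.6 to 0.7").
#' @param minValues minimum sample size for peak calling (default 20).
#' @param secondaryFrac fraction of the modal count a secondary peak must
#'   reach (default 0.25).
#' @param minSeparation minimum separation between peaks, in bins
#'   (default 3).
#' @param label distribution label.
#' @return a [KsDistribution-class] object.
#' @export
histogramPeaks <- function(values, binWidth = 0.1, minValues = 20,
                           secondaryFrac = 0.25, minSeparation = 3,
                           label = "whole") {
  values <- as.numeric(values)
  stopifnot(binWidth > 0, all(is.finite(values)), all(values >= 0))
  if (!length(values)) {
    return(new("KsDistribution", label = label, values = numeric(),
               binWidth = binWidth, counts = numeric(),
               peaks = emptyPeakFrame()))
  }
  bin <- floor(values / binWidth)            # bin k covers [k*w, (k+1)*w)
  nBins <- max(bin) + 1L
  counts <- tabulate(bin + 1L, nbins = nBins)
  names(counts) <- sprintf("[%g,%g)", (seq_len(nBins) - 1L) * binWidth,
                           seq_len(nBins) * binWidth)
  peaks <- emptyPeakFrame()
  if (length(values) >= minValues) {
    modal <- which.max(counts)               # ties -> lowest bin
    localMax <- vapply(seq_len(nBins), function(i) {
      left <- if (i > 1L) counts[i - 1L] else -Inf
      right <- if (i < nBins) counts[i + 1L] else -Inf
      counts[i] >= left && counts[i] >= right
    }, TRUE)
    cand <- which(localMax & counts >= secondaryFrac * counts[modal])
    cand <- cand[order(-counts[cand], cand)]
    accepted <- integer()
    for (i in cand) {
      if (!length(accepted) || all(abs(i - accepted) >= minSeparation)) {
        accepted <- c(accepted, i)
      }
    }
    accepted <- sort(accepted)
    peaks <- data.frame(
      lo = round((accepted - 1L) * binWidth, 10),
      hi = round(accepted * binWidth, 10),
      midpoint = round((accepted - 0.5) * binWidth, 10),
      count = as.numeric(counts[accepted]),
      primary = accepted == modal
    )
    peaks <- peaks[order(-peaks$primary, -peaks$count, peaks$lo), ,
                   drop = FALSE]
    rownames(peaks) <- NULL
  }
  new("KsDistribution", label = label, values = values,
      binWidth = binWidth, counts = as.numeric(counts), peaks = peaks)
}

emptyPeakFrame <- function() {
  data.frame(lo = numeric(), hi = numeric(), midpoint = numeric(),
             count = numeric(), primary = logical())
}

#' Compare Ks distributions across gene classes
#'
#' Each Ka/Ks pair is assigned to a tissue-response class when both members
#' carry the same class label; pairs whose members disagree are labelled
#' "mixed" and excluded from the class distributions while remaining in the
#' whole-set distribution.
#'
#' @param kaks [computeKaKs()] frame (`gene1`, `gene2`, `ks`).
#' @param geneClasses data.frame with `gene_id`, `label`.
#' @param classes class labels to compare (default the three responsive
#'   classes).
#' @param ksCap,binWidth,... forwarded to [filterKs()] /
#'   [histogramPeaks()].
#' @return list with `distributions` (named list of
#'   [KsDistribution-class]: "whole" plus one per class) and `peakTable`
#'   (data.frame `class`, `lo`, `hi`, `midpoint`, `count`, `primary`).
#' @export
classKsCompare <- function(kaks, geneClasses,
                           classes = c("leaf_specific", "root_specific",
                                       "co_expressed"),
                           ksCap = 3.5, binWidth = 0.1, ...) {
  stopifnot(all(c("gene1", "gene2", "ks") %in% names(kaks)),
            all(c("gene_id", "label") %in% names(geneClasses)))
  lab <- stats::setNames(geneClasses$label, geneClasses$gene_id)
  l1 <- unname(lab[kaks$gene1])
  l2 <- unname(lab[kaks$gene2])
  pairClass <- ifelse(!is.na(l1) & !is.na(l2) & l1 == l2, l1, "mixed")
  pairClass[is.na(l1) & is.na(l2)] <- "unclassified"

  dists <- list(whole = histogramPeaks(filterKs(kaks$ks, ksCap),
                                       binWidth = binWidth,
                                       label = "whole", ...))
  for (cl in classes) {
    v <- filterKs(kaks$ks[pairClass == cl], ksCap)
    dists[[cl]] <- histogramPeaks(v, binWidth = binWidth, label = cl, ...)
  }
  peakTable <- do.call(rbind, lapply(dists, function(d) {
    p <- ksPeaks(d)
    if (!nrow(p)) return(NULL)
    cbind(data.frame(class = d@label), p)
  }))
  if (is.null(peakTable)) {
    peakTable <- cbind(data.frame(class = character()), emptyPeakFrame())
  }
  rownames(peakTable) <- NULL
  list(distributions = dists, peakTable = peakTable,
       pairClass = data.frame(gene1 = kaks$gene1, gene2 = kaks$gene2,
                              class = pairClass))
}
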