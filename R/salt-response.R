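# Salt-stress expression analysis: FPKM, a documented stand-in DE test,
# up-regulation calling, per-tissue event counting and the time-course
# tissue-specificity classifier.

#' FPKM from a count matrix
#'
#' `FPKM[g,s] = counts[g,s] * 1e9 / (librarySize[s] * length[g])`
#' (fragments per kilobase of transcript per million mapped fragments).
#'
#' @param counts gene x sample integer matrix.
#' @param lengths per-gene transcript lengths in bp (> 0), recycled by row.
#' @param librarySizes per-sample mapped-fragment totals; defaults to
#'   column sums of `counts`.
#' @return numeric matrix of FPKM values with the dimnames of `counts`.
#' @export
fpkm <- function(counts, lengths, librarySizes = colSums(counts)) {
  counts <- as.matrix(counts)
  stopifnot(length(lengths) == nrow(counts),
            length(librarySizes) == ncol(counts))
  if (any(lengths <= 0)) stop("gene lengths must be > 0", call. = FALSE)
  if (any(librarySizes <= 0)) {
    stop("library sizes must be > 0", call. = FALSE)
  }
  sweep(sweep(counts, 2, librarySizes, "/"), 1, lengths, "/") * 1e9
}

#' Simple two-group differential-expression test
#'
#' A transparent stand-in for a full negative-binomial DE model: counts are
#' library-size normalised (per million), the log2 fold change is
#' `log2((mean_treatment + 0.5) / (mean_control + 0.5))` of normalised
#' means, and the p-value comes from a pooled-variance two-sample t-test on
#' `log2(normalised + 0.5)` replicate values. p-values are BH-adjusted
#' across genes within each contrast.
#'
#' @param counts gene x sample matrix with column names matching
#'   `design$sample`.
#' @param design data.frame with columns `sample`, `tissue`, `timepoint`,
#'   `condition` (exactly two levels: `"control"` and the treatment) and
#'   `replicate`; each tissue x timepoint x condition cell needs >= 2
#'   replicates.
#' @return data.frame of DE records: `gene_id`, `tissue`, `timepoint`,
#'   `log2fc`, `pvalue`, `fdr`.
#' @export
simpleDE <- function(counts, design) {
  counts <- as.matrix(counts)
  need <- c("sample", "tissue", "timepoint", "condition")
  stopifnot(all(need %in% names(design)))
  if (!all(design$sample %in% colnames(counts))) {
    stop("design samples missing from count matrix", call. = FALSE)
  }
  conds <- unique(design$condition)
  if (length(conds) != 2L || !"control" %in% conds) {
    stop("design must have exactly two conditions including 'control'",
         call. = FALSE)
  }
  treat <- setdiff(conds, "control")
  norm <- sweep(counts, 2, colSums(counts), "/") * 1e6
  lnorm <- log2(norm + 0.5)
  out <- list()
  for (ti in unique(design$tissue)) {
    for (tp in unique(design$timepoint[design$tissue == ti])) {
      sel <- design$tissue == ti & design$timepoint == tp
      sT <- design$sample[sel & design$condition == treat]
      sC <- design$sample[sel & design$condition == "control"]
      if (length(sT) < 2L || length(sC) < 2L) {
        stop("need >= 2 replicates per condition for ", ti, " ", tp,
             call. = FALSE)
      }
      mT <- rowMeans(norm[, sT, drop = FALSE])
      mC <- rowMeans(norm[, sC, drop = FALSE])
      log2fc <- log2((mT + 0.5) / (mC + 0.5))
      xT <- lnorm[, sT, drop = FALSE]
      xC <- lnorm[, sC, drop = FALSE]
      n1 <- ncol(xT); n2 <- ncol(xC)
      v1 <- apply(xT, 1, stats::var)
      v2 <- apply(xC, 1, stats::var)
      sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
      diff <- rowMeans(xT) - rowMeans(xC)
      tstat <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf))
      p <- 2 * stats::pt(-abs(tstat), df = n1 + n2 - 2)
      p[!is.finite(tstat)] <- 0
      p[tstat == 0 & se == 0] <- 1
      out[[paste(ti, tp)]] <- data.frame(
        gene_id = rownames(counts), tissue = ti, timepoint = tp,
        log2fc = log2fc, pvalue = p, fdr = bhAdjust(p),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call up-regulation on DE records
#'
#' A contrast is an up-regulation event iff `fdr <= fdrMax` and
#' `log2fc >= lfcMin` (one-sided: down-regulation never counts as an
#' event).
#'
#' @param de data.frame with `gene_id`, `tissue`, `timepoint`, `log2fc`,
#'   `fdr`.
#' @param fdrMax FDR threshold (default 0.05).
#' @param lfcMin minimum log2 fold change (default 1).
#' @return `de` with a logical `up` column.
#' @export
callUp <- function(de, fdrMax = 0.05, lfcMin = 1) {
  stopifnot(all(c("gene_id", "tissue", "timepoint", "log2fc", "fdr")
                %in% names(de)))
  de$up <- de$fdr <= fdrMax & de$log2fc >= lfcMin
  de
}

#' Count up-regulation events per gene and tissue
#'
#' @param calls output of [callUp()].
#' @return data.frame `gene_id`, one integer column per tissue, covering
#'   every gene in `calls`.
#' @export
countUpEvents <- function(calls) {
  stopifnot("up" %in% names(calls))
  key <- paste(calls$gene_id, calls$tissue, calls$timepoint)
  if (anyDuplicated(key)) {
    stop("duplicate (gene, tissue, timepoint) record: ",
         key[duplicated(key)][1], call. = FALSE)
  }
  genes <- sort(unique(calls$gene_id))
  tissues <- sort(unique(calls$tissue))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (ti in tissues) {
    sub <- calls[calls$tissue == ti & calls$up, , drop = FALSE]
    tab <- table(factor(sub$gene_id, levels = genes))
    out[[ti]] <- as.integer(tab)
  }
  out
}

#' Tissue-specificity classification of up-regulation patterns
#'
#' A gene up-regulated in at least `specMin` contrasts of one tissue and at
#' most `otherMax` of the other is tissue-specific; otherwise, a gene with
#' at least `coMin` events in total across both tissues is co-expressed;
#' otherwise it is unclassified. Specificity is checked before
#' co-expression (the rules cannot both fire in a 5-timepoint design, but
#' the guard matters for larger ones).
#'
#' @param upCounts data.frame from [countUpEvents()] with exactly two
#'   tissue columns, or `gene_id` plus the columns named in `tissues`.
#' @param tissues the two tissue column names (default `c("leaf",
#'   "root")`).
#' @param specMin minimum events in the specific tissue (default 4).
#' @param otherMax maximum events in the other tissue (default 1).
#' @param coMin minimum total events for co-expression (default 7).
#' @return data.frame `gene_id`, per-tissue counts, `label` in
#'   `{<tissue>_specific, co_expressed, unclassified}`.
#' @export
classifyTissue <- function(upCounts, tissues = c("leaf", "root"),
                           specMin = 4, otherMax = 1, coMin = 7) {
  stopifnot(length(tissues) == 2L,
            all(c("gene_id", tissues) %in% names(upCounts)))
  a <- upCounts[[tissues[1]]]
  b <- upCounts[[tissues[2]]]
  stopifnot(all(a >= 0), all(b >= 0))
  label <- rep("unclassified", nrow(upCounts))
  label[a + b >= coMin] <- "co_expressed"
  label[a >= specMin & b <= otherMax] <- paste0(tissues[1], "_specific")
  label[b >= specMin & a <= otherMax] <- paste0(tissues[2], "_specific")
  out <- upCounts[, c("gene_id", tissues)]
  out$label <- label
  out
}

#' Summarise tissue classes over the TDG set
#'
#' @param classes data.frame from [classifyTissue()].
#' @param tdg character vector of TDG ids; classes are counted within this
#'   set (default: all genes in `classes`).
#' @param tissues the two tissue labels used in class names.
#' @return list with `counts` (named vector over the four labels) and
#'   `totalResponsive` (sum of the three responsive classes).
#' @export
summarizeClasses <- function(classes, tdg = NULL,
                             tissues = c("leaf", "root")) {
  stopifnot(all(c("gene_id", "label") %in% names(classes)))
  if (!is.null(tdg)) {
    classes <- classes[classes$gene_id %in% tdg, , drop = FALSE]
  }
  labels <- c(paste0(tissues, "_specific"), "co_expressed", "unclassified")
  counts <- table(factor(classes$label, levels = labels))
  counts <- stats::setNames(as.integer(counts), labels)
  list(counts = counts,
       totalResponsive = sum(counts[setdiff(labels, "unclassified")]))
}
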