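# Plain-text interchange: GFF3, FASTA, outfmt-6 TSV, manifest JSON and
# generic TSV writers, so every pipeline stage can be driven from (or
# replaced by) external tools' files.

#' Write a gene annotation as GFF3
#'
#' @param annotation `GRanges` with `gene_id` metadata.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGeneAnnotation <- function(annotation, path) {
  stopifnot(is(annotation, "GRanges"))
  gr <- annotation
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = "gene", ID = gr$gene_id
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a homology table as 12-column outfmt-6 TSV (no header)
#'
#' @param hits data.frame from [generateHomologyTable()] or equivalent.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeHomologyTable <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a data.frame as headered TSV
#'
#' @param df data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a headered TSV
#' @param path input file.
#' @return data.frame.
#' @export
readTsv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path,
                               call. = FALSE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write the truth manifest as JSON
#'
#' @param manifest manifest list from [generateGenome()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Read a truth manifest written by [writeManifest()]
#' @param path JSON file.
#' @return manifest list (data-frame fields restored).
#' @export
readManifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$geneLengths <- stats::setNames(as.numeric(unlist(m$geneLengths)),
                                   m$genes)
  if (is.data.frame(m$clusters)) {
    cl <- m$clusters
    m$clusters <- lapply(seq_len(nrow(cl)), function(i) {
      list(cluster_id = cl$cluster_id[i], chromosome = cl$chromosome[i],
           members = unlist(cl$members[[i]]), trueKs = cl$trueKs[i],
           trueKaks = cl$trueKaks[i], class = cl$class[i])
    })
  }
  m
}

#' Read counts and a design table
#'
#' @param countsPath TSV with `gene_id` column then one column per sample.
#' @param designPath TSV with `sample`, `tissue`, `timepoint`, `condition`,
#'   `replicate`.
#' @return list(counts = matrix, design = data.frame).
#' @export
readExpression <- function(countsPath, designPath) {
  cdf <- readTsv(countsPath)
  design <- readTsv(designPath)
  counts <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(counts) <- cdf$gene_id
  list(counts = counts, design = design)
}
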