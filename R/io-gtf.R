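#' Read transcript models from a GTF file
#'
#' Parses a Cufflinks/Cuffcompare-style GTF (1-based inclusive
#' coordinates, `transcript` and `exon` features, attributes
#' `transcript_id`, `gene_id` and optionally `class_code`) into
#' [transcript_model()] objects with internal 0-based half-open
#' coordinates. Parsing is delegated to \pkg{rtracklayer}; a light
#' pre-scan reports malformed lines by line number.
#'
#' @param path Path to a GTF file.
#' @return List of `transcript_model`, in file order of the `transcript`
#'   features. Transcripts without a `class_code` attribute get `"="`.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  body <- !grepl("^\\s*(#|$)", lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    bad <- which(body)[which(nfield != 9L)[1L]]
    stop("malformed GTF line ", bad, " in ", path,
         ": expected 9 tab-separated fields, found ", nfield[nfield != 9L][1L])
  }
  if (!any(body)) return(list())

  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  txid <- as.character(mc$transcript_id)
  geneid <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id) else txid
  ccode <- if ("class_code" %in% names(mc)) as.character(mc$class_code)
           else rep(NA_character_, length(gr))

  as_interval <- function(i) genomic_interval(
    chrom = as.character(GenomicRanges::seqnames(gr)[i]),
    start = GenomicRanges::start(gr)[i] - 1,   # 1-based inclusive -> 0-based half-open
    end = GenomicRanges::end(gr)[i],
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr)[i])))

  tx_rows <- which(type == "transcript")
  exon_rows <- which(type == "exon")
  orphan <- setdiff(unique(txid[exon_rows]), txid[tx_rows])
  if (length(orphan) > 0L)
    stop("exon feature(s) without a parent transcript feature: ",
         paste(head(orphan, 5), collapse = ", "))

  exon_by_tx <- split(exon_rows, txid[exon_rows])
  lapply(tx_rows, function(i) {
    id <- txid[i]
    exr <- exon_by_tx[[id]]
    exons <- lapply(exr, as_interval)
    exons <- exons[order(vapply(exons, function(e) e$start, numeric(1)))]
    if (length(exons) == 0L) exons <- list(as_interval(i))
    transcript_model(
      transcript_id = id,
      gene_id = if (is.na(geneid[i])) id else geneid[i],
      interval = as_interval(i),
      exons = exons,
      class_code = if (is.na(ccode[i])) "=" else ccode[i],
      source = "gtf")
  })
}

#' Write transcript models to a GTF file
#'
#' Emits one `transcript` feature plus its `exon` features per model,
#' converting the internal 0-based half-open coordinates back to GTF's
#' 1-based inclusive convention. `read_gtf(write_gtf(x))` round-trips.
#'
#' @param transcripts List of `transcript_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  fmt <- function(iv, type, tx) {
    sprintf("%s\tlncregnet\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; class_code \"%s\";",
            iv$chrom, type, as.integer(iv$start) + 1L, as.integer(iv$end),
            if (iv$strand == ".") "." else iv$strand,
            tx$gene_id, tx$transcript_id, tx$class_code)
  }
  lines <- unlist(lapply(transcripts, function(tx) {
    c(fmt(tx$interval, "transcript", tx),
      vapply(tx$exons, fmt, character(1), type = "exon", tx = tx))
  }))
  writeLines(as.character(lines), path)
  invisible(path)
}
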