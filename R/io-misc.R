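#' Read and write FASTA sequence files
#'
#' Thin wrappers over \pkg{Biostrings} returning plain named character
#' vectors (names truncated at the first whitespace), which is the
#' sequence representation used throughout the package.
#'
#' @param path File path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' @rdname read_fasta
#' @param sequences Named character vector.
#' @export
write_fasta <- function(sequences, path) {
  ss <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Coverage track
#'
#' Dense per-base signal per chromosome, e.g. normalized ATAC-seq
#' coverage. Values are non-negative and each array spans its whole
#' chromosome.
#'
#' @param values Named list of numeric vectors, one per chromosome.
#' @param sizes Named numeric vector of chromosome sizes; must match
#'   `lengths(values)`.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, sizes) {
  stopifnot(is.list(values), !is.null(names(values)))
  sizes <- sizes[names(values)]
  if (any(is.na(sizes))) stop("sizes missing for some chromosomes")
  if (!all(lengths(values) == sizes))
    stop("coverage array lengths must equal chromosome sizes")
  if (any(vapply(values, function(v) any(v < 0), logical(1))))
    stop("coverage values must be non-negative")
  structure(list(values = values, sizes = sizes), class = "coverage_track")
}

#' Read a bedGraph coverage file into a dense track
#'
#' bedGraph rows are 0-based half-open; bases not covered by any row get
#' signal 0.
#'
#' @param path bedGraph file.
#' @param sizes Named numeric vector of chromosome sizes.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, sizes) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  values <- lapply(setNames(names(sizes), names(sizes)),
                   function(ch) numeric(sizes[[ch]]))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  s0 <- GenomicRanges::start(gr) - 1          # back to 0-based half-open
  e0 <- GenomicRanges::end(gr)
  score <- S4Vectors::mcols(gr)$score
  for (i in seq_along(gr)) {
    ch <- chrom[i]
    if (!ch %in% names(values)) stop("unknown chromosome in bedGraph: ", ch)
    if (e0[i] > sizes[[ch]])
      stop("bedGraph interval ", ch, ":", s0[i], "-", e0[i],
           " exceeds chromosome size ", sizes[[ch]])
    values[[ch]][(s0[i] + 1):e0[i]] <- score[i]
  }
  coverage_track(values, sizes)
}

#' @rdname read_bedgraph
#' @param track A `coverage_track`.
#' @return `write_bedgraph()` writes run-length-encoded non-zero runs and
#'   returns `path` invisibly; `read_bedgraph(write_bedgraph(x))`
#'   round-trips.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$values)) {
    r <- rle(track$values[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%s", ch, starts[keep], ends[keep],
                         format(r$values[keep], digits = 15, trim = TRUE,
                                scientific = FALSE)), con)
  }
  invisible(path)
}

#' Read and write two-column chromosome-size tables
#' @param path File path.
#' @return `read_chrom_sizes()`: named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.delim(path, header = FALSE, col.names = c("chrom", "size"))
  setNames(as.numeric(df$size), as.character(df$chrom))
}

#' @rdname read_chrom_sizes
#' @param sizes Named numeric vector.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(sprintf("%s\t%d", names(sizes), as.integer(sizes)), path)
  invisible(path)
}

#' Position weight matrix motif
#'
#' @param motif_id Identifier.
#' @param matrix Numeric matrix, one row per position, columns
#'   `A`, `C`, `G`, `T`; each row sums to 1 (tolerance 1e-9).
#' @param background Length-4 probability vector over A,C,G,T.
#' @return An object of class `pwm_motif`.
#' @export
pwm_motif <- function(motif_id, matrix, background = rep(0.25, 4)) {
  matrix <- as.matrix(matrix)
  stopifnot(ncol(matrix) == 4L, nrow(matrix) >= 1L)
  colnames(matrix) <- c("A", "C", "G", "T")
  if (any(matrix < 0) || any(abs(rowSums(matrix) - 1) > 1e-9))
    stop("each PWM position must be a probability vector over A,C,G,T")
  background <- as.numeric(background)
  if (length(background) != 4L || any(background < 0) ||
      abs(sum(background) - 1) > 1e-9)
    stop("background must be a length-4 probability vector")
  names(background) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, matrix = matrix,
                 background = background), class = "pwm_motif")
}

#' @export
print.pwm_motif <- function(x, ...) {
  cat(sprintf("<pwm_motif %s, %d positions>\n", x$motif_id, nrow(x$matrix)))
  invisible(x)
}

#' Read motifs in MEME minimal format
#'
#' Supports the minimal motif format: a `MEME version` header, optional
#' `Background letter frequencies` block, and per-motif
#' `letter-probability matrix` blocks. No pre-installed R package parses
#' this format, so the reader is implemented here.
#'
#' @param path MEME file.
#' @return List of [pwm_motif()]; the file-level background (uniform if
#'   absent) is attached to every motif.
#' @export
read_meme <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path))
  background <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) == 1L) {
    toks <- strsplit(paste(lines[bg_at + 1L]), "\\s+")[[1]]
    freq <- as.numeric(toks[c(FALSE, TRUE)])
    names(freq) <- toks[c(TRUE, FALSE)]
    background <- unname(freq[c("A", "C", "G", "T")])
  }
  motif_at <- grep("^MOTIF\\s", lines)
  motifs <- vector("list", length(motif_at))
  for (k in seq_along(motif_at)) {
    i <- motif_at[k]
    id <- strsplit(lines[i], "\\s+")[[1]][2]
    j <- i + 1L
    while (j <= length(lines) && !grepl("^letter-probability matrix", lines[j]))
      j <- j + 1L
    if (j > length(lines))
      stop("motif ", id, " has no letter-probability matrix")
    w <- suppressWarnings(
      as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j])))
    rows <- lines[(j + 1L):(j + w)]
    mat <- do.call(rbind, lapply(strsplit(rows, "\\s+"), as.numeric))
    mat <- mat / rowSums(mat)   # absorb printed rounding
    motifs[[k]] <- pwm_motif(id, mat, background)
  }
  motifs
}

#' @rdname read_meme
#' @param motifs List of `pwm_motif` (sharing one background).
#' @export
write_meme <- function(motifs, path) {
  bg <- if (length(motifs) > 0) motifs[[1]]$background else rep(0.25, 4)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.6f C %.6f G %.6f T %.6f",
                       bg[1], bg[2], bg[3], bg[4]), ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$motif_id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       nrow(m$matrix)), con)
    writeLines(apply(m$matrix, 1, function(r)
      paste(sprintf("%.6f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read and write tab-separated tables with a header row
#' @param path File path.
#' @return `read_tsv_table()`: a `data.frame` (strings kept as character).
#' @export
read_tsv_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv_table
#' @param records A `data.frame`.
#' @export
write_tsv <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
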