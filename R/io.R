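#' Read an expression (or metabolite) matrix with its sample design
#'
#' The matrix file is TSV with a header row of sample ids and feature ids in
#' the first column; the design file is TSV with columns \code{sample},
#' \code{timepoint}, \code{replicate}.  Timepoint order follows the design
#' file's declaration order (first appearance), never lexicographic sorting.
#' Duplicate ids, samples missing from the design, and negative or
#' non-finite values are hard errors naming the offending record.
#'
#' @param path TSV matrix file.
#' @param designPath TSV design file.
#' @return A \linkS4class{TimecourseExperiment}.
#' @export
readExpression <- function(path, designPath) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate feature id in ", path, ": ", ids[duplicated(ids)][1L])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  design <- readDesign(designPath)
  TimecourseExperiment(m, design)
}

#' @rdname readExpression
#' @export
readMetabolites <- readExpression

#' Read a sample design table
#'
#' @param path TSV with columns sample, timepoint, replicate.
#' @return data.frame with timepoint as a factor levelled in declaration order.
#' @export
readDesign <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  validateDesign(d)
}

#' Write an expression matrix and design back to TSV
#'
#' Inverse of [readExpression()] up to floating-point formatting.
#'
#' @param x a TimecourseExperiment.
#' @param path matrix TSV to write.
#' @param designPath optional design TSV to write.
#' @param assay assay to write.
#' @export
writeExpression <- function(x, path, designPath = NULL, assay = 1L) {
  m <- abundances(x, assay)
  df <- data.frame(feature = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(designPath))
    write.table(designTable(x), designPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: id, description, then member ids, tab-separated.
#'
#' @param path GMT file.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("%s line %d: GMT record needs id, description and >=1 member",
                   path, i))
    sets[[f[1L]]] <- unique(f[-(1:2)])
    desc[f[1L]] <- f[2L]
  }
  GeneSetCollection(sets, desc)
}

#' Write gene sets in GMT format
#' @param x a GeneSetCollection
#' @param path output file
#' @export
writeGmt <- function(x, path) {
  lines <- vapply(setIds(x), function(id) {
    paste(c(id, x@description[[id]], x@sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read motifs in MEME minimal format
#'
#' Parses the MEME minimal text dialect: an optional
#' \code{Background letter frequencies} block, then one or more
#' \code{MOTIF <id>} blocks each followed by a
#' \code{letter-probability matrix:} header and per-position A C G T rows.
#' Columns not summing to 1 within \code{tol} are an error naming the motif
#' and position.
#'
#' @param path MEME minimal file.
#' @param tol tolerance on per-position probability sums.
#' @return A \linkS4class{PwmLibrary}.
#' @export
readMeme <- function(path, tol = 1e-4) {
  lines <- readLines(path)
  bg <- c(A = .25, C = .25, G = .25, T = .25)
  bgLine <- grep("^Background letter frequencies", lines)
  if (length(bgLine)) {
    f <- strsplit(trimws(lines[bgLine[1L] + 1L]), "\\s+")[[1L]]
    bg <- setNames(as.numeric(f[c(2, 4, 6, 8)]), f[c(1, 3, 5, 7)])[
      c("A", "C", "G", "T")]
  }
  motifStarts <- grep("^MOTIF\\s", lines)
  if (!length(motifStarts)) stop(path, ": no MOTIF block found")
  motifs <- list()
  for (s in motifStarts) {
    id <- strsplit(trimws(lines[s]), "\\s+")[[1L]][2L]
    hdr <- s + which(grepl("^letter-probability matrix",
                           lines[(s + 1):length(lines)]))[1L]
    if (is.na(hdr)) stop(sprintf("%s motif %s: missing letter-probability matrix",
                                 path, id))
    rows <- list(); i <- hdr + 1L
    while (i <= length(lines) &&
           grepl("^\\s*[0-9.eE+-]+(\\s+[0-9.eE+-]+){3}\\s*$", lines[i])) {
      rows[[length(rows) + 1L]] <- as.numeric(strsplit(trimws(lines[i]),
                                                       "\\s+")[[1L]])
      i <- i + 1L
    }
    if (!length(rows)) stop(sprintf("%s motif %s: empty matrix", path, id))
    m <- t(do.call(rbind, rows))   # rows A,C,G,T; columns positions
    rownames(m) <- c("A", "C", "G", "T")
    bad <- which(abs(colSums(m) - 1) > tol)
    if (length(bad))
      stop(sprintf("%s motif %s: position %d probabilities sum to %.6g, not 1",
                   path, id, bad[1L], colSums(m)[bad[1L]]))
    m <- sweep(m, 2L, colSums(m), "/")   # renormalize within tolerance
    motifs[[id]] <- m
  }
  PwmLibrary(motifs, bg)
}

#' Write motifs in MEME minimal format
#' @param x a PwmLibrary
#' @param path output file
#' @export
writeMeme <- function(x, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies"), con)
  writeLines(paste(sprintf("%s %.5f", names(x@background), x@background),
                   collapse = " "), con)
  for (id in motifIds(x)) {
    m <- x@motifs[[id]]
    writeLines(c("", paste("MOTIF", id),
                 sprintf("letter-probability matrix: alength= 4 w= %d", ncol(m))),
               con)
    for (j in seq_len(ncol(m)))
      writeLines(paste(sprintf("%.6f", m[, j]), collapse = " "), con)
  }
  invisible(path)
}

#' Read an undirected interaction network edge list
#'
#' Two or three whitespace/tab-separated columns: gene, gene, optional
#' confidence weight in [0,1].  Self-loops are an error; duplicate edges
#' (in either orientation) are collapsed to one.
#'
#' @param path edge list file.
#' @return data.frame with columns from, to, weight.
#' @export
readEdges <- function(path) {
  d <- read.delim(path, header = FALSE, sep = "", stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop(path, ": need at least two columns")
  edges <- data.frame(from = as.character(d[[1L]]), to = as.character(d[[2L]]),
                      weight = if (ncol(d) >= 3L) as.numeric(d[[3L]]) else 1,
                      stringsAsFactors = FALSE)
  loop <- edges$from == edges$to
  if (any(loop))
    stop(sprintf("%s line %d: self-loop on %s", path, which(loop)[1L],
                 edges$from[loop][1L]))
  if (any(edges$weight < 0 | edges$weight > 1, na.rm = TRUE))
    stop(path, ": confidence weights must lie in [0,1]")
  dedupEdges(edges)
}

dedupEdges <- function(edges) {
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  data.frame(from = a[keep], to = b[keep], weight = edges$weight[keep],
             stringsAsFactors = FALSE)
}

#' Write an edge list
#' @param edges data.frame from, to, weight
#' @param path output file
#' @export
writeEdges <- function(edges, path) {
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read promoter sequences from FASTA
#'
#' Sequences must be non-empty and restricted to the ACGTN alphabet
#' (case-insensitive; stored upper-case).
#'
#' @param path FASTA file.
#' @return a named \code{DNAStringSet}.
#' @export
readPromoters <- function(path) {
  raw <- Biostrings::readBStringSet(path)   # no silent letter coercion
  if (any(Biostrings::width(raw) == 0L))
    stop(path, ": empty sequence for record ",
         names(raw)[Biostrings::width(raw) == 0L][1L])
  txt <- toupper(as.character(raw))
  chars <- unique(unlist(strsplit(txt, "")))
  bad <- setdiff(chars, c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop(path, ": disallowed character(s) ", paste(bad, collapse = ","),
         " (alphabet is ACGTN)")
  if (anyDuplicated(names(raw)))
    stop(path, ": duplicate promoter id ",
         names(raw)[duplicated(names(raw))][1L])
  seqs <- Biostrings::DNAStringSet(txt)
  names(seqs) <- names(raw)
  seqs
}

#' Write promoter sequences to FASTA
#' @param seqs DNAStringSet
#' @param path output file
#' @export
writePromoters <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a TF annotation table
#'
#' TSV with columns \code{gene} and \code{family}; a gene may map to at
#' most one family.
#'
#' @param path TSV file.
#' @return named character vector gene -> family.
#' @export
readTfAnnotation <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene", "family") %in% colnames(d)))
    stop(path, ": need columns gene, family")
  if (anyDuplicated(d$gene))
    stop(path, ": gene annotated twice: ", d$gene[duplicated(d$gene)][1L])
  setNames(as.character(d$family), d$gene)
}

#' Read a pathway membership map
#'
#' TSV with columns \code{pathway}, \code{member}, \code{type} where type is
#' \code{gene} or \code{metabolite}.  Every pathway must have at least one
#' member of either kind.
#'
#' @param path TSV file.
#' @return data.frame pathway, member, type.
#' @export
readPathwayMap <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("pathway", "member", "type") %in% colnames(d)))
    stop(path, ": need columns pathway, member, type")
  bad <- !d$type %in% c("gene", "metabolite")
  if (any(bad))
    stop(sprintf("%s: unknown member type '%s' (row %d)", path,
                 d$type[bad][1L], which(bad)[1L]))
  d[!duplicated(d[c("pathway", "member", "type")]), , drop = FALSE]
}

#' Write a pathway membership map
#' @param map data.frame pathway, member, type
#' @param path output file
#' @export
writePathwayMap <- function(map, path) {
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
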