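#' Read a 10x-Genomics-style filtered gene-barcode matrix
#'
#' Reads a directory holding `matrix.mtx`, `barcodes.tsv` and either
#' `genes.tsv` (v2 layout, two columns: id, symbol) or `features.tsv`
#' (v3 layout, three columns: id, symbol, type), each optionally gzipped.
#' The dialect is auto-detected from the column count of the feature file.
#' Genes become rows and cells columns, matching the on-disk orientation.
#'
#' @param dir directory with the three files.
#' @param sample_id,species,condition sample annotation attached to the
#'   returned object (condition `"control"` or `"stimulated"`).
#' @param mito_prefix symbol prefix(es) flagged as mitochondrial,
#'   case-insensitive.
#' @return a [CountMatrix-class].
#' @examples
#' d <- tempfile(); dir.create(d)
#' m <- CountMatrix(matrix(c(0, 1, 2, 0, 3, 0), 3, 2),
#'                  gene_ids = c("g1", "g2", "g3"), barcodes = c("AA", "AC"),
#'                  sample_id = "s", species = "human")
#' writeCountMatrix(m, d)
#' m2 <- read10x(d, "s", "human")
#' @export
read10x <- function(dir, sample_id, species, condition = "control",
                    mito_prefix = "MT-") {
  mtx <- find10xFile(dir, "matrix.mtx")
  bc <- find10xFile(dir, "barcodes.tsv")
  ft <- find10xFile(dir, c("features.tsv", "genes.tsv"))
  mtx_con <- openMaybeGz(mtx)
  on.exit(close(mtx_con))
  counts <- as(Matrix::readMM(mtx_con), "CsparseMatrix")
  barcodes <- readAllLines(bc)
  feat_lines <- readAllLines(ft)
  feat <- if (length(feat_lines)) {
    utils::read.table(text = feat_lines, sep = "\t", header = FALSE,
                      quote = "", comment.char = "",
                      colClasses = "character")
  } else data.frame(V1 = character(), V2 = character())
  if (nrow(feat) != nrow(counts))
    stop(sprintf(
      "integrity error: matrix declares %d genes but %s has %d lines",
      nrow(counts), basename(ft), nrow(feat)))
  if (length(barcodes) != ncol(counts))
    stop(sprintf(
      "integrity error: matrix declares %d cells but %s has %d lines",
      ncol(counts), basename(bc), length(barcodes)))
  symbols <- if (ncol(feat) >= 2) feat[[2]] else feat[[1]]
  CountMatrix(counts, gene_ids = feat[[1]], gene_symbols = symbols,
              barcodes = barcodes, sample_id = sample_id, species = species,
              condition = condition, mito_prefix = mito_prefix)
}

find10xFile <- function(dir, names) {
  if (!dir.exists(dir)) stop("format error: directory not found: ", dir)
  for (nm in names)
    for (cand in file.path(dir, c(nm, paste0(nm, ".gz"))))
      if (file.exists(cand)) return(cand)
  stop("format error: missing file ", paste(names, collapse = " or "),
       " in ", dir)
}

openMaybeGz <- function(path) {
  if (endsWith(path, ".gz")) gzfile(path, "r") else file(path, "r")
}

readAllLines <- function(path) {
  con <- openMaybeGz(path)
  on.exit(close(con))
  readLines(con)
}

#' Write a CountMatrix as a 10x-style directory
#'
#' Emits MatrixMarket `matrix.mtx`, `features.tsv` (v3: id, symbol,
#' "Gene Expression") and `barcodes.tsv`, readable by [read10x()].
#'
#' @param x a [CountMatrix-class].
#' @param dir output directory (created if needed).
#' @param gzip compress the three files.
#' @return `dir`, invisibly.
#' @export
writeCountMatrix <- function(x, dir, gzip = FALSE) {
  stopifnot(is(x, "CountMatrix"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("I/O error: cannot create ", dir)
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(as(assay(x, "counts"), "CsparseMatrix"), mtx)
  feat <- data.frame(id = rownames(x),
                     symbol = as.character(geneSymbols(x)),
                     type = rep("Gene Expression", nrow(x)))
  ftp <- file.path(dir, "features.tsv")
  bcp <- file.path(dir, "barcodes.tsv")
  utils::write.table(feat, ftp, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(colnames(x), bcp)
  if (gzip) {
    for (p in c(mtx, ftp, bcp)) {
      con <- gzfile(paste0(p, ".gz"), "wb")
      writeLines(readLines(p), con)
      close(con)
      unlink(p)
    }
  }
  invisible(dir)
}

#' Read a dense gene x cell count table
#'
#' First column gene ids, remaining columns one cell each (TSV or CSV by
#' extension), header row of barcodes.
#'
#' @inheritParams read10x
#' @param path table path.
#' @return a [CountMatrix-class].
#' @export
readDenseCounts <- function(path, sample_id, species, condition = "control",
                            mito_prefix = "MT-") {
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  tb <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          row.names = 1)
  CountMatrix(as.matrix(tb), gene_ids = rownames(tb),
              barcodes = colnames(tb), sample_id = sample_id,
              species = species, condition = condition,
              mito_prefix = mito_prefix)
}

#' Read a two-column cross-species gene map
#'
#' Two-column TSV (species A symbol, species B symbol); an optional header
#' line is detected and dropped when its fields repeat nowhere else as a
#' pair. Duplicate pair lines are deduplicated; a symbol mapping to two
#' different partners on either side is an error (the map must be
#' one-to-one). An empty file yields a symbol-intersection map.
#'
#' @param path TSV path.
#' @param header logical; `NA` (default) auto-detects a header line.
#' @return a [GeneMap-class].
#' @export
readGeneMap <- function(path, header = NA) {
  lines <- readAllLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(GeneMap(NULL))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2))
    stop("format error: gene map must have two tab-separated columns")
  if (is.na(header))
    header <- tolower(parts[[1]][1]) %in%
      c("gene", "symbol", "symbol_a", "species_a", "query", "human")
  if (isTRUE(header)) parts <- parts[-1]
  if (length(parts) == 0) return(GeneMap(NULL))
  pairs <- unique(data.frame(a = vapply(parts, `[`, "", 1),
                             b = vapply(parts, `[`, "", 2)))
  dupA <- unique(pairs$a[duplicated(pairs$a)])
  dupB <- unique(pairs$b[duplicated(pairs$b)])
  if (length(dupA) || length(dupB))
    stop("one-to-many gene map for symbol(s): ",
         paste(unique(c(dupA, dupB)), collapse = ", "))
  GeneMap(pairs)
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: per line, set name, description, then member
#'   genes, tab-separated.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readAllLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1)
  sets
}
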