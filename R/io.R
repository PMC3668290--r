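#' Read a genotype matrix
#'
#' Two dialects are supported: `"tsv"` — tab-delimited, header row of SNP
#' ids, one row per individual, entries 0/1/2 (minor-allele counts) — and
#' `"plink_raw"` — PLINK `.raw`-style, with FID IID PAT MAT SEX PHENOTYPE
#' columns followed by allele-dosage columns. `"auto"` sniffs the header.
#'
#' @param path file path.
#' @param dialect `"auto"`, `"tsv"` or `"plink_raw"`.
#' @return integer matrix (individuals x SNPs) with SNP ids as column names
#'   and, for the PLINK dialect, IIDs as row names.
#' @export
readGenotypes <- function(path, dialect = c("auto", "tsv", "plink_raw")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "auto") {
    hdr <- strsplit(readLines(path, n = 1L), "[\t ]")[[1]]
    dialect <- if (length(hdr) >= 6L &&
                   all(hdr[1:2] == c("FID", "IID"))) "plink_raw" else "tsv"
  }
  df <- read.delim(path, header = TRUE, sep = "",
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "plink_raw") {
    meta <- df[, 1:6, drop = FALSE]
    df <- df[, -(1:6), drop = FALSE]
    rn <- as.character(meta$IID)
  } else {
    rn <- NULL
  }
  G <- as.matrix(df)
  bad <- which(!(G %in% c(0L, 1L, 2L)) | is.na(G))
  if (length(bad)) {
    r <- (bad[1] - 1) %% nrow(G) + 1
    c <- (bad[1] - 1) %/% nrow(G) + 1
    stop(sprintf(
      "invalid genotype entry '%s' at individual %d, SNP '%s' (only 0/1/2 supported, no missing data)",
      G[bad[1]], r, colnames(G)[c]))
  }
  storage.mode(G) <- "integer"
  rownames(G) <- rn
  G
}

#' Write a genotype matrix
#'
#' @param G integer genotype matrix.
#' @param path file path.
#' @param dialect `"tsv"` or `"plink_raw"` (dummy FID/IID etc. columns are
#'   synthesized from row names or indices).
#' @return invisibly, `path`.
#' @export
writeGenotypes <- function(G, path, dialect = c("tsv", "plink_raw")) {
  dialect <- match.arg(dialect)
  stopifnot(all(G %in% 0:2))
  df <- as.data.frame(G)
  if (dialect == "plink_raw") {
    ids <- if (is.null(rownames(G))) paste0("IND", seq_len(nrow(G)))
           else rownames(G)
    df <- cbind(FID = ids, IID = ids, PAT = 0L, MAT = 0L, SEX = 0L,
                PHENOTYPE = -9L, df)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a quantitative trait vector
#'
#' One numeric value per line; a single non-numeric first line is treated
#' as a header.
#'
#' @param path file path.
#' @return finite numeric vector.
#' @export
readTrait <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  start <- 1L
  if (length(lines) && is.na(suppressWarnings(as.numeric(lines[1])))) {
    start <- 2L  # header
  }
  body <- lines[seq.int(start, length.out = length(lines) - start + 1L)]
  vals <- suppressWarnings(as.numeric(body))
  bad <- which(!is.finite(vals))
  if (length(bad))
    stop(sprintf("non-numeric or non-finite trait value '%s' at line %d",
                 body[bad[1]], bad[1] + start - 1L))
  vals
}

#' Write a trait vector
#'
#' @param y numeric vector.
#' @param path file path.
#' @param header optional column name to write as the first line.
#' @return invisibly, `path`.
#' @export
writeTrait <- function(y, path, header = "trait") {
  stopifnot(all(is.finite(y)))
  writeLines(c(header, format(y, digits = 15, trim = TRUE)), path)
  invisible(path)
}

#' Write results with a JSON metadata sidecar
#'
#' Writes a result table ([MbmdrResult-class] pair table or study-cell
#' data.frame) as TSV with fixed 6-significant-digit formatting and
#' deterministic row order, plus a `<path>.meta.json` sidecar recording the
#' seed, tool version and any extra metadata.
#'
#' @param x an [MbmdrResult-class] or data.frame.
#' @param path output TSV path.
#' @param seed seed to record.
#' @param meta named list of extra metadata.
#' @param sidecar write the JSON sidecar?
#' @return invisibly, `path`.
#' @export
writeResults <- function(x, path, seed = NA_integer_, meta = list(),
                         sidecar = TRUE) {
  if (is(x, "MbmdrResult")) {
    cfg <- analysisConfigOf(x)
    if (is.na(seed)) seed <- cfg@seed
    meta <- c(meta, list(test = cfg@testKind,
                         nPermutations = cfg@nPermutations,
                         alphaOverall = cfg@alphaOverall,
                         minCell = cfg@minCell,
                         alphaLabel = cfg@alphaLabel,
                         nSignificant = sum(x@pairs$significant)))
    x <- pairResults(x)
  }
  stopifnot(is.data.frame(x))
  fmt <- x
  for (cn in names(fmt)) {
    if (is.numeric(fmt[[cn]]) && !is.integer(fmt[[cn]]))
      fmt[[cn]] <- signif(fmt[[cn]], 6)
  }
  write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (sidecar) {
    meta <- c(list(seed = seed,
                   tool = "qmbmdr",
                   version = as.character(packageVersion("qmbmdr")),
                   rows = nrow(x)), meta)
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
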