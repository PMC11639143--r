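#' Read a delimited allele-frequency table
#'
#' The expected layout is a header row `SNP<delim>Pop1<delim>Pop2...`
#' followed by one row per SNP: the SNP identifier and one frequency per
#' population. Rows containing a missing token or a value outside \[0, 1\]
#' are dropped (the f-statistics assume complete frequency vectors); the
#' number of dropped rows is reported with a message.
#'
#' @param path Path to the table.
#' @param delimiter Field separator, default tab.
#' @param missing_token String that marks a missing value, default `"NA"`.
#' @return A [frequency_panel].
#' @export
read_frequency_table <- function(path, delimiter = "\t", missing_token = "NA") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("empty panel: no data rows in ", path)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 2L) stop("header must name at least one population")
  pops <- header[-1L]
  width <- length(header)
  widths <- lengths(fields[-1L])
  if (any(widths != width)) {
    bad <- which(widths != width)[1L] + 1L
    stop(sprintf("malformed row at line %d: expected %d fields, found %d",
                 bad, width, widths[bad - 1L]))
  }
  body <- matrix(unlist(fields[-1L]), ncol = width, byrow = TRUE)
  ids <- body[, 1L]
  vals <- body[, -1L, drop = FALSE]
  vals[vals == missing_token] <- NA_character_
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  keep <- !apply(is.na(num) | num < 0 | num > 1, 1L, any)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(sprintf("read_frequency_table: dropped %d row(s) with missing or out-of-range values",
                    n_dropped))
  }
  if (!any(keep)) stop("empty panel: no usable rows after filtering")
  frequency_panel(num[keep, , drop = FALSE],
                  snp_ids = ids[keep], pop_names = pops)
}

#' Collapse an EIGENSTRAT genotype triple to population frequencies
#'
#' Reads the plain-text EIGENSTRAT layout: `geno` has one line per SNP with
#' one character per sample (0/1/2 = alternate-allele count, 9 = missing),
#' `snp` gives SNP identifiers in its first column, `ind` maps each sample
#' to a population in its third column. The per-population frequency is
#' (sum of alternate-allele counts) / (2 x non-missing samples). SNPs where
#' any population has zero non-missing samples are dropped and the count is
#' reported.
#'
#' @param geno_path,snp_path,ind_path Paths to the three EIGENSTRAT files.
#' @return A [frequency_panel] with one column per population.
#' @export
read_eigenstrat <- function(geno_path, snp_path, ind_path) {
  for (p in c(geno_path, snp_path, ind_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p))
  }
  ind <- utils::read.table(ind_path, header = FALSE,
                           colClasses = "character",
                           col.names = c("sample", "sex", "pop"))
  snp <- utils::read.table(snp_path, header = FALSE,
                           colClasses = "character")
  geno_lines <- readLines(geno_path)
  geno_lines <- geno_lines[nzchar(geno_lines)]
  if (length(geno_lines) != nrow(snp)) {
    stop(sprintf("format error: %d geno lines but %d snp records",
                 length(geno_lines), nrow(snp)))
  }
  widths <- nchar(geno_lines)
  if (any(widths != nrow(ind))) {
    stop(sprintf("format error: geno line width %d does not match %d samples",
                 widths[which(widths != nrow(ind))[1L]], nrow(ind)))
  }
  g <- matrix(utf8ToInt(paste(geno_lines, collapse = "")) - 48L,
              nrow = length(geno_lines), byrow = TRUE)
  if (any(!g %in% c(0L, 1L, 2L, 9L))) {
    stop("format error: genotype characters must be 0, 1, 2 or 9")
  }
  pops <- unique(ind$pop)
  alt <- matrix(0, nrow(g), length(pops), dimnames = list(NULL, pops))
  nm <- alt
  for (p in pops) {
    cols <- which(ind$pop == p)
    sub <- g[, cols, drop = FALSE]
    ok <- sub != 9L
    alt[, p] <- rowSums(sub * ok)
    nm[, p] <- rowSums(ok)
  }
  keep <- rowSums(nm == 0) == 0L
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(sprintf("read_eigenstrat: dropped %d SNP(s) entirely missing in some population",
                    n_dropped))
  }
  if (!any(keep)) stop("empty panel: all SNPs dropped")
  freqs <- alt[keep, , drop = FALSE] / (2 * nm[keep, , drop = FALSE])
  frequency_panel(freqs, snp_ids = snp[[1L]][keep], pop_names = pops)
}

#' Write an allele-frequency table
#'
#' Writes the tab-delimited (by default) layout read by
#' [read_frequency_table()], with frequencies at 6 decimals; a write/read
#' round trip reproduces the panel at that precision.
#'
#' @param panel A [frequency_panel].
#' @param path Output path.
#' @param delimiter Field separator, default tab.
#' @param digits Decimals used for frequencies, default 6.
#' @export
write_frequency_table <- function(panel, path, delimiter = "\t", digits = 6L) {
  stopifnot(is_frequency_panel(panel))
  if (ncol(panel) == 0L) stop("panel has no populations")
  header <- paste(c("SNP", colnames(panel)), collapse = delimiter)
  body <- apply(format(round(unclass(panel), digits), nsmall = digits,
                       trim = TRUE, scientific = FALSE),
                1L, paste, collapse = delimiter)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, paste(rownames(panel), body, sep = delimiter)), con)
  invisible(path)
}
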