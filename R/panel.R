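#' Allele-frequency panel
#'
#' A frequency panel is the phase-space embedding of a set of populations:
#' a numeric matrix with one row per SNP and one column per population,
#' every entry an allele frequency in \[0, 1\]. Each population is a point
#' in an s-dimensional space whose axes are the SNPs; all f-statistics in
#' this package are scalar products of difference vectors in that space.
#'
#' @param freqs Numeric matrix, SNPs x populations, entries in \[0, 1\].
#' @param snp_ids Character vector of SNP identifiers (defaults to rownames
#'   of `freqs`, or `snp_1 ... snp_s`).
#' @param pop_names Character vector of unique population labels (defaults
#'   to colnames of `freqs`).
#' @return An object of class `frequency_panel`: the matrix with SNP ids as
#'   rownames and population labels as colnames.
#' @examples
#' p <- frequency_panel(matrix(c(0.1, 0.9, 0.2, 0.8), 2, 2),
#'                      pop_names = c("a", "b"))
#' n_snps(p)
#' @export
frequency_panel <- function(freqs, snp_ids = NULL, pop_names = NULL) {
  freqs <- as.matrix(freqs)
  storage.mode(freqs) <- "double"
  if (is.null(pop_names)) pop_names <- colnames(freqs)
  if (is.null(snp_ids)) snp_ids <- rownames(freqs)
  if (ncol(freqs) == 0L || length(pop_names) == 0L) {
    stop("a frequency panel needs at least one population")
  }
  if (is.null(pop_names)) {
    stop("population names are required (colnames or `pop_names`)")
  }
  if (is.null(snp_ids)) snp_ids <- paste0("snp_", seq_len(nrow(freqs)))
  if (length(pop_names) != ncol(freqs)) {
    stop("length(pop_names) must equal ncol(freqs)")
  }
  if (length(snp_ids) != nrow(freqs)) {
    stop("length(snp_ids) must equal nrow(freqs)")
  }
  if (anyDuplicated(pop_names)) {
    stop("population labels must be unique")
  }
  if (anyNA(freqs)) {
    stop("frequency panel must not contain missing values")
  }
  if (any(freqs < 0 | freqs > 1)) {
    stop("all allele frequencies must lie in [0, 1]")
  }
  dimnames(freqs) <- list(as.character(snp_ids), as.character(pop_names))
  structure(freqs, class = c("frequency_panel", "matrix", "array"))
}

#' @rdname frequency_panel
#' @param x,panel A `frequency_panel`.
#' @export
is_frequency_panel <- function(x) inherits(x, "frequency_panel")

#' @rdname frequency_panel
#' @export
n_snps <- function(panel) nrow(panel)

#' @rdname frequency_panel
#' @export
pop_names <- function(panel) colnames(panel)

#' @rdname frequency_panel
#' @export
snp_ids <- function(panel) rownames(panel)

#' @param ... Ignored.
#' @rdname frequency_panel
#' @export
print.frequency_panel <- function(x, ...) {
  cat(sprintf("<frequency_panel> %d SNPs x %d populations\n",
              nrow(x), ncol(x)))
  cat("populations:", paste(colnames(x), collapse = ", "), "\n")
  invisible(x)
}

# single population column as a plain vector; errors on unknown label
pop_vector <- function(panel, label) {
  if (length(label) != 1L || !label %in% colnames(panel)) {
    stop(sprintf("unknown population label: '%s'", paste(label, collapse = ",")),
         call. = FALSE)
  }
  panel[, label]
}

check_pops <- function(panel, labels) {
  missing <- setdiff(labels, colnames(panel))
  if (length(missing) > 0L) {
    stop(sprintf("unknown population label(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(labels)
}
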