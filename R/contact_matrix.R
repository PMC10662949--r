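#' Symmetric binned Hi-C contact matrix
#'
#' @param matrix symmetric numeric matrix (bins x bins, genome-wide with
#'   chromosomes concatenated in genome order); `NA` marks masked entries.
#' @param resolution bin size in bp.
#' @param genome the `genome_model` defining chromosome order and lengths,
#'   or `NULL` if `chromosomes` is given directly.
#' @param chromosomes alternative to `genome`: data.frame `name`, `length`.
#' @param normalization one of `"raw"`, `"vc_sqrt"`, `"observed_expected"`,
#'   `"log2_ratio"`.
#' @param condition free-text condition label.
#' @param tol symmetry tolerance (relative).
#' @return object of class `contact_matrix` with the matrix, the bin table
#'   (`chromosome`, `start`, `end`, `partial`) and per-chromosome bin index
#'   offsets.
#' @export
contact_matrix <- function(matrix, resolution, genome = NULL,
                           chromosomes = NULL,
                           normalization = c("raw", "vc_sqrt",
                                             "observed_expected",
                                             "log2_ratio"),
                           condition = NA_character_, tol = 1e-8) {
  normalization <- match.arg(normalization)
  if (is.null(chromosomes)) {
    stopifnot(inherits(genome, "genome_model"))
    chromosomes <- genome$chromosomes
  }
  bins <- do.call(rbind, lapply(seq_len(nrow(chromosomes)), function(i) {
    L <- chromosomes$length[i]
    nb <- ceiling(L / resolution)
    data.frame(chromosome = chromosomes$name[i],
               start = (seq_len(nb) - 1) * resolution,
               end = pmin(seq_len(nb) * resolution, L),
               partial = seq_len(nb) * resolution > L,
               stringsAsFactors = FALSE)
  }))
  n <- nrow(bins)
  stopifnot(is.matrix(matrix), nrow(matrix) == n, ncol(matrix) == n)
  mx <- max(abs(matrix), na.rm = TRUE)
  asym <- max(abs(matrix - t(matrix)), na.rm = TRUE)
  if (is.finite(mx) && mx > 0 && asym > tol * mx)
    stop("matrix is not symmetric within tolerance")
  if (normalization == "raw" && any(matrix < 0, na.rm = TRUE))
    stop("raw contact matrix must be non-negative")
  structure(list(matrix = matrix, resolution = resolution,
                 chromosomes = chromosomes, bins = bins,
                 normalization = normalization, condition = condition),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %d bins @ %g bp [%s], %d chromosome(s)%s\n",
              nrow(x$matrix), x$resolution, x$normalization,
              nrow(x$chromosomes),
              if (is.na(x$condition)) "" else paste0(", ", x$condition)))
  invisible(x)
}

# bin index range of one chromosome
.chrom_bin_idx <- function(m, chrom) {
  which(m$bins$chromosome == chrom)
}

# logical matrix: TRUE where both bins on the same chromosome
.intra_mask <- function(m) {
  outer(m$bins$chromosome, m$bins$chromosome, "==")
}

#' Total counts of a contact matrix
#'
#' Defined over the upper triangle including the diagonal (each pair
#' counted once), matching the simulator's read-pair budget.
#' @param m a `contact_matrix`.
#' @return numeric scalar.
#' @export
contact_total <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  sum(m$matrix[upper.tri(m$matrix, diag = TRUE)], na.rm = TRUE)
}

#' Write a contact matrix as dense TSV
#'
#' A `#` header records resolution, normalization and the chromosome
#' offsets, so the file round-trips through [read_contact_tsv()].
#'
#' @param m a `contact_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contact_tsv <- function(m, path) {
  stopifnot(inherits(m, "contact_matrix"))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c(
    sprintf("# resolution=%g", m$resolution),
    sprintf("# normalization=%s", m$normalization),
    sprintf("# condition=%s", m$condition),
    sprintf("# chromosome=%s:%g", m$chromosomes$name,
            m$chromosomes$length)), con)
  utils::write.table(m$matrix, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a dense TSV contact matrix written by [write_contact_tsv()]
#' @param path input file.
#' @return a `contact_matrix`.
#' @export
read_contact_tsv <- function(path) {
  hdr <- character(0)
  con <- file(path, "r")
  on.exit(close(con), add = TRUE)
  repeat {
    l <- readLines(con, 1)
    if (!length(l) || !startsWith(l, "#")) break
    hdr <- c(hdr, sub("^# *", "", l))
  }
  get1 <- function(key) sub(paste0("^", key, "="), "",
                            grep(paste0("^", key, "="), hdr, value = TRUE))
  chrom_spec <- get1("chromosome")
  chromosomes <- data.frame(
    name = sub(":.*$", "", chrom_spec),
    length = as.numeric(sub("^.*:", "", chrom_spec)),
    stringsAsFactors = FALSE)
  body <- c(l, readLines(con))
  M <- as.matrix(utils::read.delim(text = body, header = FALSE))
  dimnames(M) <- NULL
  contact_matrix(M, resolution = as.numeric(get1("resolution")),
                 chromosomes = chromosomes,
                 normalization = get1("normalization"),
                 condition = get1("condition"))
}
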