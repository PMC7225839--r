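#' Genotype matrix container
#'
#' Builds the package's central genotype container: an individuals-by-markers
#' allele-dosage matrix plus marker metadata. Codominant (SNP-style) markers
#' carry dosages in \{0, 1, 2\}; dominant (presence/absence tag) markers carry
#' \{0, 1\}. `NA` marks a missing call in either class.
#'
#' @param dosages Numeric matrix, lines x markers. Row names are line ids and
#'   column names marker ids; default ids are generated when absent.
#' @param marker_class `"codominant"` or `"dominant"`.
#' @param chrom Optional chromosome id per marker.
#' @param pos Optional marker position per marker (1-based physical bp or cM;
#'   cM positions are what the doubled-haploid simulator consumes).
#' @param present_allele Optional per-marker orientation flag for dominant
#'   data: which codominant allele ("ref" counts dosage 0, "alt" dosage 2)
#'   was designated tag-present when the marker was collapsed.
#' @return An object of class `geno_matrix`.
#' @seealso [read_genotypes()], [compute_qc()], [grm()]
#' @export
genotype_matrix <- function(dosages, marker_class = c("codominant", "dominant"),
                            chrom = NULL, pos = NULL, present_allele = NULL) {
  marker_class <- match.arg(marker_class)
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(rownames(dosages)) && nrow(dosages) > 0)
    rownames(dosages) <- paste0("line", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)) && ncol(dosages) > 0)
    colnames(dosages) <- paste0("m", seq_len(ncol(dosages)))
  if (anyDuplicated(rownames(dosages)))
    stop("duplicate line ids in genotype matrix")
  if (anyDuplicated(colnames(dosages)))
    stop("duplicate marker ids in genotype matrix")
  vals <- dosages[!is.na(dosages)]
  allowed <- if (marker_class == "codominant") c(0, 1, 2) else c(0, 1)
  # post-imputation matrices hold fractional dosages; only the range is policed
  if (length(vals) && (min(vals) < 0 || max(vals) > max(allowed)))
    stop(sprintf("dosages outside [0, %d] for %s markers",
                 max(allowed), marker_class))
  if (!is.null(chrom) && length(chrom) != ncol(dosages))
    stop("chrom length must equal marker count")
  if (!is.null(pos) && length(pos) != ncol(dosages))
    stop("pos length must equal marker count")
  structure(
    list(dosages = dosages, marker_class = marker_class,
         chrom = chrom, pos = pos, present_allele = present_allele),
    class = "geno_matrix")
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Line identifiers of a genotype matrix
#' @param geno A `geno_matrix`.
#' @return Character vector of line ids.
#' @export
line_ids <- function(geno) rownames(geno$dosages)

#' Marker identifiers of a genotype matrix
#' @param geno A `geno_matrix`.
#' @return Character vector of marker ids.
#' @export
marker_ids <- function(geno) colnames(geno$dosages)

#' @export
print.geno_matrix <- function(x, ...) {
  d <- dim(x$dosages)
  miss <- mean(is.na(x$dosages))
  cat(sprintf("geno_matrix: %d lines x %d %s markers (%.1f%% missing)\n",
              d[1], d[2], x$marker_class, 100 * miss))
  if (!is.null(x$chrom))
    cat(sprintf("  map: %d chromosome(s)\n", length(unique(x$chrom))))
  invisible(x)
}

#' Subset a genotype matrix by markers or lines
#'
#' Index-based subsetting that keeps the marker metadata (map, class,
#' dominant-tag orientation) in step with the dosage matrix.
#'
#' @param geno A `geno_matrix`.
#' @param j Marker indices (or ids via `match`).
#' @param i Line indices.
#' @return A `geno_matrix`.
#' @export
subset_markers <- function(geno, j) {
  genotype_matrix(geno$dosages[, j, drop = FALSE], geno$marker_class,
                  chrom = geno$chrom[j], pos = geno$pos[j],
                  present_allele = geno$present_allele[j])
}

#' @rdname subset_markers
#' @export
subset_lines <- function(geno, i) {
  genotype_matrix(geno$dosages[i, , drop = FALSE], geno$marker_class,
                  chrom = geno$chrom, pos = geno$pos,
                  present_allele = geno$present_allele)
}
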