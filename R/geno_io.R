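## Genotype file readers/writers: HapMap, VCF (GT only), CSV dosage dialect.

IUPAC_HET <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

#' Read a genotype matrix from file
#'
#' Reads called genotypes into a [genotype_matrix()]. Three formats are
#' supported:
#' \describe{
#'   \item{hapmap}{TASSEL-style tab-delimited HapMap: 11 metadata columns
#'     (`rs#`, `alleles`, `chrom`, `pos`, ...) followed by one column per
#'     line. Calls are single-letter IUPAC codes (heterozygote codes R, Y, S,
#'     W, K, M map to dosage 1; `N` to missing) or two-letter diplotypes
#'     (`AA`, `AC`, `NN`). Dosage counts the second allele of the `alleles`
#'     field (the alternate allele).}
#'   \item{vcf}{VCF 4.x via the vcfR package; only the GT field is used,
#'     `./.` becomes missing.}
#'   \item{csv}{The package's dosage dialect: first column line ids, one
#'     column per marker, values 0/1/2 (codominant) or 0/1 (dominant), empty
#'     or NA for missing. Written by [write_genotypes()].}
#' }
#'
#' @param path File path.
#' @param format `"hapmap"`, `"vcf"` or `"csv"`.
#' @param marker_class Marker class to stamp on CSV input (HapMap and VCF are
#'   always codominant).
#' @return A `geno_matrix`, lines x markers.
#' @export
read_genotypes <- function(path, format = c("hapmap", "vcf", "csv"),
                           marker_class = "codominant") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         hapmap = read_hapmap(path),
         vcf = read_vcf_gt(path),
         csv = read_dosage_csv(path, marker_class))
}

read_hapmap <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (nrow(tab) == 0) stop("HapMap file has no marker records: ", path)
  if (ncol(tab) < 12) stop("HapMap file needs 11 metadata columns plus ",
                           "at least one genotype column: ", path)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicate marker names in HapMap file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  alleles <- strsplit(as.character(tab[[2]]), "/", fixed = TRUE)
  bad <- which(lengths(alleles) != 2)
  if (length(bad))
    stop(sprintf("malformed alleles field at data line %d: '%s'",
                 bad[1] + 1L, tab[[2]][bad[1]]))
  calls <- as.matrix(tab[, -(1:11), drop = FALSE])
  n_markers <- nrow(calls)
  dos <- matrix(NA_real_, nrow = ncol(calls), ncol = n_markers,
                dimnames = list(colnames(calls), ids))
  for (j in seq_len(n_markers)) {
    a <- toupper(alleles[[j]])          # a[1] ref, a[2] alt (counted)
    g <- toupper(calls[j, ])
    d <- rep(NA_real_, length(g))
    w <- nchar(g)
    if (any(w == 1)) {
      s <- g[w == 1]
      d1 <- rep(NA_real_, length(s))
      d1[s == a[1]] <- 0
      d1[s == a[2]] <- 2
      het <- s %in% names(IUPAC_HET)
      d1[het] <- 1
      d1[s == "N" | s == "-"] <- NA
      unknown <- is.na(d1) & !(s %in% c("N", "-")) & !het &
        !(s %in% a)
      if (any(unknown))
        stop(sprintf("unrecognized genotype code '%s' at data line %d",
                     s[which(unknown)[1]], j + 1L))
      ## het codes must be consistent with the marker's two alleles
      if (any(het)) {
        exp_pair <- paste(sort(a), collapse = "")
        bad_het <- het & IUPAC_HET[s] != exp_pair
        if (any(bad_het))
          stop(sprintf(
            "heterozygote code '%s' inconsistent with alleles %s/%s at data line %d",
            s[which(bad_het)[1]], a[1], a[2], j + 1L))
      }
      d[w == 1] <- d1
    }
    if (any(w == 2)) {
      s <- g[w == 2]
      d2 <- vapply(strsplit(s, ""), function(p) {
        if (any(p == "N")) return(NA_real_)
        if (!all(p %in% a)) return(-1)
        sum(p == a[2])
      }, numeric(1))
      if (any(d2 %in% -1))
        stop(sprintf("unrecognized genotype code '%s' at data line %d",
                     s[which(d2 %in% -1)[1]], j + 1L))
      d[w == 2] <- d2
    }
    if (any(!w %in% c(1, 2)))
      stop(sprintf("mixed-ploidy or malformed call '%s' at data line %d",
                   g[which(!w %in% c(1, 2))[1]], j + 1L))
    dos[, j] <- d
  }
  genotype_matrix(dos, "codominant",
                  chrom = as.character(tab[[3]]), pos = as.numeric(tab[[4]]))
}

read_vcf_gt <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || nrow(gt) == 0) stop("VCF has no GT records: ", path)
  if (anyDuplicated(rownames(gt)))
    stop("duplicate marker names in VCF: ",
         paste(unique(rownames(gt)[duplicated(rownames(gt))]), collapse = ", "))
  gt2 <- gsub("|", "/", gt, fixed = TRUE)
  dos <- apply(gt2, c(1, 2), function(g) {
    if (is.na(g) || g %in% c("./.", ".")) return(NA_real_)
    al <- suppressWarnings(as.integer(strsplit(g, "/", fixed = TRUE)[[1]]))
    if (length(al) != 2 || anyNA(al)) return(NA_real_)
    sum(al > 0)
  })
  fix <- vcfR::getFIX(v)
  genotype_matrix(t(dos), "codominant",
                  chrom = as.character(fix[, "CHROM"]),
                  pos = as.numeric(fix[, "POS"]))
}

read_dosage_csv <- function(path, marker_class) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("dosage CSV has no marker columns: ", path)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  genotype_matrix(m, marker_class)
}

#' Write a genotype matrix to file
#'
#' @param geno A `geno_matrix`.
#' @param path Output path.
#' @param format `"csv"` (dosage dialect read back by [read_genotypes()]) or
#'   `"hapmap"`. HapMap export encodes codominant dosages as A (ref
#'   homozygote), M (heterozygote), C (alt homozygote) and N (missing), with
#'   alleles `A/C`; it requires integer dosages (impute-free data).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, format = c("csv", "hapmap")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(line_id = rownames(geno$dosages),
                     geno$dosages, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    if (geno$marker_class != "codominant")
      stop("HapMap export is defined for codominant markers only")
    d <- geno$dosages
    if (any(!is.na(d) & d != round(d)))
      stop("HapMap export requires integer dosages")
    code <- matrix("N", nrow = nrow(d), ncol = ncol(d))
    code[!is.na(d) & d == 0] <- "A"
    code[!is.na(d) & d == 1] <- "M"
    code[!is.na(d) & d == 2] <- "C"
    meta <- data.frame(
      `rs#` = colnames(d), alleles = "A/C",
      chrom = if (is.null(geno$chrom)) "0" else geno$chrom,
      pos = if (is.null(geno$pos)) seq_len(ncol(d)) else geno$pos,
      strand = "+", `assembly#` = NA, center = NA, protLSID = NA,
      assayLSID = NA, panelLSID = NA, QCcode = NA, check.names = FALSE)
    out <- cbind(meta, as.data.frame(t(code)))
    colnames(out)[-(1:11)] <- rownames(d)
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       quote = FALSE, na = "NA")
  }
  invisible(path)
}
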