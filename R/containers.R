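#' Construct a gene annotation table
#'
#' A gene annotation is a data frame with one row per locus and columns
#' `id`, `chrom`, `start`, `end` (1-based, inclusive), `strand` (`+`/`-`)
#' and `biotype` (`mRNA`/`lncRNA`). The constructor validates the
#' invariants; all pipeline functions taking an `annotation` argument
#' expect this layout.
#'
#' @param id,chrom character vectors.
#' @param start,end integer-like genomic coordinates, 1-based inclusive.
#' @param strand character, `"+"` or `"-"`.
#' @param biotype character, `"mRNA"` or `"lncRNA"`.
#' @return a validated data frame of class `c("gene_annotation", "data.frame")`.
#' @export
gene_annotation <- function(id, chrom, start, end, strand, biotype) {
  ann <- data.frame(id = as.character(id), chrom = as.character(chrom),
                    start = as.integer(start), end = as.integer(end),
                    strand = as.character(strand),
                    biotype = as.character(biotype),
                    stringsAsFactors = FALSE)
  validate_annotation(ann)
}

#' @rdname gene_annotation
#' @param ann a data frame with the annotation columns.
#' @export
validate_annotation <- function(ann) {
  req <- c("id", "chrom", "start", "end", "strand", "biotype")
  miss <- setdiff(req, names(ann))
  if (length(miss)) {
    stop("annotation is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(ann)) {
    if (anyDuplicated(ann$id)) stop("duplicated feature id in annotation",
                                    call. = FALSE)
    if (any(ann$start < 1L)) stop("annotation start must be >= 1",
                                  call. = FALSE)
    if (any(ann$start > ann$end)) stop("annotation start must be <= end",
                                       call. = FALSE)
    if (!all(ann$strand %in% c("+", "-"))) {
      stop("annotation strand must be '+' or '-'", call. = FALSE)
    }
    if (!all(ann$biotype %in% c("mRNA", "lncRNA"))) {
      stop("annotation biotype must be 'mRNA' or 'lncRNA'", call. = FALSE)
    }
  }
  class(ann) <- unique(c("gene_annotation", class(ann)))
  ann
}

#' Construct an expression matrix
#'
#' Features x samples matrix of non-negative values with a unit tag
#' (`count`, `FPKM` or `TPM`) and a condition label per sample.
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param unit one of `"count"`, `"FPKM"`, `"TPM"`.
#' @param conditions named character vector mapping every sample id to a
#'   condition label (e.g. `NF`, `LF`).
#' @return an object of class `"expression_matrix"`: the matrix with
#'   attributes `unit` and `conditions`.
#' @export
expression_matrix <- function(values, unit = c("count", "FPKM", "TPM"),
                              conditions) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values)) && nrow(values) > 0) {
    stop("expression matrix must have feature ids as rownames", call. = FALSE)
  }
  if (is.null(colnames(values))) {
    stop("expression matrix must have sample ids as colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("duplicated feature ids",
                                            call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("duplicated sample ids",
                                            call. = FALSE)
  if (any(values < 0, na.rm = TRUE)) stop("expression values must be >= 0",
                                          call. = FALSE)
  missing_cond <- setdiff(colnames(values), names(conditions))
  if (length(missing_cond)) {
    stop("sample(s) without condition label: ",
         paste(missing_cond, collapse = ", "), call. = FALSE)
  }
  structure(values, unit = unit,
            conditions = conditions[colnames(values)],
            class = c("expression_matrix", "matrix", "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d features x %d samples [%s]\n",
              nrow(x), ncol(x), attr(x, "unit")))
  cond <- attr(x, "conditions")
  cat("conditions:", paste(sprintf("%s=%s", names(cond), cond),
                           collapse = ", "), "\n")
  invisible(x)
}

em_unit <- function(x) attr(x, "unit")
em_conditions <- function(x) attr(x, "conditions")

#' Construct genotype calls
#'
#' Biallelic SNP genotypes coded as alt-allele counts 0/1/2 (`NA` =
#' missing call).
#'
#' @param snps data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (single bases, ref != alt).
#' @param codes integer matrix, SNPs x accessions, entries in
#'   `c(0, 1, 2, NA)`; colnames are accession ids.
#' @return a list of class `"genotype_calls"` with elements `snps` and
#'   `codes`.
#' @export
genotype_calls <- function(snps, codes) {
  codes <- as.matrix(codes)
  stopifnot(is.data.frame(snps),
            all(c("chrom", "pos", "ref", "alt") %in% names(snps)),
            nrow(snps) == nrow(codes))
  if (nrow(snps)) {
    if (any(snps$pos < 1L)) stop("SNP pos must be >= 1", call. = FALSE)
    if (any(snps$ref == snps$alt)) stop("ref and alt alleles must differ",
                                        call. = FALSE)
  }
  if (is.null(colnames(codes))) stop("codes must have accession ids as colnames",
                                     call. = FALSE)
  if (anyDuplicated(colnames(codes))) stop("duplicated accession ids",
                                           call. = FALSE)
  bad <- !(codes %in% c(0L, 1L, 2L) | is.na(codes))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  structure(list(snps = snps, codes = codes), class = "genotype_calls")
}

#' @export
print.genotype_calls <- function(x, ...) {
  cat(sprintf("genotype_calls: %d SNPs x %d accessions (%.1f%% missing)\n",
              nrow(x$codes), ncol(x$codes),
              100 * mean(is.na(x$codes))))
  invisible(x)
}

# Validate a phenotype table: named character vector accession -> class.
validate_phenotypes <- function(class_of, accessions = NULL,
                                classes = c("NF", "LF")) {
  if (!all(class_of %in% classes)) {
    stop("phenotype classes must be one of: ", paste(classes, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(accessions)) {
    miss <- setdiff(accessions, names(class_of))
    if (length(miss)) {
      stop("accession(s) without phenotype class: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  class_of
}
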