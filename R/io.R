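#' Read a gene annotation from GFF3
#'
#' Reads a GFF3 file into the package's annotation table. Records are
#' selected by the biotype attribute (default key `"biotype"`, values
#' `mRNA`/`lncRNA`); ids come from the `ID` attribute. Coordinates stay
#' 1-based inclusive as in GFF3.
#'
#' @param path path to a GFF3 file.
#' @param biotype_key column-9 attribute key holding the biotype.
#' @return a `gene_annotation` data frame.
#' @export
read_gff3 <- function(path, biotype_key = "biotype") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L) {
      stop(sprintf("malformed GFF3 line %d: expected 9 fields, got %d",
                   i, length(f)), call. = FALSE)
    }
    if (!f[7] %in% c("+", "-")) {
      stop(sprintf("unknown strand '%s' on GFF3 line %d", f[7], i),
           call. = FALSE)
    }
  }
  if (!length(body)) {
    return(gene_annotation(character(), character(), integer(), integer(),
                           character(), character()))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  if (!"ID" %in% names(mc)) stop("GFF3 records lack an ID attribute",
                                 call. = FALSE)
  if (!biotype_key %in% names(mc)) {
    stop("GFF3 records lack the biotype attribute '", biotype_key, "'",
         call. = FALSE)
  }
  gene_annotation(
    id = as.character(mc$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    biotype = as.character(mc[[biotype_key]])
  )
}

#' Write a gene annotation to GFF3
#'
#' Inverse of [read_gff3()]: the written file reads back to an identical
#' annotation table.
#'
#' @param ann a `gene_annotation` data frame.
#' @param path output path.
#' @param biotype_key attribute key used for the biotype.
#' @export
write_gff3 <- function(ann, path, biotype_key = "biotype") {
  ann <- validate_annotation(ann)
  attr_col <- sprintf("ID=%s;%s=%s", ann$id, biotype_key, ann$biotype)
  rows <- sprintf("%s\tflorin\tgene\t%d\t%d\t.\t%s\t.\t%s",
                  ann$chrom, ann$start, ann$end, ann$strand, attr_col)
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Read transcript sequences from FASTA
#'
#' Ids are taken from the header up to the first whitespace; sequences are
#' upper-cased and U is normalised to T so that all downstream sequence
#' logic runs on the DNA alphabet.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences (names = ids), in file
#'   order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) return(stats::setNames(character(), character()))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for FASTA id: ", ids[!nzchar(seqs)][1],
         call. = FALSE)
  }
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    stop("non-ACGT/U character in FASTA record: ", ids[bad][1],
         call. = FALSE)
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' First column = feature id, remaining columns = samples, with a header
#' row.
#'
#' @param path path to a TSV file.
#' @param unit unit tag for the values (`count`, `FPKM`, `TPM`).
#' @param conditions named character vector mapping sample ids to
#'   condition labels.
#' @return an [expression_matrix()].
#' @export
read_expression_table <- function(path, unit = "count", conditions) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression table needs a feature column plus >= 1 sample",
                           call. = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1]])
  expression_matrix(m, unit = unit, conditions = conditions)
}

#' Write an expression matrix to TSV
#'
#' @param em an [expression_matrix()].
#' @param path output path.
#' @param id_col name of the feature-id column in the header.
#' @export
write_expression_table <- function(em, path, id_col = "feature") {
  df <- data.frame(rownames(em), as.data.frame(unclass(em)[, , drop = FALSE]),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(em))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read biallelic SNP genotypes from a VCF
#'
#' A minimal GT-only reader: only biallelic SNP records (single-base ref
#' and alt) are consumed; all other records are skipped and the skip count
#' reported via a message. Calls are coded by alt-allele count (0/1/2),
#' `./.` (or `.|.`) as missing; phased and unphased separators are
#' accepted.
#'
#' @param path path to an (uncompressed) VCF.
#' @return a [genotype_calls()] object; the number of skipped records is
#'   available as attribute `"skipped"`.
#' @export
read_vcf_minimal <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_rec <- nrow(fix)
  if (n_rec == 0) {
    return(genotype_calls(data.frame(chrom = character(), pos = integer(),
                                     ref = character(), alt = character()),
                          matrix(integer(), 0, 0,
                                 dimnames = list(NULL, character()))))
  }
  keep <- !is.na(fix$ALT) & nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% DNA_BASES & fix$ALT %in% DNA_BASES
  skipped <- sum(!keep)
  if (skipped) message(skipped, " non-biallelic/non-SNP record(s) skipped")
  fmt <- v@gt[, 1]
  if (!all(vapply(strsplit(fmt, ":", fixed = TRUE),
                  function(x) "GT" %in% x, logical(1)))) {
    stop("VCF record without GT in FORMAT", call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  codes <- matrix(NA_integer_, nrow(gt), ncol(gt),
                  dimnames = list(NULL, colnames(gt)))
  for (code in 0:2) {
    pats <- switch(as.character(code),
                   "0" = c("0/0", "0|0"),
                   "1" = c("0/1", "0|1", "1/0", "1|0"),
                   "2" = c("1/1", "1|1"))
    codes[gt %in% pats] <- code
  }
  gc <- genotype_calls(
    snps = data.frame(chrom = fix$CHROM[keep],
                      pos = as.integer(fix$POS[keep]),
                      ref = fix$REF[keep], alt = fix$ALT[keep],
                      stringsAsFactors = FALSE),
    codes = codes
  )
  attr(gc, "skipped") <- skipped
  gc
}

#' Write biallelic genotypes to a minimal VCF
#'
#' @param gc a [genotype_calls()] object.
#' @param path output path.
#' @export
write_vcf_minimal <- function(gc, path) {
  stopifnot(inherits(gc, "genotype_calls"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(gc$codes)),
                     collapse = "\t")), con)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gc$codes + 1L],
                   nrow(gc$codes), ncol(gc$codes))
  gt_str[is.na(gc$codes)] <- "./."
  for (i in seq_len(nrow(gc$snps))) {
    writeLines(paste(c(gc$snps$chrom[i], gc$snps$pos[i], ".",
                       gc$snps$ref[i], gc$snps$alt[i], ".", "PASS", ".",
                       "GT", gt_str[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}

NETWORK_EDGE_KINDS <- c("miRNA->mRNA", "miRNA->lncRNA",
                        "lncRNA-mRNA(cis)", "lncRNA-mRNA(trans)")

validate_edges <- function(edges) {
  req <- c("source", "target", "kind")
  if (!all(req %in% names(edges))) {
    stop("network edges need columns source, target, kind", call. = FALSE)
  }
  if (nrow(edges)) {
    if (!all(edges$kind %in% NETWORK_EDGE_KINDS)) {
      stop("unknown edge kind; allowed: ",
           paste(NETWORK_EDGE_KINDS, collapse = ", "), call. = FALSE)
    }
    if (any(edges$source == edges$target)) stop("self-edges are not allowed",
                                                call. = FALSE)
  }
  edges
}

#' Write a regulatory network to disk
#'
#' Edge-list TSV (fixed column order `source`, `target`, `kind`) or
#' GraphML via igraph.
#'
#' @param edges data frame with columns `source`, `target`, `kind`.
#' @param path output path.
#' @param format `"tsv"` or `"graphml"`.
#' @export
write_network <- function(edges, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  edges <- validate_edges(edges)
  if (format == "tsv") {
    utils::write.table(edges[, c("source", "target", "kind")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      edges[, c("source", "target", "kind")], directed = TRUE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read an edge-list TSV written by [write_network()]
#'
#' @param path path to the TSV.
#' @return data frame with columns `source`, `target`, `kind`.
#' @export
read_network <- function(path) {
  edges <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = "character")
  validate_edges(edges)
}
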