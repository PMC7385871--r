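#' Read and write the standard interchange formats
#'
#' FASTA files are handled through Biostrings; VCF files are written in a
#' fixed VCF 4.2 dialect with phased `GT` fields and read back through vcfR;
#' BED tables and truth TSVs are plain tab-separated text.
#'
#' @param ref a `reference_seq`
#' @param path file path
#' @name graphpop-io
NULL

#' @rdname graphpop-io
#' @export
write_fasta <- function(ref, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(ref$sequence, ref$name))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname graphpop-io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  structure(list(name = sub("\\s.*", "", names(x)[1]),
                 sequence = as.character(x[[1]]),
                 length = Biostrings::width(x)[1]),
            class = "reference_seq")
}

#' Write a variant panel as VCF 4.2 with phased genotypes
#'
#' @param panel a [simulate_population()] panel
#' @param path output file
#' @export
write_vcf <- function(panel, path) {
  v <- panel$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", panel$ref_name),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$samples$sample),
                     collapse = "\t")), con)
  if (nrow(v) > 0) {
    H <- panel$haplotypes
    gts <- matrix("", nrow(panel$samples), nrow(v))
    for (i in seq_len(nrow(panel$samples))) {
      r <- 2L * i - 1L
      gts[i, ] <- paste0(H[r, ], "|", H[r + 1L, ])
    }
    rows <- vapply(seq_len(nrow(v)), function(j) {
      paste(c(v$chrom[j], v$pos[j] + 1L, v$id[j], v$ref[j], v$alt[j], ".",
              "PASS", paste0("VT=", v$vclass[j]), "GT", gts[, j]),
            collapse = "\t")
    }, "")
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a phased biallelic VCF into a variant panel
#'
#' Sample-to-population assignment defaults to a single population `"pop1"`;
#' pass a named vector to override.
#'
#' @param path VCF file (plain text)
#' @param pops optional named character vector sample -> population
#' @export
read_vcf_panel <- function(path, pops = NULL) {
  vc <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vc@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vc)
  samples <- colnames(gt)
  pop <- if (is.null(pops)) rep("pop1", length(samples)) else pops[samples]
  rlen <- nchar(fix$REF); alen <- nchar(fix$ALT)
  vclass <- ifelse(rlen == 1 & alen == 1, "SNP",
                   ifelse(alen > rlen, "INS", "DEL"))
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                sprintf("v%05d", seq_len(nrow(fix))), fix$ID)
  variants <- tibble::tibble(id = ids, chrom = fix$CHROM,
                             pos = as.integer(fix$POS) - 1L,
                             ref = fix$REF, alt = fix$ALT, vclass = vclass,
                             length_delta = as.integer(alen - rlen))
  H <- matrix(0L, nrow = 2 * length(samples), ncol = nrow(variants),
              dimnames = list(paste0(rep(samples, each = 2), "_h", 1:2),
                              ids))
  for (i in seq_along(samples)) {
    parts <- strsplit(gt[, i], "[|/]")
    H[2 * i - 1, ] <- as.integer(vapply(parts, `[`, "", 1))
    H[2 * i, ] <- as.integer(vapply(parts, `[`, "", 2))
  }
  smp <- tibble::tibble(sample = samples, pop = pop)
  af <- .panel_af(H, rep(pop, each = 2), unique(pop))
  structure(list(variants = variants, samples = smp, haplotypes = H,
                 af = af, ref_name = variants$chrom[1]),
            class = "variant_panel")
}

#' @rdname graphpop-io
#' @param annotations BED-like data frame (`start`, `end`, `label`)
#' @param chrom chromosome name for the BED records
#' @export
write_bed <- function(annotations, path, chrom = "chrS") {
  utils::write.table(
    data.frame(chrom = chrom, start = annotations$start,
               end = annotations$end, name = annotations$label),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname graphpop-io
#' @export
read_bed <- function(path) {
  b <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(b)[1:3] <- c("chrom", "start", "end")
  if (ncol(b) >= 4) names(b)[4] <- "label" else b$label <- "region"
  tibble::as_tibble(b[, c("start", "end", "label")])
}

#' Write simulated reads as FASTQ with truth-encoding names
#'
#' Read names encode the truth fields: sample, haplotype, true reference
#' start, strand, mate and non-reference flag. A companion truth TSV can be
#' written with [write_truth_tsv()].
#'
#' @param reads a [simulate_reads()] tibble
#' @param path output file
#' @export
write_fastq <- function(reads, path) {
  nr <- reads$contains_nonref
  nr[is.na(nr)] <- FALSE
  names <- sprintf("@%s|%s|h%d|%d|%s|nonref=%d", reads$id, reads$sample,
                   reads$hap, reads$true_ref_start, reads$strand,
                   as.integer(nr))
  qual <- strrep("I", nchar(reads$seq))
  writeLines(as.vector(rbind(names, reads$seq, "+", qual)), path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
write_truth_tsv <- function(reads, path) {
  utils::write.table(
    reads[, c("id", "sample", "hap", "true_ref_start", "true_ref_end",
              "strand", "contains_nonref")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genotype calls as VCF 4.2 with GT, AD, DP and site annotations
#'
#' Homozygous-reference calls are not emitted as variant records.
#'
#' @param calls a [pileup_and_call()] tibble
#' @param path output file
#' @param chrom contig name
#' @param sample sample name for the genotype column
#' @export
write_calls_vcf <- function(calls, path, chrom = "chrS", sample = "sample1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", chrom),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mean mapping quality\">",
               "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sample), collapse = "\t")), con)
  keep <- calls$genotype != "0/0"
  cc <- calls[keep, , drop = FALSE]
  if (nrow(cc) > 0) {
    rows <- sprintf("%s\t%d\t%s\t%s\t%s\t%.1f\t%s\tMQ=%.1f;QD=%.2f\tGT:AD:DP\t%s:%d,%d:%d",
                    chrom, cc$pos + 1L, cc$id, cc$ref, cc$alt, cc$QUAL,
                    ifelse(cc$filter_status == "pass", "PASS",
                           cc$filter_reason),
                    cc$mean_MQ, cc$QD, cc$genotype, cc$AD_ref, cc$AD_alt,
                    cc$DP)
    writeLines(rows, con)
  }
  invisible(path)
}
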