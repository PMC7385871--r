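#' Build a major-allele consensus linear reference
#'
#' Replaces the reference allele by the alternate allele at every panel site
#' whose alternate allele frequency in `pop` strictly exceeds 0.5 (at exactly
#' 0.5 the reference allele is retained), optionally restricted to SNPs so
#' the coordinate system is preserved. The returned chain maps original
#' reference coordinates to consensus coordinates.
#'
#' @param ref a [generate_reference()] reference
#' @param panel a [simulate_population()] panel
#' @param pop population label (or vector of labels pooled for a multi-
#'   population consensus)
#' @param snp_only replace only SNP alleles
#' @return list with `consensus` (a `reference_seq`), `chain` (a
#'   [chain_map()], original -> consensus), and `replaced` (tibble of
#'   replaced sites)
#' @export
build_consensus <- function(ref, panel, pop, snp_only = FALSE) {
  if (!all(pop %in% panel$samples$pop)) stop("unknown population")
  rows <- .hap_rows(panel, pop = pop)
  af <- if (ncol(panel$haplotypes) > 0)
    colMeans(panel$haplotypes[rows, , drop = FALSE]) else numeric(0)
  sel <- panel$variants[af > 0.5, , drop = FALSE]
  if (snp_only) sel <- sel[sel$vclass == "SNP", , drop = FALSE]
  ap <- apply_variants(ref$sequence, sel)
  cons <- structure(list(name = paste0(ref$name, "_consensus"),
                         sequence = ap$sequence,
                         length = nchar(ap$sequence)),
                    class = "reference_seq")
  list(consensus = cons, chain = ap$chain, replaced = sel)
}
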