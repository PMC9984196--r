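#' Build a dual spliced + unspliced transcriptome
#'
#' For every transcript in the annotation two sequences are produced: the
#' spliced isoform (exon sequences concatenated 5' to 3') and the
#' unspliced isoform (the full genomic span from transcript start to end,
#' introns retained). Quantifying reads against both lets pre-mRNA and
#' mature mRNA abundances be estimated competitively. Minus-strand
#' transcripts are reverse-complemented; single-exon transcripts yield two
#' identical sequences. Record ids carry \code{"::spliced"} /
#' \code{"::unspliced"} suffixes and records are ordered by transcript id,
#' spliced before unspliced.
#'
#' @param genome a \code{Biostrings::DNAStringSet} named by contig, or the
#'   path of a genome FASTA.
#' @param annotation a \code{GenomicRanges::GRanges} of exons (metadata
#'   columns \code{type == "exon"}, \code{transcript_id} or \code{Parent},
#'   optional \code{gene_id}), or the path of a GFF3 file.
#' @return list with \code{seqs} (a \code{DNAStringSet}) and \code{map}
#'   (data.frame \code{record_id}, \code{transcript_id}, \code{gene_id},
#'   \code{isoform_class}, \code{n_exons}, \code{length}).
#' @export
build_dual_transcriptome <- function(genome, annotation) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (!methods::is(genome, "DNAStringSet"))
    stop("genome must be a DNAStringSet or FASTA path")
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (is.character(annotation))
    annotation <- rtracklayer::import(annotation, format = "gff3")
  gr <- annotation
  mc <- S4Vectors::mcols(gr)
  if ("type" %in% names(mc)) gr <- gr[mc$type == "exon"]
  mc <- S4Vectors::mcols(gr)
  if (!length(gr)) stop("annotation contains no exon records")
  tx <- if ("transcript_id" %in% names(mc)) as.character(mc$transcript_id)
        else if ("Parent" %in% names(mc))
          vapply(mc$Parent, function(p) as.character(p)[1], character(1))
        else stop("exons need a transcript_id or Parent attribute")
  tx <- sub("^transcript:", "", tx)
  gene <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id) else tx
  if (anyNA(tx)) stop("exon(s) without transcript assignment")

  out_ids <- character(0); out_seqs <- character(0)
  map <- NULL
  for (t in sort(unique(tx))) {
    sel <- which(tx == t)
    ex <- gr[sel]
    chr <- as.character(GenomicRanges::seqnames(ex))
    if (length(unique(chr)) != 1)
      stop("transcript ", t, " spans multiple contigs")
    chr <- chr[1]
    if (!chr %in% names(genome))
      stop("contig ", chr, " not found in the genome")
    strand <- unique(as.character(BiocGenerics::strand(ex)))
    if (length(strand) != 1 || !strand %in% c("+", "-"))
      stop("transcript ", t, " has unknown or mixed strand: ",
           paste(strand, collapse = "/"))
    st <- BiocGenerics::start(ex); en <- BiocGenerics::end(ex)
    if (any(st < 1) || any(en > length(genome[[chr]])))
      stop("exon of transcript ", t, " lies outside contig ", chr)
    o <- order(st)
    spliced <- do.call(Biostrings::xscat,
                       lapply(o, function(i)
                         Biostrings::subseq(genome[[chr]], st[i], en[i])))
    unspliced <- Biostrings::subseq(genome[[chr]], min(st), max(en))
    if (strand == "-") {
      spliced <- Biostrings::reverseComplement(spliced)
      unspliced <- Biostrings::reverseComplement(unspliced)
    }
    out_ids <- c(out_ids, paste0(t, "::spliced"), paste0(t, "::unspliced"))
    out_seqs <- c(out_seqs, as.character(spliced), as.character(unspliced))
    map <- rbind(map,
                 data.frame(record_id = paste0(t, c("::spliced", "::unspliced")),
                            transcript_id = t, gene_id = gene[sel][1],
                            isoform_class = c("spliced", "unspliced"),
                            n_exons = length(sel),
                            length = c(sum(en - st + 1),
                                       max(en) - min(st) + 1),
                            stringsAsFactors = FALSE))
  }
  seqs <- Biostrings::DNAStringSet(out_seqs)
  names(seqs) <- out_ids
  rownames(map) <- NULL
  list(seqs = seqs, map = map)
}

#' Compare localization bias between spliced and unspliced isoforms
#'
#' Pairs the bias of each transcript's spliced and unspliced isoform (ids
#' suffixed \code{"::spliced"} / \code{"::unspliced"}) and compares the two
#' class distributions with a two-sided Wilcoxon rank-sum test. A nuclear
#' pre-mRNA pool depleted from the assayed compartment shows up as
#' systematically lower unspliced bias.
#'
#' @param bias a \code{bias_table} whose \code{gene_id} values are dual
#'   transcriptome record ids.
#' @param map the \code{map} element from
#'   \code{\link{build_dual_transcriptome}}.
#' @return list: \code{pairs} (data.frame \code{transcript_id},
#'   \code{spliced_bias}, \code{unspliced_bias}, \code{difference}),
#'   \code{median_spliced}, \code{median_unspliced}, \code{p_value}.
#' @export
compare_isoform_bias <- function(bias, map) {
  if (!all(c("gene_id", "bias") %in% names(bias)))
    stop("bias needs gene_id and bias columns")
  m <- merge(map, bias[, c("gene_id", "bias")],
             by.x = "record_id", by.y = "gene_id")
  sp <- m$bias[m$isoform_class == "spliced"]
  un <- m$bias[m$isoform_class == "unspliced"]
  if (length(sp) < 2 || length(un) < 2)
    stop("need at least 2 measured transcripts per isoform class")
  wide <- merge(
    stats::setNames(m[m$isoform_class == "spliced",
                      c("transcript_id", "bias")],
                    c("transcript_id", "spliced_bias")),
    stats::setNames(m[m$isoform_class == "unspliced",
                      c("transcript_id", "bias")],
                    c("transcript_id", "unspliced_bias")))
  wide$difference <- wide$spliced_bias - wide$unspliced_bias
  ht <- rank_sum_test(sp, un)
  list(pairs = wide,
       median_spliced = stats::median(sp),
       median_unspliced = stats::median(un),
       p_value = ht$p_value)
}
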