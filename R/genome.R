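#' Genome model for synthetic cohorts
#'
#' A `genome_model` holds chromosome sizes, gene models with strand-aware
#' transcription start sites (TSS), optionally exon structure, and optionally
#' nucleotide sequence. It grounds every interval operation in the pipeline:
#' peak placement, fragment simulation, nearest-TSS target assignment and
#' genomic-context classification.
#'
#' Coordinates are 1-based and inclusive in memory (the Bioconductor
#' convention); all files written to disk use BED 0-based half-open
#' coordinates via \pkg{rtracklayer}.
#'
#' @param chromosomes named integer vector of chromosome lengths in bp.
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end`, `tss`.
#' @param exons optional data.frame with columns `gene_id`, `chrom`, `start`,
#'   `end`; when absent each gene body counts as a single exon.
#' @param sequence optional [Biostrings::DNAStringSet] named by chromosome.
#' @return an object of class `genome_model`.
#' @export
genome_model <- function(chromosomes, genes, exons = NULL, sequence = NULL) {
  stopifnot(is.numeric(chromosomes), !is.null(names(chromosomes)))
  genes <- as.data.frame(genes)
  if (nrow(genes) > 0) {
    needed <- c("gene_id", "chrom", "strand", "start", "end", "tss")
    if (!all(needed %in% names(genes)))
      stop("genes must have columns: ", paste(needed, collapse = ", "))
    if (anyDuplicated(genes$gene_id))
      stop("gene_ids must be unique")
    exp_tss <- ifelse(genes$strand == "+", genes$start, genes$end)
    if (!all(genes$tss == exp_tss))
      stop("TSS must equal gene start on + strand and gene end on - strand")
    bad <- genes$start < 1 | genes$end > chromosomes[genes$chrom]
    if (any(bad))
      stop("gene coordinates outside chromosome bounds: ",
           paste(genes$gene_id[bad], collapse = ", "))
  }
  structure(
    list(chromosomes = chromosomes, genes = genes, exons = exons,
         sequence = sequence),
    class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosome(s), %.3g Mb, %d gene(s)%s\n",
              length(x$chromosomes), sum(x$chromosomes) / 1e6,
              nrow(x$genes),
              if (is.null(x$sequence)) "" else ", with sequence"))
  invisible(x)
}

## Place n non-overlapping elements of width w on [1, L]; returns sorted starts.
## Classic spacing construction: draw n distinct offsets in the shrunken
## interval, then re-expand, which guarantees pairwise gaps >= w.
place_nonoverlapping <- function(n, L, w, min_gap = 0) {
  if (n == 0) return(integer(0))
  eff <- w + min_gap
  slack <- L - n * eff
  if (slack < n)
    stop(sprintf(
      "density infeasible: cannot place %d elements of width %d (gap %d) on %d bp",
      n, w, min_gap, L))
  offs <- sort(sample.int(slack, n))
  offs + (seq_len(n) - 1L) * eff + 1L
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate a random genome with uniformly placed genes
#'
#' Chromosomes are named `chr1..chrN` and share a common length. Genes are
#' placed uniformly at random without overlap, with random strands; the TSS
#' is the gene start on the `+` strand and the gene end on the `-` strand.
#' Sequence, when requested, is i.i.d. uniform over `{A,C,G,T}` (motifs are
#' planted later by [plant_motifs()]).
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_genes number of genes to place.
#' @param seed integer seed; output is byte-identical for a fixed seed.
#' @param gene_length gene body length in bp (default 1000).
#' @param exons_per_gene exons per gene; when `> 1` the gene body is split
#'   into that many equal exons separated by introns, enabling intron/exon
#'   context classification.
#' @param with_sequence generate nucleotide sequence (default TRUE).
#' @return a [genome_model()].
#' @export
generate_genome <- function(n_chrom, chrom_length, n_genes, seed,
                            gene_length = 1000, exons_per_gene = 1,
                            with_sequence = TRUE) {
  stopifnot(n_chrom >= 1, chrom_length >= 1, n_genes >= 0)
  set.seed(seed)
  chroms <- stats::setNames(rep(as.integer(chrom_length), n_chrom),
                            paste0("chr", seq_len(n_chrom)))
  if (n_genes > 0 && n_genes * gene_length > 0.5 * sum(chroms))
    stop(sprintf(
      "density infeasible: %d genes x %d bp exceed half the genome (%d bp)",
      n_genes, gene_length, sum(chroms)))
  ## deal genes across chromosomes as evenly as randomness allows
  per_chrom <- tabulate(sample.int(n_chrom, n_genes, replace = TRUE), n_chrom)
  genes <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
    ng <- per_chrom[i]
    if (ng == 0) return(NULL)
    starts <- place_nonoverlapping(ng, chroms[i], gene_length)
    data.frame(chrom = names(chroms)[i], start = starts,
               end = starts + gene_length - 1L,
               strand = sample(c("+", "-"), ng, replace = TRUE))
  }))
  if (is.null(genes))
    genes <- data.frame(gene_id = character(0), chrom = character(0),
                        strand = character(0), start = integer(0),
                        end = integer(0), tss = integer(0))
  else {
    genes$gene_id <- sprintf("gene_%04d", seq_len(nrow(genes)))
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
    genes <- genes[, c("gene_id", "chrom", "strand", "start", "end", "tss")]
  }
  exons <- NULL
  if (exons_per_gene > 1 && nrow(genes) > 0) {
    k <- as.integer(exons_per_gene)
    exon_w <- gene_length %/% (2 * k - 1)
    if (exon_w < 1) stop("gene_length too short for requested exon count")
    exons <- do.call(rbind, lapply(seq_len(nrow(genes)), function(g) {
      s <- genes$start[g] + (seq_len(k) - 1L) * 2L * exon_w
      data.frame(gene_id = genes$gene_id[g], chrom = genes$chrom[g],
                 start = s, end = pmin(s + exon_w - 1L, genes$end[g]))
    }))
    ## keep the last exon flush with the annotated gene end
    last <- cumsum(rep(k, nrow(genes)))
    exons$end[last] <- genes$end
  }
  sequence <- NULL
  if (with_sequence) {
    sequence <- Biostrings::DNAStringSet(
      vapply(chroms, random_dna, character(1)))
    names(sequence) <- names(chroms)
  }
  genome_model(chroms, genes, exons = exons, sequence = sequence)
}

#' Gene TSS positions as a GRanges of width-1 anchors
#' @param genome a [genome_model()].
#' @return a [GenomicRanges::GRanges] with one range per gene at its TSS.
#' @export
tss_ranges <- function(genome) {
  g <- genome$genes
  GenomicRanges::GRanges(g$chrom,
                         IRanges::IRanges(g$tss, width = 1),
                         strand = g$strand, gene_id = g$gene_id,
                         seqlengths = genome$chromosomes)
}

#' Write a genome model to disk (chrom.sizes + GFF3 + FASTA)
#' @param genome a [genome_model()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sizes <- file.path(dir, "genome.chrom.sizes")
  utils::write.table(
    data.frame(names(genome$chromosomes), unname(genome$chromosomes)),
    sizes, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  gff <- file.path(dir, "genes.gff3")
  g <- genome$genes
  gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                               strand = g$strand,
                               seqlengths = genome$chromosomes)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- g$gene_id
  rtracklayer::export(gr, gff, format = "gff3")
  paths <- c(sizes, gff)
  if (!is.null(genome$sequence)) {
    fa <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(genome$sequence, fa)
    paths <- c(paths, fa)
  }
  invisible(paths)
}

#' Read a genome model back from chrom.sizes + GFF3 (+ optional FASTA)
#' @param sizes_file two-column chrom.sizes file.
#' @param gff3_file GFF3 with `gene` features carrying an `ID`.
#' @param fasta_file optional FASTA of chromosome sequence.
#' @return a [genome_model()].
#' @export
read_genome <- function(sizes_file, gff3_file, fasta_file = NULL) {
  sz <- utils::read.table(sizes_file, sep = "\t",
                          col.names = c("chrom", "length"))
  chroms <- stats::setNames(as.integer(sz$length), sz$chrom)
  gr <- rtracklayer::import(gff3_file, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  genes <- data.frame(
    gene_id = S4Vectors::mcols(gr)$ID,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr))
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  sequence <- if (!is.null(fasta_file))
    Biostrings::readDNAStringSet(fasta_file)
  if (!is.null(sequence)) names(sequence) <- sub("\\s.*$", "", names(sequence))
  genome_model(chroms, genes, sequence = sequence)
}
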